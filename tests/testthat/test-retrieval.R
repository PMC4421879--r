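# Phase-stepping retrieval, flat-field correction, unwrapping.

sineFrames <- function(I0, V, psi, N, shape = c(1, 1)) {
  k <- seq_len(N) - 1
  vals <- I0 * (1 + V * cos(2 * pi * k / N + psi))
  array(rep(vals, each = prod(shape)), c(shape, N))
}

test_that("retrieval is exact on noiseless sinusoids", {
  r <- retrieveStepping(sineFrames(100, 0.3, 0.7, 5))
  expect_equal(as.vector(r$I0), 100)
  expect_equal(as.vector(r$psi), 0.7)
  expect_equal(as.vector(r$V), 0.3)
  # three-step minimal case recovers the same triplet
  r3 <- retrieveStepping(sineFrames(100, 0.3, 0.7, 3))
  expect_equal(as.vector(r3$psi), 0.7, tolerance = 1e-12)
  expect_equal(as.vector(r3$V), 0.3, tolerance = 1e-12)
  # sweep N, psi, V
  for (N in 3:8) for (psi in c(-3, -1.2, 0, 0.5, 3)) for (V in c(0.05, 0.5, 0.95)) {
    r <- retrieveStepping(sineFrames(50, V, psi, N))
    expect_equal(as.vector(r$psi), psi, tolerance = 1e-9)
    expect_equal(as.vector(r$V), V, tolerance = 1e-9)
    expect_equal(as.vector(r$I0), 50, tolerance = 1e-9)
  }
})

test_that("estimator matches a per-pixel least-squares sinusoid fit", {
  # oracle: solve I_k = a + b cos(t_k) + c sin(t_k) by normal equations,
  # psi = atan2(-c, b), V = sqrt(b^2 + c^2) / a
  lsOracle <- function(y, N) {
    t <- 2 * pi * (seq_len(N) - 1) / N
    X <- cbind(1, cos(t), sin(t))
    beta <- solve(crossprod(X), crossprod(X, y))
    c(I0 = beta[1], psi = atan2(-beta[3], beta[2]),
      V = sqrt(beta[2]^2 + beta[3]^2) / beta[1])
  }
  set.seed(42)
  npix <- 1000; N <- 5
  budget <- 860
  psi0 <- runif(npix, -1, 1)
  frames <- sapply(seq_len(N) - 1, function(k)
    rpois(npix, budget * (1 + 0.3 * cos(2 * pi * k / N + psi0))))
  r <- retrieveStepping(array(frames, c(npix, 1, N)))
  ref <- t(apply(frames, 1, lsOracle, N = N))
  rms <- sqrt(mean((as.vector(r$psi) - ref[, "psi"])^2))
  expect_lt(rms, 1e-3)
  expect_lt(max(abs(as.vector(r$V) - ref[, "V"])), 1e-9)
})

test_that("noisy phase estimate is unbiased within Monte-Carlo error", {
  set.seed(9)
  psi0 <- 0.6; V <- 0.3; budget <- 400; N <- 5; reps <- 10000
  frames <- sapply(seq_len(N) - 1, function(k)
    rpois(reps, budget * (1 + V * cos(2 * pi * k / N + psi0))))
  r <- retrieveStepping(array(frames, c(reps, 1, N)))
  err <- mean(r$psi) - psi0
  mcse <- sd(r$psi) / sqrt(reps)
  expect_lt(abs(err), 4 * mcse + 1e-3)
})

test_that("flat-field correction divides and wraps correctly", {
  s <- retrieveStepping(sineFrames(80, 0.25, 3.0, 5))
  r <- retrieveStepping(sineFrames(100, 0.30, -3.0, 5))
  fc <- flatCorrect(s, r)
  expect_equal(as.vector(fc$trans), 0.8)
  expect_equal(as.vector(fc$dphase), 6 - 2 * pi, tolerance = 1e-9)
  expect_equal(as.vector(fc$visRatio), 0.25 / 0.30)
  # identity on itself
  id <- flatCorrect(s, s)
  expect_equal(as.vector(id$trans), 1)
  expect_equal(as.vector(id$dphase), 0)
  expect_equal(as.vector(id$visRatio), 1)
  # antisymmetry of the corrected phase
  ba <- flatCorrect(r, s)
  expect_equal(phaseCT:::.wrapPhase(fc$dphase + ba$dphase),
               array(0, dim(fc$dphase)), tolerance = 1e-9)
})

test_that("zero-intensity pixels are flagged invalid and propagate", {
  fr <- sineFrames(100, 0.3, 0.2, 5, shape = c(2, 2))
  fr[1, 1, ] <- 0
  r <- retrieveStepping(fr)
  expect_true(r$invalid[1, 1])
  fc <- flatCorrect(r, r)
  expect_true(is.na(fc$trans[1, 1]))
  expect_false(any(is.na(fc$trans[-1, ])))
  expect_error(retrieveStepping(fr[, , 1:2]), "3")
})

test_that("row unwrapping restores wrapped ramps and leaves clean maps", {
  ramp <- seq(0, 6 * pi, length.out = 100)      # wraps twice
  wrapped <- phaseCT:::.wrapPhase(ramp)
  un <- unwrapRows(wrapped)
  expect_equal(un, ramp, tolerance = 1e-9)
  # 2-D map, row-wise
  m <- matrix(rep(wrapped, 3), ncol = 3)
  um <- unwrapRows(m)
  expect_equal(um[, 2], ramp, tolerance = 1e-9)
  # already-smooth map unchanged
  sm <- matrix(seq(-1, 1, length.out = 30), ncol = 3)
  expect_equal(unwrapRows(sm), sm)
  expect_equal(unwrapRows(matrix(0, 5, 4)), matrix(0, 5, 4))
})

test_that("retrieveStack processes a full simulated stack", {
  proj <- new("ProjectionSet", angles = c(0, 60, 120),
              dphase = array(0.25, c(8, 4, 3)),
              trans = array(0.9, c(8, 4, 3)),
              pixelSize = 0.1, talbotDistance = 3024, g2Pitch = 10)
  st <- simulateStepping(proj, Inf, visibility = 0.3, nSteps = 5)
  ret <- retrieveStack(st)
  expect_s4_class(ret, "RetrievedProjectionSet")
  expect_equal(unique(as.vector(ret@dphase)), 0.25, tolerance = 1e-12)
  expect_equal(unique(as.vector(ret@trans)), 0.9, tolerance = 1e-12)
  expect_equal(unique(as.vector(ret@visRatio)), 1, tolerance = 1e-12)
})
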