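# Forward model: projection geometry, stepping-curve synthesis, photon
# budget, Poisson statistics.

smallProjection <- function(psi = 0.3, trans = 0.9, n = 6, nAngles = 2) {
  new("ProjectionSet", angles = seq_len(nAngles) - 1,
      dphase = array(psi, c(n, n, nAngles)),
      trans = array(trans, c(n, n, nAngles)),
      pixelSize = 0.1, talbotDistance = 3024, g2Pitch = 10)
}

test_that("projection of a homogeneous slab has zero differential phase", {
  n <- 32
  grid <- array(1.025, c(n, n, 2))     # tissue fills the whole field
  ph <- new("DensityPhantom", grid = grid, voxelSize = 0.1,
            mediumDensity = 1.025, zOverM = 0.55,
            labels = array(0L, c(n, n, 2)))
  opt <- densityToOptical(ph, refBeam())
  proj <- projectVolume(opt, refGeometry(), 10, c(0, 45, 90))
  interior <- 8:24
  expect_true(all(abs(proj@dphase[interior, , ]) < 1e-12))
})

test_that("cylinder projection is antisymmetric with zero integral", {
  ph <- cylinderPhantom(n = 48, nz = 2, drho = 0.02, frac = 0.5)
  opt <- densityToOptical(ph, refBeam())
  proj <- projectVolume(opt, refGeometry(), 10, c(0, 90))
  psi <- proj@dphase[, 1, 1]
  # integral of the derivative of a compact bump vanishes
  expect_lt(abs(sum(psi)) , 1e-6 * max(abs(psi)))
  # antisymmetry about the axis
  n <- length(psi)
  expect_equal(psi[2:(n - 1)], -rev(psi)[2:(n - 1)], tolerance = 1e-6)
})

test_that("differential phase is linear in the decrement", {
  ph <- cylinderPhantom(n = 32, nz = 2, drho = 0.01)
  ph2 <- cylinderPhantom(n = 32, nz = 2, drho = 0.02)
  opt1 <- densityToOptical(ph, refBeam())
  opt2 <- densityToOptical(ph2, refBeam())
  p1 <- projectVolume(opt1, refGeometry(), 10, c(0, 30))
  p2 <- projectVolume(opt2, refGeometry(), 10, c(0, 30))
  expect_equal(p2@dphase, 2 * p1@dphase, tolerance = 1e-9)
})

test_that("projector agrees with a brute-force rotation oracle", {
  # oracle: at angle 0 the projection is a plain column sum; at 90 deg a
  # row sum of the slice
  n <- 32
  set.seed(7)
  slice <- matrix(runif(n * n), n, n)
  vol <- array(slice, c(n, n, 1))
  p <- array(phaseCT:::cpp_project(as.double(vol), as.integer(c(n, n, 1)),
                                   c(0, pi / 2), 1.0), c(n, 1, 2))
  expect_equal(p[, 1, 1], rowSums(slice), tolerance = 1e-6)
  expect_equal(p[, 1, 2], colSums(slice), tolerance = 1e-6)
})

test_that("noiseless stepping round-trips exactly through retrieval", {
  proj <- smallProjection(psi = 0.42, trans = 0.83)
  for (N in c(3L, 5L, 8L)) {
    st <- simulateStepping(proj, Inf, visibility = 0.31, nSteps = N)
    r <- retrieveStepping(st@frames[, , , 1])
    rr <- retrieveStepping(st@reference[, , , 1])
    fc <- flatCorrect(r, rr)
    expect_equal(unique(as.vector(fc$trans)), 0.83, tolerance = 1e-12)
    expect_equal(unique(as.vector(fc$dphase)), 0.42, tolerance = 1e-12)
    expect_equal(unique(as.vector(r$V)), 0.31, tolerance = 1e-12)
  }
})

test_that("mean over a noiseless sine stack is gain x budget x trans", {
  proj <- smallProjection(psi = 1.1, trans = 0.7)
  st <- simulateStepping(proj, Inf, visibility = 0.4, nSteps = 5,
                         noiselessScale = 1000)
  expect_equal(mean(apply(st@frames[, , , 1], c(1, 2), mean)),
               1000 * 0.7, tolerance = 1e-9)
})

test_that("triangle-profile first harmonic carries the 8/pi^2 factor", {
  proj <- smallProjection(psi = 0.2, trans = 1.0)
  st <- simulateStepping(proj, Inf, visibility = 0.4, nSteps = 24L,
                         profile = "triangle")
  r <- retrieveStepping(st@frames[, , , 1])
  expect_equal(unique(as.vector(r$V)) / 0.4, 8 / pi^2, tolerance = 5e-3)
})

test_that("photon budget follows flux x area x exposure x transmission", {
  beam <- refBeam()
  det <- detectorSpec(effectivePixel = 15.5)
  expect_equal(fluxToBudget(beam, det, 0.1, 1.0), 2883, tolerance = 2e-4)
  expect_equal(fluxToBudget(beam, det, 0.1, 0), 0)
  expect_equal(fluxToBudget(beam, det, 0.5, 0.3),
               5 * fluxToBudget(beam, det, 0.1, 0.3))
})

test_that("Poisson counts have variance/mean approximately the gain", {
  proj <- smallProjection(psi = 0, trans = 1, n = 128, nAngles = 1)
  for (g in c(1, 7)) {
    st <- simulateStepping(proj, photonBudget = 500, visibility = 0,
                           nSteps = 3L, gain = g, seed = 11)
    x <- as.vector(st@frames)
    expect_equal(var(x) / mean(x), g, tolerance = 0.05)
  }
})

test_that("background phase noise shrinks as the budget grows", {
  proj <- smallProjection(psi = 0, trans = 1, n = 64, nAngles = 1)
  sds <- vapply(1:5, function(m) {
    st <- simulateStepping(proj, photonBudget = m * 860, visibility = 0.3,
                           nSteps = 5L, seed = 3)
    r <- retrieveStepping(st@frames[, , , 1])
    sd(as.vector(r$psi))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("invalid simulation inputs are rejected", {
  proj <- smallProjection()
  expect_error(simulateStepping(proj, visibility = 1.5), "visibility")
  expect_error(simulateStepping(proj, photonBudget = -1), "photonBudget")
  expect_error(simulateStepping(proj, nSteps = 2), "nSteps")
})
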