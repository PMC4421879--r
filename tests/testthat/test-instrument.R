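# Closed-form instrument calculators: wavelength conversion, Talbot
# distance, tilted-analyser geometry, phase-shift scaling, detector
# geometry, Beer-Lambert budgets.

test_that("energy-to-wavelength conversion and rounding modes", {
  expect_equal(energyToWavelength(1.23984), 1.0)
  expect_equal(energyToWavelength(25, "3sf"), 0.0496)
  expect_equal(energyToWavelength(25), 1.23984 / 25)
  expect_equal(energyToWavelength(18.8), 0.0659489, tolerance = 1e-5)
  expect_error(energyToWavelength(0), "positive")
  expect_error(energyToWavelength(-5), "positive")
})

test_that("Talbot distance reproduces the instrument numbers and scalings", {
  lam25 <- energyToWavelength(25, "3sf")
  expect_equal(round(talbotDistance(10, lam25, 3)), 3024)
  expect_equal(talbotDistance(10, lam25, 1),
               talbotDistance(10, lam25, 3) / 3)
  lam188 <- energyToWavelength(18.8)
  expect_equal(round(talbotDistance(10, lam188, 3)), 2274)
  expect_error(talbotDistance(10, lam25, 2), "odd")
  expect_error(talbotDistance(10, lam25, -1), "odd")
  # linear in p, inverse in lambda, over a grid
  for (p in c(1, 3, 5, 7)) for (lam in c(0.03, 0.05, 0.08)) {
    expect_equal(talbotDistance(10, lam, p), p * talbotDistance(10, lam, 1))
    expect_equal(talbotDistance(10, lam, p),
                 talbotDistance(10, 2 * lam, p) * 2)
  }
})

test_that("tilted-G2 span and achromaticity match the quoted geometry", {
  expect_equal(tiltSpan(25, 45), 8.84, tolerance = 5e-4)
  expect_equal(tiltSpan(25, 0), 0)
  expect_equal(tiltSpan(25, 90), 12.5)
  expect_error(tiltSpan(-1, 45), ">= 0")
  # monotone on [0, 90]
  spans <- vapply(seq(0, 90, by = 5), function(t) tiltSpan(25, t),
                  numeric(1))
  expect_true(all(diff(spans) > 0))

  sh <- achromaticShift(tiltSpan(25, 45), 3024, 0.0496)
  expect_equal(signif(sh$relativeShift, 2), 5.8e-3)
  expect_equal(signif(sh$deltaLambda, 2), 2.9e-4)
  expect_equal(achromaticShift(0, 3024, 0.0496)$relativeShift, 0)
  expect_equal(achromaticShift(0, 3024, 0.0496)$deltaLambda, 0)
  # invariant under joint rescale of dz and z
  for (s in c(0.5, 2, 10))
    expect_equal(achromaticShift(s * 8.84, s * 3024)$relativeShift,
                 achromaticShift(8.84, 3024)$relativeShift)
})

test_that("grating phase shift scales as 1/E from the design point", {
  g1 <- refG1()
  expect_equal(gratingPhaseShift(g1, 18.8), pi / 2)
  expect_equal(gratingPhaseShift(g1, 25), (pi / 2) * 18.8 / 25)
  expect_equal(gratingPhaseShift(g1, 9.4), pi)
  # phi(E) * E constant
  Es <- c(10, 15, 20, 30, 40)
  expect_equal(gratingPhaseShift(g1, Es) * Es,
               rep(pi / 2 * 18.8, length(Es)))
})

test_that("detector geometry: effective pixel, override and field of view", {
  withOverride <- detectorSpec(effectivePixel = 15.5)
  eg <- effectiveGeometry(withOverride)
  expect_equal(eg$fovReported, 31.7)
  expect_equal(effectiveGeometry(
    detectorSpec(nPixels = 1, effectivePixel = 15.5))$fov, 0.0155)
  noOverride <- detectorSpec(6.5, 0.425)
  expect_equal(effectiveGeometry(noOverride)$effectivePixel, 6.5 / 0.425)
  expect_equal(signif(effectiveGeometry(noOverride)$effectivePixel, 4),
               15.29)
})

test_that("Beer-Lambert transmission multiplies over entries", {
  expect_equal(beerLambertTransmission(NULL), 1.0)
  expect_equal(beerLambertTransmission(
    data.frame(massAtten = 1, density = 1, path = 10)), exp(-1))
  water <- data.frame(massAtten = 0.5075, density = 1.0, path = 25)
  expect_equal(beerLambertTransmission(water), 0.281, tolerance = 1e-3)
  expect_error(beerLambertTransmission(
    data.frame(massAtten = 1, density = 1, path = -1)), ">= 0")
  # concatenation = product
  a <- data.frame(massAtten = 0.3, density = 1.1, path = 5)
  b <- data.frame(massAtten = 0.8, density = 0.9, path = 12)
  expect_equal(beerLambertTransmission(rbind(a, b)),
               beerLambertTransmission(a) * beerLambertTransmission(b))
})

test_that("spec objects validate their invariants", {
  expect_error(beamSpec(-1), "positive")
  expect_error(gratingSpec(10, tilt = 120), "tilt")
  expect_error(scanProtocol(600, 2), "nSteps")
  expect_error(scanProtocol(600, 5, pulsesPer180 = 1000,
                            pulseResolution = 0.002), "180")
  b <- beamSpec(25)
  expect_s4_class(b, "BeamSpec")
  expect_equal(b@wavelength, 1.23984 / 25)
})
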