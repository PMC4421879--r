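# Densitometry: decrement-to-density conversion, ROI statistics,
# histograms, volume/mass, density resolution.

test_that("decrement-to-density conversion and calibration scaling", {
  beam <- refBeam()
  conv1 <- densityConversion(beam@wavelength, 0.55, 1, 1.005)
  z <- new("DeltaVolume", grid = array(0, c(4, 4, 2)), voxelSize = 0.1,
           wavelength = beam@wavelength)
  expect_true(all(deltaToDensity(z, conv1)@grid == 1.005))
  one <- new("DeltaVolume", grid = array(3.65e-7, c(2, 2, 2)),
             voxelSize = 0.1, wavelength = beam@wavelength)
  expect_equal(mean(deltaToDensity(one, conv1)@grid) - 1.005, 1.0,
               tolerance = 2e-3)
  conv145 <- densityConversion(beam@wavelength, 0.55, 1.45, 1.005)
  d1 <- deltaToDensity(one, conv1)@grid - 1.005
  d145 <- deltaToDensity(one, conv145)@grid - 1.005
  expect_equal(d145, 1.45 * d1)
  bad <- densityConversion(0.07, 0.55)
  expect_error(deltaToDensity(one, bad), "wavelength")
})

test_that("ROI statistics use the sample standard deviation", {
  v <- array(1.5, c(3, 3, 3))
  m <- array(TRUE, c(3, 3, 3))
  s <- roiStats(v, m)
  expect_equal(s$mean, 1.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 27)
  two <- array(c(1.00, 1.02), c(2, 1, 1))
  s2 <- roiStats(two, array(TRUE, c(2, 1, 1)))
  expect_equal(s2$mean, 1.01)
  expect_equal(s2$sd, 0.01414, tolerance = 1e-3)
  expect_error(roiStats(v, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("histograms conserve counts and find injected modes", {
  v <- array(1.5, c(4, 4, 1))
  h <- densityHistogram(v, binWidth = 0.01)
  expect_equal(sum(h$counts), 16)
  expect_equal(sum(h$counts > 0), 1)
  # two-component mixture
  set.seed(1)
  mix <- array(c(rnorm(4000, 1.01, 0.002), rnorm(4000, 1.04, 0.002)),
               c(8000, 1, 1))
  h2 <- densityHistogram(mix, binWidth = 0.002)
  expect_equal(sum(h2$counts), 8000)
  expect_equal(length(h2$modes), 2L)
  expect_equal(h2$modes[1], 1.01, tolerance = 0.002)
  expect_equal(h2$modes[2], 1.04, tolerance = 0.002)
  expect_true(!is.unsorted(h2$modes))
  expect_error(densityHistogram(v, binWidth = 0), "binWidth")
})

test_that("volume and mass accounting", {
  v <- array(1.0, c(10, 10, 10))
  m <- v > 0
  vm <- volumeMass(v, m, voxelSize = 0.1)
  expect_equal(vm$volume_mm3, 1.0)
  expect_equal(vm$mass_g, 1e-3)        # 1 mm^3 of water = 1 mg
  # additivity over a label split
  m1 <- m; m1[6:10, , ] <- FALSE
  m2 <- m & !m1
  vm1 <- volumeMass(v, m1, 0.1); vm2 <- volumeMass(v, m2, 0.1)
  expect_equal(vm1$volume_mm3 + vm2$volume_mm3, vm$volume_mm3)
  expect_equal(vm1$mass_g + vm2$mass_g, vm$mass_g)
  # doubling the density doubles the mass only
  vm2x <- volumeMass(2 * v, m, 0.1)
  expect_equal(vm2x$mass_g, 2 * vm$mass_g)
  expect_equal(vm2x$volume_mm3, vm$volume_mm3)
})

test_that("density resolution recovers an injected background sigma", {
  expect_equal(densityResolution(array(1.005, c(10, 10, 10))), 0)
  set.seed(2)
  bg <- array(1.005 + rnorm(30^3, sd = 1.51e-3), c(30, 30, 30))
  expect_equal(densityResolution(bg), 1.51, tolerance = 0.05)
  # translation invariance
  expect_equal(densityResolution(bg + 5), densityResolution(bg),
               tolerance = 1e-9)
})

test_that("threshold segmentation respects the bounding region", {
  v <- array(1, c(4, 4, 1)); v[2, 2, 1] <- 2; v[4, 4, 1] <- 2
  within <- array(FALSE, c(4, 4, 1)); within[1:3, 1:3, 1] <- TRUE
  seg <- thresholdSegment(v, 1.5, within)
  expect_equal(sum(seg), 1)
  expect_true(seg[2, 2, 1])
})

test_that("full-chain density map reproduces compartment densities", {
  full <- makeFetusPhantom(scenarioParams("fetus_fresh", n = 48))
  zLiver <- round(mean(which(full@labels == 2L, arr.ind = TRUE)[, 3]))
  ph <- centralSlab(full, 2L, zCenter = zLiver)
  rho <- reconstructDensity(ph, nAngles = 200)
  liver <- erodeMask(ph@labels == 2L, 1)
  expect_equal(roiStats(rho, liver)$mean, 1.055, tolerance = 0.002)
  bg <- erodeMask(ph@labels == 0L, 4)
  expect_equal(roiStats(rho, bg)$mean, 1.005, tolerance = 0.002)
})
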