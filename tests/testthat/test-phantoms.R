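# Synthetic phantoms and the density -> optical conversion.

test_that("fetus phantom writes the requested compartment densities", {
  par <- scenarioParams("fetus_fresh", n = 48)
  ph <- makeFetusPhantom(par)
  expect_s4_class(ph, "DensityPhantom")
  expect_equal(sort(unique(as.vector(ph@labels))), 0:3)
  expect_equal(mean(ph@grid[ph@labels == 2L]), 1.055)
  expect_equal(mean(ph@grid[ph@labels == 1L]), 1.025)
  expect_true(all(ph@grid[ph@labels == 0L] == ph@mediumDensity))
  # determinism
  ph2 <- makeFetusPhantom(par)
  expect_identical(ph@grid, ph2@grid)
  expect_identical(ph@labels, ph2@labels)
})

test_that("fixation shrinks the liver by the configured volume fraction", {
  fresh <- makeFetusPhantom(scenarioParams("fetus_fresh", n = 64))
  fixed <- makeFetusPhantom(scenarioParams("fetus_fixed", n = 64))
  ratio <- sum(fixed@labels == 2L) / sum(fresh@labels == 2L)
  expect_equal(ratio, 0.65, tolerance = 0.02)
  # density increment applied to every tissue compartment
  for (l in 1:3)
    expect_equal(mean(fixed@grid[fixed@labels == l]) -
                   mean(fresh@grid[fresh@labels == l]), 0.015,
                 tolerance = 1e-12)
  # liver mass decreases under fixation (volume loss beats density gain)
  mf <- volumeMass(fresh@grid, fresh@labels == 2L, 0.1)
  mx <- volumeMass(fixed@grid, fixed@labels == 2L, 0.1)
  expect_lt(mx$mass_g, mf$mass_g)
  expect_lt(mx$volume_mm3, mf$volume_mm3)
})

test_that("aorta ring conserves layer mass across stretch steps", {
  masses <- rho2 <- numeric(6)
  for (k in 0:5) {
    a <- makeAortaPhantom(scenarioParams("aorta_stretch", n = 64,
                                         stretchStep = k))
    masses[k + 1] <- sum(a@grid[a@labels > 0L]) * a@voxelSize^3
    rho2[k + 1] <- mean(a@grid[a@labels == 2L])
  }
  expect_lt(diff(range(masses)) / masses[1], 0.005)
  expect_true(all(diff(rho2) > 0))
  expect_lte(rho2[6] - rho2[1], 0.005)
})

test_that("aorta ring at step 0 shows two distinct density modes", {
  a <- makeAortaPhantom(scenarioParams("aorta_stretch", n = 64))
  h <- densityHistogram(a@grid, a@labels > 0L, binWidth = 0.002)
  expect_equal(length(h$modes), 2L)
  expect_equal(h$modes[1], 1.045, tolerance = 0.002)
  expect_equal(h$modes[2], 1.060, tolerance = 0.002)
})

test_that("stretching thins the wall", {
  wallWidth <- function(k) {
    a <- makeAortaPhantom(scenarioParams("aorta_stretch", n = 64,
                                         stretchStep = k))
    mid <- dim(a@grid)[3] / 2
    row <- a@labels[, dim(a@grid)[2] / 2, mid]
    sum(row > 0L) / 2                       # two wall crossings
  }
  expect_lt(wallWidth(5), wallWidth(0))
})

test_that("density-to-optical conversion follows the decrement relation", {
  beam <- refBeam()
  c0 <- refDeltaPerDensity()
  # 1 g/cm^3 at 25 keV, Z/M 0.55
  expect_equal(c0, 3.65e-7, tolerance = 2e-3)
  ph <- cylinderPhantom(n = 24, nz = 2, drho = 0.02)
  opt <- densityToOptical(ph, beam)
  expect_equal(opt@delta, ph@grid * c0)
  expect_equal(opt@mediumDelta, ph@mediumDensity * c0)
  # homogeneous medium: delta - mediumDelta vanishes
  hom <- cylinderPhantom(n = 16, nz = 2, drho = 0)
  opt0 <- densityToOptical(hom, beam)
  expect_true(all(abs(opt0@delta - opt0@mediumDelta) < 1e-20))
  # linearity in rho
  ph2 <- ph; ph2@grid <- 2 * ph@grid
  expect_equal(densityToOptical(ph2, beam)@delta, 2 * opt@delta)
})

test_that("optical conversion inverts through the densitometry relation", {
  beam <- refBeam()
  ph <- cylinderPhantom(n = 24, nz = 2, drho = 0.013)
  opt <- densityToOptical(ph, beam)
  dvol <- new("DeltaVolume", grid = opt@delta - opt@mediumDelta,
              voxelSize = ph@voxelSize, wavelength = beam@wavelength)
  conv <- densityConversion(beam@wavelength, 0.55, 1, ph@mediumDensity)
  rho <- deltaToDensity(dvol, conv)
  expect_equal(rho@grid, ph@grid, tolerance = 1e-12)
})

test_that("phantom parameter validation", {
  expect_error(scenarioParams(shrinkage = 1.2), "shrinkage")
  expect_error(makeAortaPhantom(scenarioParams("fetus_fresh")), "scenario")
  expect_error(makeFetusPhantom(scenarioParams("aorta_stretch")),
               "scenario")
  expect_error(makeAortaPhantom(
    scenarioParams("aorta_stretch", n = 64, stretchStep = 40,
                   nStretchSteps = 40)), "grid|voxel")
})
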