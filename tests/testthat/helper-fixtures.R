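# Shared fixtures: the reference instrument (25 keV, 10 um gratings,
# third-order Talbot distance, tilted analyser) and small builders used
# across the suite.

refBeam <- function() beamSpec(25, rounding = "3sf")

refG1 <- function() gratingSpec(10, "phase", designEnergy = 18.8,
                                designPhaseShift = pi / 2, extent = 25)

refGeometry <- function() {
  geometrySpec(refBeam(), refG1(),
               gratingSpec(10, "absorption", extent = 25, tilt = 45),
               order = 3L)
}

refDeltaPerDensity <- function() {
  # delta per (g cm^-3) at the 3-s.f. 25 keV wavelength
  phaseCT:::.deltaPerDensity(refBeam()@wavelength, 0.55)
}

# homogeneous cylinder phantom: density contrast drho above saline inside
# radius frac*n/2, nz slices
cylinderPhantom <- function(n = 64, nz = 4, drho = 0.02, frac = 0.6,
                            medium = 1.005, vx = 0.1) {
  x <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(x^2, x^2, "+"))
  cyl <- r <= frac * n / 2
  grid <- array(medium, c(n, n, nz))
  lab <- array(0L, c(n, n, nz))
  for (z in seq_len(nz)) {
    s <- grid[, , z]; s[cyl] <- medium + drho; grid[, , z] <- s
    l <- lab[, , z]; l[cyl] <- 1L; lab[, , z] <- l
  }
  new("DensityPhantom", grid = grid, voxelSize = vx,
      mediumDensity = medium, zOverM = 0.55, labels = lab)
}

uniformAngles <- function(n) seq(0, 180, length.out = n + 1L)[seq_len(n)]

# noiseless project -> reconstruct -> density for a phantom
reconstructDensity <- function(phantom, nAngles = 300,
                               method = "hilbert") {
  beam <- refBeam()
  opt <- densityToOptical(phantom, beam)
  proj <- projectVolume(opt, refGeometry(), 10, uniformAngles(nAngles))
  dvol <- fbpDpc(proj, method = method, wavelength = beam@wavelength)
  conv <- densityConversion(beam@wavelength, phantom@zOverM, 1,
                            phantom@mediumDensity)
  deltaToDensity(dvol, conv)
}

# 6-connected binary erosion, used to take interior ROI masks
erodeMask <- function(m, times = 1L) {
  for (i in seq_len(times)) {
    d <- dim(m); e <- m
    e[2:(d[1] - 1), , ] <- e[2:(d[1] - 1), , ] & m[1:(d[1] - 2), , ] &
      m[3:d[1], , ]
    e[, 2:(d[2] - 1), ] <- e[, 2:(d[2] - 1), ] & m[, 1:(d[2] - 2), ] &
      m[, 3:d[2], ]
    if (d[3] > 2)
      e[, , 2:(d[3] - 1)] <- e[, , 2:(d[3] - 1)] & m[, , 1:(d[3] - 2)] &
        m[, , 3:d[3]]
    m <- e
  }
  m
}

# padded bounding box of a mask
maskBBox <- function(m, pad = 4L) {
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(m))
  b <- array(FALSE, dim(m))
  b[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  b
}

# extract a central-slab sub-phantom (slices are independent in parallel
# geometry, so thin slabs reconstruct identically to the full volume)
centralSlab <- function(phantom, nz = 4L, zCenter = NULL) {
  d <- dim(phantom@grid)
  if (is.null(zCenter)) zCenter <- floor(d[3] / 2)
  zi <- seq.int(zCenter - floor(nz / 2) + 1L, length.out = nz)
  zi <- zi[zi >= 1L & zi <= d[3]]
  new("DensityPhantom", grid = phantom@grid[, , zi, drop = FALSE],
      voxelSize = phantom@voxelSize,
      mediumDensity = phantom@mediumDensity, zOverM = phantom@zOverM,
      labels = phantom@labels[, , zi, drop = FALSE])
}
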