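# Synthetic voxel phantoms: a fetus-like nested-ellipsoid body with organ
# compartments (fresh vs formalin-fixed variants) and a two-layer vessel
# ring under stepwise stretch, plus the conversion from mass density to
# optical properties (refractive-index decrement and linear attenuation).

# delta per (g cm^-3) at wavelength lambda (nm):
#   delta = r_e lambda^2 N_A (Z/M) rho / (2 pi), rho converted g/cm^3 -> g/m^3
.deltaPerDensity <- function(wavelength, zOverM) {
  lam <- wavelength * 1e-9                       # nm -> m
  .r.e.m * lam^2 * .N.A * zOverM * 1e6 / (2 * pi)
}

#' Scenario parameters for the synthetic phantoms
#'
#' Plain parameter list with the defaults that define the study conditions:
#' saline medium 1.005 g cm^-3; fetus compartments body 1.025, brain 1.035,
#' liver 1.055 g cm^-3; formalin fixation shrinks the liver by 35% in
#' volume and raises all tissue densities by 0.015 g cm^-3; the vessel ring
#' has intima 1.045 / externa 1.060 g cm^-3 walls, elongates by 8% per
#' stretch step and accumulates a 0.004 g cm^-3 density rise over the
#' series (mass-conserving thinning).
#'
#' @param scenario "fetus_fresh", "fetus_fixed" or "aorta_stretch"
#' @param n grid side (voxels); the volume is n x n x n
#' @param voxelSize voxel edge (mm)
#' @param mediumDensity saline density rho_w (g cm^-3)
#' @param zOverM Z/M of soft tissue
#' @param organDensities named numeric: body, brain, liver (fresh state) or
#'   intima, externa for the ring
#' @param shrinkage liver volume fraction lost on fixation, in \[0, 1)
#' @param densityIncrement fixation density rise (g cm^-3), or for the ring
#'   the total rise over the whole stretch series
#' @param stretchStep stretch step index (0 = initial) for the ring
#' @param nStretchSteps number of stretch steps in the series
#' @param stretchPerStep fractional elongation per step
#' @param seed random seed (the generators are deterministic geometry; the
#'   seed is carried for provenance and any jittered variants)
#' @return a named list of validated parameters
#' @export
scenarioParams <- function(scenario = c("fetus_fresh", "fetus_fixed",
                                        "aorta_stretch"),
                           n = 128L, voxelSize = 0.1,
                           mediumDensity = 1.005, zOverM = 0.55,
                           organDensities = NULL,
                           shrinkage = 0.35, densityIncrement = NULL,
                           stretchStep = 0L, nStretchSteps = 5L,
                           stretchPerStep = 0.08, seed = 1L) {
  scenario <- match.arg(scenario)
  if (shrinkage < 0 || shrinkage >= 1)
    stop("shrinkage must lie in [0, 1)")
  if (is.null(densityIncrement))
    densityIncrement <- if (scenario == "aorta_stretch") 0.004 else 0.015
  if (densityIncrement < 0) stop("densityIncrement must be >= 0")
  if (is.null(organDensities))
    organDensities <- if (scenario == "aorta_stretch")
      c(intima = 1.045, externa = 1.060)
    else
      c(body = 1.025, brain = 1.035, liver = 1.055)
  if (stretchStep < 0) stop("stretchStep must be >= 0")
  list(scenario = scenario, n = as.integer(n), voxelSize = voxelSize,
       mediumDensity = mediumDensity, zOverM = zOverM,
       organDensities = organDensities, shrinkage = shrinkage,
       densityIncrement = densityIncrement,
       stretchStep = as.integer(stretchStep),
       nStretchSteps = as.integer(nStretchSteps),
       stretchPerStep = stretchPerStep, seed = as.integer(seed))
}

# voxel-centre coordinates (voxel units, centred on the grid)
.axisCoords <- function(n) seq_len(n) - (n + 1) / 2

# ellipsoid membership mask on an n^3 grid; centre/semi in voxel units
.ellipsoidMask <- function(n, centre, semi) {
  x <- .axisCoords(n)
  q1 <- ((x - centre[1]) / semi[1])^2
  q2 <- ((x - centre[2]) / semi[2])^2
  q3 <- ((x - centre[3]) / semi[3])^2
  Q <- outer(outer(q1, q2, "+"), q3, "+")
  Q <= 1
}

#' Fetus-like nested-ellipsoid phantom
#'
#' A body ellipsoid in saline containing a liver and a brain-like
#' compartment.  The fixed-state variant shrinks the liver isotropically
#' about its centroid by the configured volume fraction and raises the
#' density of every tissue compartment by the fixation increment
#' (labels: 1 = body, 2 = liver, 3 = brain).
#'
#' @param params a [scenarioParams()] list with scenario "fetus_fresh" or
#'   "fetus_fixed"
#' @return a [DensityPhantom-class]
#' @examples
#' ph <- makeFetusPhantom(scenarioParams("fetus_fresh", n = 48))
#' @export
makeFetusPhantom <- function(params) {
  if (!params$scenario %in% c("fetus_fresh", "fetus_fixed"))
    stop("params$scenario must be fetus_fresh or fetus_fixed")
  n <- params$n
  dens <- params$organDensities
  if (!all(c("body", "brain", "liver") %in% names(dens)))
    stop("organDensities needs body, brain, liver")
  fixed <- params$scenario == "fetus_fixed"
  inc <- if (fixed) params$densityIncrement else 0

  # geometry in fractions of the grid side; body fits the inscribed circle
  bodyC  <- c(0, 0, 0);              bodySemi  <- c(0.34, 0.26, 0.40) * n
  liverC <- c(0.06, 0.04, -0.10) * n; liverSemi <- c(0.13, 0.115, 0.105) * n
  brainC <- c(-0.02, 0, 0.26) * n;   brainSemi <- c(0.11, 0.10, 0.09) * n
  if (fixed) liverSemi <- liverSemi * (1 - params$shrinkage)^(1 / 3)

  if (any(abs(bodyC) + bodySemi > n / 2))
    stop("body compartment exceeds the grid")

  grid <- array(params$mediumDensity, dim = c(n, n, n))
  labels <- array(0L, dim = c(n, n, n))
  put <- function(mask, lab, rho) {
    grid[mask] <<- rho
    labels[mask] <<- lab
  }
  put(.ellipsoidMask(n, bodyC, bodySemi), 1L, dens[["body"]] + inc)
  put(.ellipsoidMask(n, liverC, liverSemi), 2L, dens[["liver"]] + inc)
  put(.ellipsoidMask(n, brainC, brainSemi), 3L, dens[["brain"]] + inc)

  new("DensityPhantom", grid = grid, voxelSize = params$voxelSize,
      mediumDensity = params$mediumDensity, zOverM = params$zOverM,
      labels = labels)
}

#' Two-layer vessel-ring phantom under stepwise stretch
#'
#' An annular tube (axis vertical) with two concentric wall layers of
#' distinct density (labels: 1 = intima, inner; 2 = externa, outer).  Each
#' stretch step elongates the tube axially and thins the wall such that
#' each layer's mass (density x volume) is conserved while its density
#' rises linearly to the configured total increment at the final step.
#' The tube length is snapped to whole slices and the layer radii are
#' solved against the discrete voxel counts, so the voxelized layer mass
#' is conserved across steps to within one voxel per slice by
#' construction.
#'
#' @param params a [scenarioParams()] list with scenario "aorta_stretch";
#'   `stretchStep` selects the state (0 = initial)
#' @return a [DensityPhantom-class]
#' @export
makeAortaPhantom <- function(params) {
  if (params$scenario != "aorta_stretch")
    stop("params$scenario must be aorta_stretch")
  n <- params$n; vx <- params$voxelSize
  dens <- params$organDensities
  if (!all(c("intima", "externa") %in% names(dens)))
    stop("organDensities needs intima, externa")
  k <- params$stretchStep; K <- params$nStretchSteps
  if (k > K) stop("stretchStep exceeds nStretchSteps")

  r0 <- 0.28 * n * vx                 # lumen radius (mm)
  t1 <- 0.08 * n * vx                 # intima thickness at step 0 (mm)
  t2 <- 0.08 * n * vx                 # externa thickness at step 0 (mm)
  L0 <- 0.5 * n * vx                  # tube length at step 0 (mm)
  r1 <- r0 + t1; r2 <- r1 + t2
  rho1.0 <- dens[["intima"]]; rho2.0 <- dens[["externa"]]
  frac <- if (K > 0) k / K else 0
  rho1 <- rho1.0 + params$densityIncrement * frac
  rho2 <- rho2.0 + params$densityIncrement * frac

  # reference discrete layer volumes at step 0 define the layer masses;
  # a sub-voxel centre offset lifts lattice-radius degeneracies so the
  # voxel count varies in fine steps with the radius
  x <- .axisCoords(n) * vx
  rmap <- sqrt(outer((x - 0.2371 * vx)^2, (x - 0.4113 * vx)^2, "+"))
  nz0 <- round(L0 / vx)
  count <- function(rlo, rhi) sum(rmap >= rlo & rmap < rhi)
  M1 <- rho1.0 * count(r0, r1) * nz0 * vx^3
  M2 <- rho2.0 * count(r1, r2) * nz0 * vx^3

  nzk <- round(L0 * (1 + params$stretchPerStep * k) / vx)
  if (nzk > n) stop("stretched tube exceeds the grid height")
  # total voxel counts that conserve each layer's mass at the new density
  N1 <- round(M1 / (rho1 * vx^3))
  N2 <- round(M2 / (rho2 * vx^3))
  # per-slice membership in radius order outward from the lumen: the first
  # C1 voxels beyond r0 form the intima, the next C2 the externa, so the
  # counts (hence masses) are met exactly while the layers stay annular
  wall <- which(rmap >= r0)
  wall <- wall[order(rmap[wall])]
  C1 <- N1 %/% nzk; C2 <- N2 %/% nzk
  extra1 <- N1 - C1 * nzk; extra2 <- N2 - C2 * nzk
  if (C1 + C2 + 2L > length(wall)) stop("ring exceeds the grid")
  mkSlice <- function(c1, c2) {
    lab <- matrix(0L, n, n)
    lab[wall[seq_len(c1)]] <- 1L
    lab[wall[c1 + seq_len(c2)]] <- 2L
    lab
  }
  r1k <- rmap[wall[C1]]; r2k <- rmap[wall[C1 + C2]]
  if (min(r1k - r0, r2k - r1k) < vx)
    stop("wall thinner than one voxel; reduce stretch or enlarge the grid")

  zi <- seq.int(floor((n - nzk) / 2) + 1L, length.out = nzk)
  grid <- array(params$mediumDensity, dim = c(n, n, n))
  labels <- array(0L, dim = c(n, n, n))
  for (j in seq_along(zi)) {
    labSlice <- mkSlice(C1 + (j <= extra1), C2 + (j <= extra2))
    slice <- matrix(params$mediumDensity, n, n)
    slice[labSlice == 1L] <- rho1
    slice[labSlice == 2L] <- rho2
    grid[, , zi[j]] <- slice
    labels[, , zi[j]] <- labSlice
  }
  new("DensityPhantom", grid = grid, voxelSize = vx,
      mediumDensity = params$mediumDensity, zOverM = params$zOverM,
      labels = labels)
}

#' Convert a density phantom to optical properties
#'
#' delta(rho) = r_e lambda^2 N_A (Z/M) rho / (2 pi) per voxel and a simple
#' linear attenuation mu = muPerDensity x rho.  Attenuation is a single
#' proportionality constant (tissue ~ water): absorption contrast is not
#' the signal here, it only sets the photon statistics.
#'
#' @param phantom a [DensityPhantom-class]
#' @param beam a [BeamSpec-class] (its wavelength drives the conversion)
#' @param muPerDensity linear attenuation per unit density
#'   (mm^-1 per g cm^-3); default 0.05, about water at 25 keV
#' @return an [OpticalVolume-class]
#' @examples
#' ph <- makeFetusPhantom(scenarioParams(n = 32))
#' densityToOptical(ph, beamSpec(25))
#' @export
densityToOptical <- function(phantom, beam, muPerDensity = 0.05) {
  stopifnot(is(phantom, "DensityPhantom"), is(beam, "BeamSpec"))
  if (!is.finite(phantom@zOverM) || phantom@zOverM <= 0)
    stop("phantom has no Z/M value")
  c0 <- .deltaPerDensity(beam@wavelength, phantom@zOverM)
  new("OpticalVolume",
      delta = phantom@grid * c0,
      mu = phantom@grid * muPerDensity,
      wavelength = beam@wavelength, voxelSize = phantom@voxelSize,
      mediumDelta = phantom@mediumDensity * c0)
}
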