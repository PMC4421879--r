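# Forward acquisition model: parallel-beam projection of the optical
# volume into differential-phase / transmission sinograms, and synthesis
# of phase-stepping frame stacks with fringe visibility and Poisson
# photon noise.

#' Project an optical volume into differential-phase sinograms
#'
#' Parallel geometry with a vertical rotation axis; the differential axis
#' is the horizontal detector axis (perpendicular to the grating lines).
#' Per angle the projected decrement t_delta(s, z) is the line integral of
#' delta along the beam; the stepping-curve phase is
#' psi = (2 pi z_T / d2) d t_delta / d s with central finite differences
#' (one-sided at the edges), and the transmission is exp(-integral of mu).
#' psi is positive where delta increases toward +s.
#'
#' @param optical an [OpticalVolume-class]
#' @param geometry a [GeometrySpec-class] (talbotDistance sets the phase
#'   sensitivity)
#' @param g2Pitch analyser grating pitch (um)
#' @param angles projection angles (deg), strictly increasing in \[0, 180)
#' @param relative subtract the medium decrement before projecting, so the
#'   sinograms encode delta - delta_medium (default TRUE: the water cell
#'   makes the medium the phase reference)
#' @return a [ProjectionSet-class]
#' @export
projectVolume <- function(optical, geometry, g2Pitch, angles,
                          relative = TRUE) {
  stopifnot(is(optical, "OpticalVolume"), is(geometry, "GeometrySpec"))
  if (is.unsorted(angles, strictly = TRUE))
    stop("angles must be strictly increasing")
  d <- dim(optical@delta)
  delta <- optical@delta
  if (relative) delta <- delta - optical@mediumDelta
  if (any(abs(delta[c(1, d[1]), , ]) > 0) ||
      any(abs(delta[, c(1, d[2]), ]) > 0))
    warning("object touches the lateral grid edge; ",
            "derivative artefacts expected")
  rad <- angles * pi / 180
  vx <- optical@voxelSize
  tdelta <- array(cpp_project(as.double(delta), as.integer(d), rad, 1.0),
                  dim = c(d[1], d[3], length(angles))) * vx
  tmu <- array(cpp_project(as.double(optical@mu), as.integer(d), rad, 1.0),
               dim = c(d[1], d[3], length(angles))) * vx
  # d/ds with central differences, spacing = pixel (= voxel) size in mm
  ddelta <- .diffAlongS(tdelta, vx)
  scale <- 2 * pi * geometry@talbotDistance / (g2Pitch / 1000)   # mm / mm
  new("ProjectionSet", angles = as.numeric(angles),
      dphase = scale * ddelta, trans = exp(-tmu), pixelSize = vx,
      talbotDistance = geometry@talbotDistance, g2Pitch = g2Pitch)
}

# central differences along the first (detector) axis of an ndet x nz x na
# array; forward/backward at the edges
.diffAlongS <- function(x, h) {
  n <- dim(x)[1]
  out <- x
  out[2:(n - 1), , ] <- (x[3:n, , , drop = FALSE] -
                         x[1:(n - 2), , , drop = FALSE]) / (2 * h)
  out[1, , ] <- (x[2, , ] - x[1, , ]) / h
  out[n, , ] <- (x[n, , ] - x[n - 1, , ]) / h
  out
}

# stepping-curve shape: 1 + V * carrier(phase); sine carrier is cos, the
# triangle carrier is the unit-peak triangle wave with the same fundamental
# phase (Fourier fundamental amplitude 8/pi^2)
.steppingCurve <- function(phase, visibility, profile) {
  carrier <- switch(profile,
    sine = cos(phase),
    triangle = (2 / pi) * asin(cos(phase)),
    stop("profile must be 'sine' or 'triangle'"))
  1 + visibility * carrier
}

#' Synthesize phase-stepping frame stacks
#'
#' Expected counts in frame k (k = 0..N-1):
#' gain x budget x trans x s(2 pi k / N + psi), where s is 1 + V cos for
#' the sine profile or the unit-period triangle wave of the same
#' fundamental phase for the triangle profile.  Photons are Poisson
#' sampled, then the detector gain is applied (so count fluctuations are
#' photon-limited whenever gain > 1).  The reference stack uses trans = 1
#' and psi = 0.  `photonBudget = Inf` gives the noiseless expectation
#' (gain x budget replaced by `noiselessScale`).
#'
#' @param projections a [ProjectionSet-class]
#' @param photonBudget expected photons per pixel per frame; Inf = noiseless
#' @param visibility fringe visibility V in \[0, 1\]
#' @param nSteps phase steps per period (>= 3)
#' @param profile "sine" (default) or "triangle"
#' @param gain counts per detected photon
#' @param seed RNG seed for the Poisson sampling
#' @param noiselessScale mean counts used when photonBudget is Inf
#' @return a [SteppingStack-class]
#' @export
simulateStepping <- function(projections, photonBudget = Inf,
                             visibility = 0.3, nSteps = 5L,
                             profile = c("sine", "triangle"), gain = 1,
                             seed = 1L, noiselessScale = 1000) {
  stopifnot(is(projections, "ProjectionSet"))
  profile <- match.arg(profile)
  if (visibility < 0 || visibility > 1)
    stop("visibility must lie in [0, 1]")
  if (photonBudget < 0) stop("photonBudget must be >= 0")
  nSteps <- as.integer(nSteps)
  if (nSteps < 3L) stop("nSteps must be >= 3")
  d <- dim(projections@dphase)
  noiseless <- !is.finite(photonBudget)
  base <- if (noiseless) noiselessScale else photonBudget
  frames <- array(0, dim = c(d[1], d[2], nSteps, d[3]))
  refs <- array(0, dim = c(d[1], d[2], nSteps, d[3]))
  if (!noiseless) set.seed(seed)
  for (k in seq_len(nSteps)) {
    stepPhase <- 2 * pi * (k - 1) / nSteps
    mean_s <- base * projections@trans *
      .steppingCurve(stepPhase + projections@dphase, visibility, profile)
    mean_r <- array(base * .steppingCurve(stepPhase, visibility, profile),
                    dim = d)
    if (noiseless) {
      frames[, , k, ] <- gain * mean_s
      refs[, , k, ] <- gain * mean_r
    } else {
      frames[, , k, ] <- gain * array(rpois(length(mean_s), mean_s), dim = d)
      refs[, , k, ] <- gain * array(rpois(length(mean_r), mean_r), dim = d)
    }
  }
  new("SteppingStack", frames = frames, reference = refs,
      angles = projections@angles, photonBudget = photonBudget,
      visibility = visibility, gain = gain, profile = profile,
      pixelSize = projections@pixelSize,
      talbotDistance = projections@talbotDistance,
      g2Pitch = projections@g2Pitch)
}

#' Photon budget per detector pixel
#'
#' fluxDensity x (effective pixel area in mm^2) x exposure x system
#' transmission: the expected number of detected photons per pixel per
#' frame.
#'
#' @param beam a [BeamSpec-class]
#' @param detector a [DetectorSpec-class]
#' @param exposure exposure time (s)
#' @param systemTransmission combined transmission of water cell, windows
#'   and gratings, in \[0, 1\]
#' @return expected photons per pixel
#' @examples
#' fluxToBudget(beamSpec(25), detectorSpec(effectivePixel = 15.5), 0.1, 1.0)
#' @export
fluxToBudget <- function(beam, detector, exposure, systemTransmission = 1) {
  stopifnot(is(beam, "BeamSpec"), is(detector, "DetectorSpec"))
  if (exposure < 0 || systemTransmission < 0)
    stop("exposure and systemTransmission must be >= 0")
  ep <- effectiveGeometry(detector)$effectivePixel / 1000   # um -> mm
  beam@fluxDensity * ep^2 * exposure * systemTransmission
}
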