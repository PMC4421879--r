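#' @import methods
#' @importFrom stats rpois sd fft mvfft nextn
#' @importFrom utils write.csv
#' @useDynLib phaseCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Physical constants, kept in one place.  hc in keV nm; r_e in m; N_A per mol.
.hc.keV.nm   <- 1.23984
.r.e.m       <- 2.8179e-15
.N.A         <- 6.022e23

#' BeamSpec: monochromatic beam description
#'
#' Photon energy, derived wavelength and flux density at the sample position
#' of a quasi-parallel synchrotron beam.
#'
#' @slot energy photon energy (keV)
#' @slot wavelength wavelength (nm), hc/E
#' @slot fluxDensity photons s^-1 mm^-2 at the sample plane
#' @export
setClass("BeamSpec",
  representation(energy = "numeric", wavelength = "numeric",
                 fluxDensity = "numeric"),
  prototype(fluxDensity = 1.2e8),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) != 1L || !is.finite(object@energy) ||
        object@energy <= 0)
      msg <- c(msg, "energy must be a positive scalar (keV)")
    if (length(object@wavelength) == 1L && is.finite(object@wavelength)) {
      ref <- .hc.keV.nm / object@energy
      if (abs(object@wavelength - ref) > 0.05 * ref)
        msg <- c(msg, "wavelength inconsistent with hc/energy")
    }
    if (any(object@fluxDensity < 0))
      msg <- c(msg, "fluxDensity must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' GratingSpec: a phase or absorption grating
#'
#' @slot pitch grating pitch d (um)
#' @slot kind "phase" or "absorption"
#' @slot designEnergy energy at which designPhaseShift holds (keV)
#' @slot designPhaseShift phase shift imprinted at designEnergy (rad)
#' @slot extent side length of the patterned area (mm)
#' @slot tilt inclination toward the optical axis (deg); 0 = untilted
#' @export
setClass("GratingSpec",
  representation(pitch = "numeric", kind = "character",
                 designEnergy = "numeric", designPhaseShift = "numeric",
                 extent = "numeric", tilt = "numeric"),
  prototype(kind = "phase", designEnergy = NA_real_,
            designPhaseShift = NA_real_, extent = 25, tilt = 0),
  validity = function(object) {
    msg <- character()
    if (object@pitch <= 0) msg <- c(msg, "pitch must be > 0")
    if (!object@kind %in% c("phase", "absorption"))
      msg <- c(msg, "kind must be 'phase' or 'absorption'")
    if (is.finite(object@tilt) && (object@tilt < 0 || object@tilt > 90))
      msg <- c(msg, "tilt must lie in [0, 90] degrees")
    if (is.finite(object@designPhaseShift) &&
        (object@designPhaseShift <= 0 || object@designPhaseShift > pi))
      msg <- c(msg, "designPhaseShift must lie in (0, pi]")
    if (length(msg)) msg else TRUE
  })

#' GeometrySpec: interferometer geometry
#'
#' Talbot order and distance plus the tilted-G2 quantities: the half-span
#' delta z of the G1-G2 distance across the inclined analyser grating and
#' the corresponding virtual wavelength shift over the full span.
#'
#' @slot talbotOrder odd positive Talbot order p
#' @slot talbotDistance z_Talbot (mm)
#' @slot deltaZ half-span of the G1-G2 distance (mm)
#' @slot deltaLambda virtual wavelength shift over -deltaZ..+deltaZ (nm)
#' @export
setClass("GeometrySpec",
  representation(talbotOrder = "integer", talbotDistance = "numeric",
                 deltaZ = "numeric", deltaLambda = "numeric"),
  prototype(deltaZ = 0, deltaLambda = 0),
  validity = function(object) {
    msg <- character()
    p <- object@talbotOrder
    if (length(p) != 1L || is.na(p) || p < 1L || p %% 2L == 0L)
      msg <- c(msg, "talbotOrder must be an odd positive integer")
    if (object@talbotDistance <= 0)
      msg <- c(msg, "talbotDistance must be > 0")
    if (object@deltaZ < 0) msg <- c(msg, "deltaZ must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' DetectorSpec: lens-coupled imaging detector
#'
#' @slot nativePixel camera pixel size (um)
#' @slot magnification lens (de)magnification factor
#' @slot nPixels pixels per side
#' @slot effectivePixel object-plane pixel (um); NA means nativePixel/magnification
#' @slot readout frame readout time (s)
#' @slot gain A/D counts per detected X-ray photon
#' @export
setClass("DetectorSpec",
  representation(nativePixel = "numeric", magnification = "numeric",
                 nPixels = "integer", effectivePixel = "numeric",
                 readout = "numeric", gain = "numeric"),
  prototype(effectivePixel = NA_real_, readout = 0.05, gain = 1),
  validity = function(object) {
    msg <- character()
    if (object@nativePixel <= 0) msg <- c(msg, "nativePixel must be > 0")
    if (object@magnification <= 0) msg <- c(msg, "magnification must be > 0")
    if (object@nPixels < 1L) msg <- c(msg, "nPixels must be >= 1")
    if (object@readout < 0) msg <- c(msg, "readout must be >= 0")
    if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ScanProtocol: on-the-fly tomographic acquisition parameters
#'
#' @slot nProjections number of projections Y over 180 degrees
#' @slot nSteps phase steps per projection (>= 3)
#' @slot exposure exposure time per frame (s)
#' @slot readout camera readout time per frame (s)
#' @slot settle analyser-grating step settle delay (s)
#' @slot pulsesPer180 motor pulses for a 180 degree rotation
#' @slot pulseResolution degrees per motor pulse
#' @slot flatInterval rotation interval between flat-field blocks (deg)
#' @slot flatFrames frames per flat-field block
#' @export
setClass("ScanProtocol",
  representation(nProjections = "integer", nSteps = "integer",
                 exposure = "numeric", readout = "numeric",
                 settle = "numeric", pulsesPer180 = "integer",
                 pulseResolution = "numeric", flatInterval = "numeric",
                 flatFrames = "integer"),
  prototype(nSteps = 5L, readout = 0.05, settle = 0.03,
            pulsesPer180 = 90000L, pulseResolution = 0.002,
            flatInterval = 36, flatFrames = 5L),
  validity = function(object) {
    msg <- character()
    if (object@nProjections < 0L)
      msg <- c(msg, "nProjections must be >= 0")
    if (object@nSteps < 3L) msg <- c(msg, "nSteps must be >= 3")
    if (any(c(object@exposure, object@readout, object@settle) < 0))
      msg <- c(msg, "times must be >= 0")
    if (object@pulsesPer180 < 1L)
      msg <- c(msg, "pulsesPer180 must be >= 1")
    if (abs(object@pulsesPer180 * object@pulseResolution - 180) > 1e-6)
      msg <- c(msg, "pulsesPer180 * pulseResolution must equal 180 degrees")
    if (object@flatInterval <= 0)
      msg <- c(msg, "flatInterval must be > 0")
    if (object@flatFrames < 0L) msg <- c(msg, "flatFrames must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Schedule: derived trigger timeline
#'
#' Ordered event list (time, kind, projection, step) with summary scalars.
#' Kinds are "trigger", "g2_step", "flat_block_start", "flat_frame".
#'
#' @slot events data.frame(time_s, kind, proj, step)
#' @slot totalTime last event end time (s)
#' @slot rotationSpeed pulses per second (integer-truncated)
#' @export
setClass("Schedule",
  representation(events = "data.frame", totalTime = "numeric",
                 rotationSpeed = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    need <- c("time_s", "kind", "proj", "step")
    if (!all(need %in% names(ev)))
      msg <- c(msg, "events must have columns time_s, kind, proj, step")
    else if (nrow(ev) > 1L && any(diff(ev$time_s) < -1e-9))
      msg <- c(msg, "event times must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' DensityPhantom: voxelized mass-density phantom
#'
#' A 3-D grid of mass density (g cm^-3) immersed in a homogeneous medium
#' (normal saline), with an integer compartment label map.
#'
#' @slot grid 3-D numeric array, mass density (g cm^-3)
#' @slot voxelSize isotropic voxel edge (mm)
#' @slot mediumDensity density of the surrounding saline rho_w (g cm^-3)
#' @slot zOverM electrons-per-molecular-weight ratio Z/M of the tissue
#' @slot labels integer array, same shape; 0 = medium
#' @export
setClass("DensityPhantom",
  representation(grid = "array", voxelSize = "numeric",
                 mediumDensity = "numeric", zOverM = "numeric",
                 labels = "array"),
  prototype(zOverM = 0.55),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3L)
      msg <- c(msg, "grid must be a 3-D array")
    if (any(object@grid <= 0)) msg <- c(msg, "densities must be > 0")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
    if (!identical(dim(object@grid), dim(object@labels)))
      msg <- c(msg, "grid and labels must share a shape")
    if (length(msg)) msg else TRUE
  })

#' OpticalVolume: refractive-index decrement and attenuation volume
#'
#' @slot delta 3-D array of the decrement delta (dimensionless)
#' @slot mu 3-D array of linear attenuation (mm^-1)
#' @slot wavelength nm
#' @slot voxelSize mm
#' @slot mediumDelta decrement of the surrounding medium (reference)
#' @export
setClass("OpticalVolume",
  representation(delta = "array", mu = "array", wavelength = "numeric",
                 voxelSize = "numeric", mediumDelta = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@delta), dim(object@mu)))
      msg <- c(msg, "delta and mu must share a shape")
    if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ProjectionSet: per-angle differential-phase and transmission maps
#'
#' Sinogram container: stepping-curve phase psi (rad) and transmission per
#' detector pixel (s = differential axis, z = rows) per rotation angle.
#'
#' @slot angles degrees, strictly increasing, in [0, 180)
#' @slot dphase array ndet x nz x nangles (rad)
#' @slot trans array ndet x nz x nangles, in (0, 1]
#' @slot pixelSize detector pixel in the object plane (mm)
#' @slot talbotDistance G1-G2 distance used for the phase scaling (mm)
#' @slot g2Pitch analyser grating pitch (um)
#' @export
setClass("ProjectionSet",
  representation(angles = "numeric", dphase = "array", trans = "array",
                 pixelSize = "numeric", talbotDistance = "numeric",
                 g2Pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@angles, strictly = TRUE))
      msg <- c(msg, "angles must be strictly increasing")
    if (!identical(dim(object@dphase), dim(object@trans)))
      msg <- c(msg, "dphase and trans must share a shape")
    if (length(dim(object@dphase)) != 3L ||
        dim(object@dphase)[3] != length(object@angles))
      msg <- c(msg, "third dimension must match the angle list")
    if (!all(is.finite(object@dphase)))
      msg <- c(msg, "dphase must be finite")
    if (length(msg)) msg else TRUE
  })

#' SteppingStack: simulated phase-stepping frames
#'
#' Per angle, nSteps count frames plus a reference (no sample) stack.
#' Frames are 4-D: ndet x nz x nSteps x nangles.
#'
#' @slot frames counts with the sample in the beam
#' @slot reference counts without the sample
#' @slot angles degrees
#' @slot photonBudget expected photons per pixel per frame (Inf = noiseless)
#' @slot visibility fringe visibility used in the simulation
#' @slot gain counts per photon
#' @slot profile "sine" or "triangle"
#' @slot pixelSize mm
#' @slot talbotDistance mm
#' @slot g2Pitch um
#' @export
setClass("SteppingStack",
  representation(frames = "array", reference = "array", angles = "numeric",
                 photonBudget = "numeric", visibility = "numeric",
                 gain = "numeric", profile = "character",
                 pixelSize = "numeric", talbotDistance = "numeric",
                 g2Pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 4L)
      msg <- c(msg, "frames must be ndet x nz x nSteps x nangles")
    if (dim(object@frames)[3] < 3L)
      msg <- c(msg, "at least 3 phase steps are required")
    if (any(object@frames < 0)) msg <- c(msg, "counts must be >= 0")
    if (object@visibility < 0 || object@visibility > 1)
      msg <- c(msg, "visibility must lie in [0, 1]")
    if (!object@profile %in% c("sine", "triangle"))
      msg <- c(msg, "profile must be 'sine' or 'triangle'")
    if (length(msg)) msg else TRUE
  })

#' RetrievedProjectionSet: flat-corrected retrieval results
#'
#' Transmission, wrapped differential phase and visibility ratio per pixel
#' per angle, after flat-field correction.
#'
#' @slot trans I0_sample / I0_reference
#' @slot dphase psi_sample - psi_reference wrapped to (-pi, pi] (rad)
#' @slot visRatio V_sample / V_reference (dark-field channel)
#' @slot angles degrees
#' @slot pixelSize mm
#' @slot talbotDistance mm
#' @slot g2Pitch um
#' @export
setClass("RetrievedProjectionSet",
  representation(trans = "array", dphase = "array", visRatio = "array",
                 angles = "numeric", pixelSize = "numeric",
                 talbotDistance = "numeric", g2Pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@dphase)
    if (!identical(d, dim(object@trans)) ||
        !identical(d, dim(object@visRatio)))
      msg <- c(msg, "trans, dphase, visRatio must share a shape")
    rng <- range(object@dphase[is.finite(object@dphase)])
    if (length(rng) == 2L && (rng[1] <= -pi - 1e-9 || rng[2] > pi + 1e-9))
      msg <- c(msg, "dphase must be wrapped to (-pi, pi]")
    if (length(msg)) msg else TRUE
  })

#' DeltaVolume: reconstructed refractive-index-decrement difference
#'
#' Voxel values are the decrement relative to the surrounding medium
#' (delta - delta_medium); the background mean is ~0 by construction.
#'
#' @slot grid 3-D array of delta differences (dimensionless)
#' @slot voxelSize mm
#' @slot wavelength nm
#' @export
setClass("DeltaVolume",
  representation(grid = "array", voxelSize = "numeric",
                 wavelength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3L)
      msg <- c(msg, "grid must be a 3-D array")
    if (!all(is.finite(object@grid)))
      msg <- c(msg, "grid must be finite")
    if (length(msg)) msg else TRUE
  })

#' DensityConversion: decrement-to-density conversion parameters
#'
#' Parameters of the linear relation between the refractive-index decrement
#' and mass density for soft tissue, plus the detector calibration factor
#' applied to measured decrement differences.
#'
#' @slot wavelength nm
#' @slot zOverM electrons per molecular weight (0.55 for soft tissue)
#' @slot calibration multiplicative factor applied to the measured decrement
#' @slot mediumDensity rho_w of the saline (g cm^-3)
#' @export
setClass("DensityConversion",
  representation(wavelength = "numeric", zOverM = "numeric",
                 calibration = "numeric", mediumDensity = "numeric"),
  prototype(zOverM = 0.55, calibration = 1.45, mediumDensity = 1.005),
  validity = function(object) {
    msg <- character()
    if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
    if (object@zOverM <= 0) msg <- c(msg, "zOverM must be > 0")
    if (object@calibration <= 0) msg <- c(msg, "calibration must be > 0")
    if (length(msg)) msg else TRUE
  })

#' DensityVolume: reconstructed mass-density map
#'
#' @slot grid 3-D array of mass density (g cm^-3)
#' @slot voxelSize mm
#' @slot mediumDensity rho_w used in the conversion (g cm^-3)
#' @export
setClass("DensityVolume",
  representation(grid = "array", voxelSize = "numeric",
                 mediumDensity = "numeric"),
  validity = function(object) {
    if (length(dim(object@grid)) != 3L) "grid must be a 3-D array" else TRUE
  })
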