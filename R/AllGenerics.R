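#' Accessor generics
#'
#' Small accessor family shared by the volume-like classes: `voxelGrid()`
#' returns the raw 3-D array, `voxelSize()` the voxel edge length in mm,
#' `angles()` the rotation angles of a projection container.
#'
#' @param object a phaseCT S4 object
#' @return the slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(object) standardGeneric("voxelGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("mediumDensity", function(object) standardGeneric("mediumDensity"))

#' @rdname accessors
#' @export
setMethod("voxelGrid", "DensityPhantom", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("voxelGrid", "DeltaVolume", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("voxelGrid", "DensityVolume", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityPhantom", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "OpticalVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DeltaVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("angles", "ProjectionSet", function(object) object@angles)
#' @rdname accessors
#' @export
setMethod("angles", "SteppingStack", function(object) object@angles)
#' @rdname accessors
#' @export
setMethod("angles", "RetrievedProjectionSet", function(object) object@angles)
#' @rdname accessors
#' @export
setMethod("labelMap", "DensityPhantom", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("mediumDensity", "DensityPhantom",
          function(object) object@mediumDensity)
#' @rdname accessors
#' @export
setMethod("mediumDensity", "DensityVolume",
          function(object) object@mediumDensity)

.dim3 <- function(x) paste(dim(x), collapse = " x ")

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf("BeamSpec: %.4g keV (lambda = %.4g nm), %.3g ph/s/mm^2\n",
              object@energy, object@wavelength, object@fluxDensity))
})

setMethod("show", "GratingSpec", function(object) {
  cat(sprintf("GratingSpec (%s): pitch %.3g um, extent %.3g mm, tilt %.3g deg\n",
              object@kind, object@pitch, object@extent, object@tilt))
})

setMethod("show", "GeometrySpec", function(object) {
  cat(sprintf(
    "GeometrySpec: order %d, z_Talbot %.4g mm, dz %.4g mm, dlambda %.3g nm\n",
    object@talbotOrder, object@talbotDistance, object@deltaZ,
    object@deltaLambda))
})

setMethod("show", "ScanProtocol", function(object) {
  cat(sprintf(
    "ScanProtocol: %d projections x %d steps, %.3g s exposure (+%.3g s readout, +%.3g s settle)\n",
    object@nProjections, object@nSteps, object@exposure, object@readout,
    object@settle))
  cat(sprintf("  flats every %.3g deg (%d frames); %d pulses per 180 deg\n",
              object@flatInterval, object@flatFrames, object@pulsesPer180))
})

setMethod("show", "Schedule", function(object) {
  cat(sprintf("Schedule: %d events, total %.4g s, %d pulses/s\n",
              nrow(object@events), object@totalTime,
              as.integer(object@rotationSpeed)))
})

setMethod("show", "DensityPhantom", function(object) {
  cat(sprintf(
    "DensityPhantom: %s voxels @ %.3g mm, medium %.4g g/cm^3, %d compartments\n",
    .dim3(object@grid), object@voxelSize, object@mediumDensity,
    length(setdiff(unique(as.vector(object@labels)), 0L))))
})

setMethod("show", "OpticalVolume", function(object) {
  cat(sprintf("OpticalVolume: %s voxels, lambda %.4g nm, delta in [%.3g, %.3g]\n",
              .dim3(object@delta), object@wavelength,
              min(object@delta), max(object@delta)))
})

setMethod("show", "ProjectionSet", function(object) {
  cat(sprintf("ProjectionSet: %d angles, %s sinogram, pixel %.3g mm\n",
              length(object@angles), .dim3(object@dphase), object@pixelSize))
})

setMethod("show", "SteppingStack", function(object) {
  cat(sprintf(
    "SteppingStack: %d angles x %d steps (%s profile), budget %.4g ph, V = %.3g\n",
    length(object@angles), dim(object@frames)[3], object@profile,
    object@photonBudget, object@visibility))
})

setMethod("show", "RetrievedProjectionSet", function(object) {
  cat(sprintf("RetrievedProjectionSet: %d angles, %s maps\n",
              length(object@angles), .dim3(object@dphase)))
})

setMethod("show", "DeltaVolume", function(object) {
  cat(sprintf("DeltaVolume: %s voxels @ %.3g mm, lambda %.4g nm\n",
              .dim3(object@grid), object@voxelSize, object@wavelength))
})

setMethod("show", "DensityVolume", function(object) {
  cat(sprintf("DensityVolume: %s voxels @ %.3g mm, medium %.4g g/cm^3\n",
              .dim3(object@grid), object@voxelSize, object@mediumDensity))
})

setMethod("show", "DensityConversion", function(object) {
  cat(sprintf(
    "DensityConversion: lambda %.4g nm, Z/M %.3g, calibration %.3g, rho_w %.4g\n",
    object@wavelength, object@zOverM, object@calibration,
    object@mediumDensity))
})
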