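# Closed-form instrument-design calculations for a two-grating Talbot
# interferometer: wavelengths, fractional Talbot distances, tilted-analyser
# geometry and achromaticity, grating phase shift vs energy, detector
# geometry and Beer-Lambert transmission budgets.

#' Construct a BeamSpec
#'
#' @param energy photon energy (keV)
#' @param fluxDensity photons s^-1 mm^-2 at the sample (default the
#'   bending-magnet value 1.2e8)
#' @param rounding wavelength rounding convention, `"full"` (default) or
#'   `"3sf"` (3 significant figures, the convention under which the printed
#'   instrument numbers reproduce)
#' @return a [BeamSpec-class] object
#' @examples
#' beamSpec(25)
#' @export
beamSpec <- function(energy, fluxDensity = 1.2e8, rounding = c("full", "3sf")) {
  rounding <- match.arg(rounding)
  new("BeamSpec", energy = energy,
      wavelength = energyToWavelength(energy, rounding),
      fluxDensity = fluxDensity)
}

#' Construct a GratingSpec
#'
#' @param pitch grating pitch d (um)
#' @param kind "phase" or "absorption"
#' @param designEnergy energy at which `designPhaseShift` holds (keV)
#' @param designPhaseShift imprinted phase shift at `designEnergy` (rad)
#' @param extent patterned side length (mm)
#' @param tilt inclination toward the optical axis (deg)
#' @return a [GratingSpec-class] object
#' @export
gratingSpec <- function(pitch, kind = c("phase", "absorption"),
                        designEnergy = NA_real_,
                        designPhaseShift = NA_real_,
                        extent = 25, tilt = 0) {
  kind <- match.arg(kind)
  new("GratingSpec", pitch = pitch, kind = kind,
      designEnergy = designEnergy, designPhaseShift = designPhaseShift,
      extent = extent, tilt = tilt)
}

#' Construct a DetectorSpec
#'
#' @param nativePixel camera pixel (um)
#' @param magnification lens (de)magnification factor
#' @param nPixels pixels per side
#' @param effectivePixel optional object-plane pixel override (um); the
#'   default `NA` means `nativePixel / magnification`
#' @param readout frame readout time (s)
#' @param gain A/D counts per detected photon
#' @return a [DetectorSpec-class] object
#' @export
detectorSpec <- function(nativePixel = 6.5, magnification = 0.425,
                         nPixels = 2048, effectivePixel = NA_real_,
                         readout = 0.05, gain = 1) {
  new("DetectorSpec", nativePixel = nativePixel,
      magnification = magnification, nPixels = as.integer(nPixels),
      effectivePixel = effectivePixel, readout = readout, gain = gain)
}

#' Photon energy to wavelength
#'
#' lambda = hc / E with hc = 1.23984 keV nm.  The `"3sf"` mode rounds the
#' result to 3 significant figures; the closed-form instrument numbers are
#' quoted under that convention.
#'
#' @param energy photon energy (keV), positive
#' @param rounding `"full"` (default) or `"3sf"`
#' @return wavelength (nm)
#' @examples
#' energyToWavelength(25, "3sf")   # 0.0496
#' @export
energyToWavelength <- function(energy, rounding = c("full", "3sf")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energy must be positive (keV)")
  lambda <- .hc.keV.nm / energy
  if (rounding == "3sf") lambda <- signif(lambda, 3) else lambda
}

#' Fractional Talbot distance of a phase grating
#'
#' z_Talbot = p d^2 / (2 lambda) for odd order p, the distance at which a
#' pi/2 phase grating forms an intensity self-image.
#'
#' @param pitch grating pitch d (um)
#' @param wavelength lambda (nm)
#' @param order odd positive Talbot order p
#' @return distance (mm)
#' @examples
#' talbotDistance(10, energyToWavelength(25, "3sf"), 3)   # ~3024 mm
#' @export
talbotDistance <- function(pitch, wavelength, order = 3L) {
  if (length(order) != 1L || !is.finite(order) || order < 1 ||
      order %% 2 == 0)
    stop("order must be an odd positive integer")
  if (pitch <= 0 || wavelength <= 0)
    stop("pitch and wavelength must be positive")
  # d in um, lambda in nm: p * d^2 / (2 lambda) comes out directly in mm
  order * pitch^2 / (2 * wavelength)
}

#' Half-span of the G1-G2 distance across a tilted analyser grating
#'
#' When the analyser grating of side `extent` is inclined by `tilt` toward
#' the optical axis with its centre at z_Talbot, the G1-G2 distance varies
#' by +/- (extent/2) sin(tilt) between the top and bottom of the field.
#'
#' @param extent grating side length (mm)
#' @param tilt inclination angle (deg), in \[0, 90\]
#' @return half-span delta z (mm)
#' @examples
#' tiltSpan(25, 45)   # 8.84 mm
#' @export
tiltSpan <- function(extent, tilt) {
  if (extent < 0) stop("extent must be >= 0")
  if (tilt < 0 || tilt > 90) stop("tilt must lie in [0, 90] degrees")
  (extent / 2) * sin(tilt * pi / 180)
}

#' Virtual wavelength shift across a tilted analyser grating
#'
#' The Talbot distance is proportional to 1/lambda, so a span z_Talbot
#' +/- delta z is equivalent to a virtual wavelength span with full-range
#' relative shift 2 delta z / z_Talbot.
#'
#' @param deltaZ half-span of the G1-G2 distance (mm)
#' @param talbotDistance z_Talbot (mm)
#' @param wavelength lambda (nm); may be omitted for the relative shift only
#' @return list with `relativeShift` (dimensionless, full span) and
#'   `deltaLambda` (nm, `NA` if wavelength missing)
#' @examples
#' achromaticShift(8.84, 3024, 0.0496)
#' @export
achromaticShift <- function(deltaZ, talbotDistance, wavelength = NA_real_) {
  if (talbotDistance <= 0) stop("talbotDistance must be > 0")
  if (deltaZ < 0) stop("deltaZ must be >= 0")
  rel <- 2 * deltaZ / talbotDistance
  list(relativeShift = rel, deltaLambda = rel * wavelength)
}

#' Grating phase shift at an arbitrary energy
#'
#' Scales the design phase shift by designEnergy/energy (the decrement of
#' the grating material scales as lambda^2 while the imprinted phase is
#' delta t 2 pi / lambda, hence phi proportional to 1/E).  Valid away from
#' absorption edges of the grating material; this is a model assumption,
#' not a tabulated delta(E).
#'
#' @param grating a [GratingSpec-class] with design energy and phase set
#' @param energy query energy (keV)
#' @return phase shift (rad)
#' @examples
#' g1 <- gratingSpec(10, "phase", designEnergy = 18.8, designPhaseShift = pi/2)
#' gratingPhaseShift(g1, 25)
#' @export
gratingPhaseShift <- function(grating, energy) {
  stopifnot(is(grating, "GratingSpec"))
  if (any(energy <= 0)) stop("energy must be positive")
  if (!is.finite(grating@designEnergy) ||
      !is.finite(grating@designPhaseShift))
    stop("grating has no design energy / phase shift")
  grating@designPhaseShift * grating@designEnergy / energy
}

#' Effective detector geometry
#'
#' Object-plane pixel size (native pixel over lens magnification, unless an
#' explicit override is stored in the spec) and the resulting field of view.
#'
#' @param detector a [DetectorSpec-class]
#' @return list with `effectivePixel` (um), `fov` (mm, full precision) and
#'   `fovReported` (mm, rounded to 0.1 mm as conventionally quoted)
#' @examples
#' effectiveGeometry(detectorSpec(effectivePixel = 15.5))
#' @export
effectiveGeometry <- function(detector) {
  stopifnot(is(detector, "DetectorSpec"))
  if (detector@magnification == 0) stop("magnification must be non-zero")
  ep <- if (is.finite(detector@effectivePixel)) detector@effectivePixel
        else detector@nativePixel / detector@magnification
  fov <- detector@nPixels * ep / 1000   # um -> mm
  list(effectivePixel = ep, fov = fov, fovReported = round(fov, 1))
}

#' Beer-Lambert transmission through a stack of absorbers
#'
#' exp(-sum (mu/rho) rho t) over the supplied entries.  Mass attenuation
#' coefficients are caller-supplied (no embedded database).
#'
#' @param entries data.frame with columns `massAtten` (cm^2 g^-1),
#'   `density` (g cm^-3) and `path` (mm); zero rows means no absorber
#' @return transmitted fraction in (0, 1]
#' @examples
#' water <- data.frame(massAtten = 0.5075, density = 1.0, path = 25)
#' beerLambertTransmission(water)   # ~0.281 at 25 keV
#' @export
beerLambertTransmission <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0L) return(1.0)
  need <- c("massAtten", "density", "path")
  if (!all(need %in% names(entries)))
    stop("entries needs columns massAtten, density, path")
  if (any(entries$path < 0)) stop("path lengths must be >= 0")
  if (any(entries$massAtten < 0) || any(entries$density < 0))
    stop("coefficients and densities must be >= 0")
  # path mm -> cm to match cm^2/g * g/cm^3
  exp(-sum(entries$massAtten * entries$density * entries$path / 10))
}

#' Assemble the interferometer geometry from beam and gratings
#'
#' Convenience constructor computing z_Talbot, the tilted-G2 half-span and
#' the virtual wavelength shift in one step.
#'
#' @param beam a [BeamSpec-class]
#' @param g1 phase grating ([GratingSpec-class])
#' @param g2 analyser grating ([GratingSpec-class]); its `tilt` and `extent`
#'   set the achromaticity numbers
#' @param order odd Talbot order
#' @return a [GeometrySpec-class]
#' @export
geometrySpec <- function(beam, g1, g2, order = 3L) {
  zt <- talbotDistance(g1@pitch, beam@wavelength, order)
  dz <- tiltSpan(g2@extent, g2@tilt)
  sh <- achromaticShift(dz, zt, beam@wavelength)
  new("GeometrySpec", talbotOrder = as.integer(order), talbotDistance = zt,
      deltaZ = dz, deltaLambda = sh$deltaLambda)
}
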