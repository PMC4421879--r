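# Differential-phase filtered backprojection: slice-by-slice parallel-beam
# FBP where the ramp filter is replaced by a Hilbert-type kernel
# (frequency response sgn(f)/(2i) up to normalization) because each
# projection is the transverse derivative of the projected phase.  An
# integrate-then-ramp route is provided as an internal cross-check.

# Filter the detector axis (rows) of an ndet x m matrix.  The discrete
# filters are the DFTs of the band-limited spatial kernels (the Ram-Lak
# kernel for the ramp; its analogue for derivative data, i.e. the inverse
# transform of sgn(f)/(2 pi i) truncated at Nyquist), not direct samples
# of |f| / sgn(f): frequency-sampled filters misweight the lowest
# frequencies and bias the reconstructed interior.
.filterRows <- function(q, pixel, kernel = c("hilbert", "ramp"),
                        window = TRUE) {
  kernel <- match.arg(kernel)
  ndet <- nrow(q)
  npad <- nextn(2L * ndet, 2)
  k <- c(0:(npad / 2), -(npad / 2 - 1):-1)     # circular sample offsets
  h <- numeric(npad)
  odd <- k %% 2 != 0
  if (kernel == "ramp") {
    h[1] <- 1 / (4 * pixel^2)
    h[odd] <- -1 / (pi^2 * k[odd]^2 * pixel^2)
  } else {
    h[odd] <- 1 / (pi^2 * k[odd] * pixel)
  }
  H <- fft(h)
  if (window) {
    j <- 0:(npad - 1)
    f <- ifelse(j <= npad / 2, j, j - npad) / (npad * pixel)
    H <- H * 0.5 * (1 + cos(pi * f * 2 * pixel))   # Hann at Nyquist
  }
  qp <- rbind(q, matrix(0, npad - ndet, ncol(q)))
  filt <- Re(mvfft(mvfft(qp) * H, inverse = TRUE) / npad) * pixel
  filt[seq_len(ndet), , drop = FALSE]
}

#' Differential-phase filtered backprojection
#'
#' Reconstructs the refractive-index-decrement difference volume from a
#' set of differential-phase sinograms.  The stepping phase is scaled back
#' to the transverse derivative of the projected decrement by
#' d2 / (2 pi z_T); the Hilbert kernel then performs filtered
#' backprojection of derivative data directly, returning delta - delta_medium.
#' The kernel is apodized with a Hann window at the Nyquist frequency and
#' rows are zero-padded to the next power of two.  `method =
#' "integrate-ramp"` instead integrates psi along the detector axis
#' (cumulative sum) and applies a conventional ramp filter; the two routes
#' agree to within discretization error and serve as mutual checks.
#'
#' @param sinograms a [RetrievedProjectionSet-class] or
#'   [ProjectionSet-class] (wrapped phase in rad per angle)
#' @param method "hilbert" (default) or "integrate-ramp"
#' @param window apply the Hann apodization (default TRUE)
#' @param wavelength carried into the output volume metadata (nm)
#' @return a [DeltaVolume-class]
#' @export
fbpDpc <- function(sinograms, method = c("hilbert", "integrate-ramp"),
                   window = TRUE, wavelength = NA_real_) {
  method <- match.arg(method)
  if (!(is(sinograms, "RetrievedProjectionSet") ||
        is(sinograms, "ProjectionSet")))
    stop("sinograms must be a RetrievedProjectionSet or ProjectionSet")
  ang <- sinograms@angles
  if (length(ang) < 3L) stop("at least 3 angles are required")
  sp <- diff(ang)
  if (max(sp) > 2 * min(sp) + 1e-9)
    warning("angles are markedly non-uniform; FBP assumes uniform coverage")
  psi <- sinograms@dphase
  psi[!is.finite(psi)] <- 0
  d <- dim(psi)
  pixel <- sinograms@pixelSize
  # stepping phase -> d t_delta / d s (dimensionless)
  q <- psi * (sinograms@g2Pitch / 1000) / (2 * pi * sinograms@talbotDistance)
  dim(q) <- c(d[1], d[2] * d[3])
  filt <- if (method == "hilbert") {
    .filterRows(q, pixel, "hilbert", window)
  } else {
    p <- apply(q, 2, cumsum) * pixel
    .filterRows(p, pixel, "ramp", window)
  }
  dim(filt) <- d
  vol <- cpp_backproject(as.double(filt), as.integer(d), ang * pi / 180,
                         d[1], d[1])
  vol <- array(vol, dim = c(d[1], d[1], d[2])) * (pi / length(ang))
  new("DeltaVolume", grid = vol, voxelSize = pixel,
      wavelength = wavelength)
}

#' Ring-artefact score
#'
#' Standard deviation of the polar-angle-averaged radial profile within a
#' background annulus of a reconstructed slice: detector-pixel-correlated
#' errors backproject onto circles, so a structured radial profile (after
#' averaging out statistical noise along each ring) indicates ring
#' artefacts.  The score is invariant under in-plane rotation.
#'
#' @param x a [DeltaVolume-class], [DensityVolume-class] or a 2-D matrix
#' @param rInner,rOuter annulus radii as fractions of the half-side
#'   (defaults 0.6 and 0.9); must lie inside the grid
#' @param slice slice index for volumes (default: middle slice)
#' @return the ring score (same units as the input values)
#' @export
ringMetric <- function(x, rInner = 0.6, rOuter = 0.9, slice = NULL) {
  img <- if (is.matrix(x)) x else {
    g <- voxelGrid(x)
    if (is.null(slice)) slice <- ceiling(dim(g)[3] / 2)
    g[, , slice]
  }
  n1 <- nrow(img); n2 <- ncol(img)
  if (rOuter > 1 || rInner < 0 || rInner >= rOuter)
    stop("annulus must satisfy 0 <= rInner < rOuter <= 1")
  half <- (min(n1, n2) - 1) / 2
  cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
  r <- sqrt(outer((seq_len(n1) - cx)^2, (seq_len(n2) - cy)^2, "+"))
  sel <- r >= rInner * half & r <= rOuter * half
  if (!any(sel)) stop("annulus lies outside the grid")
  rbin <- round(r[sel])
  prof <- tapply(img[sel], rbin, mean)
  if (length(prof) < 2L) return(0)
  sd(prof)
}
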