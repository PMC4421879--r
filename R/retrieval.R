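# Phase-stepping retrieval: per-pixel mean intensity, stepping-curve phase
# and visibility from N equally spaced frames over one grating period,
# plus flat-field correction and 1-D phase unwrapping.

.wrapPhase <- function(x) {
  # wrap to (-pi, pi]
  pi - ((pi - x) %% (2 * pi))
}

#' First-harmonic phase-stepping retrieval
#'
#' Per pixel over N >= 3 equally spaced steps covering one grating period:
#' I0 = mean of the frames, complex first harmonic
#' a1 = (2/N) sum_k I_k exp(-i 2 pi k / N), psi = Arg(a1), V = |a1| / I0.
#' This is exact for any noiseless curve I0 (1 + V cos(2 pi k/N + psi))
#' and coincides with the per-pixel least-squares sinusoid fit for equally
#' spaced steps.
#'
#' @param frames 3-D array (nx x ny x N) or a list of N matrices
#' @return list of matrices `I0`, `psi` (rad, in (-pi, pi\]), `V`, and a
#'   logical `invalid` mask flagging I0 = 0 pixels
#' @examples
#' k <- 0:4
#' frames <- sapply(k, function(kk) 100 * (1 + 0.3 * cos(2 * pi * kk / 5 + 0.7)))
#' retrieveStepping(array(rep(frames, each = 1), c(1, 1, 5)))
#' @export
retrieveStepping <- function(frames) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  d <- dim(frames)
  N <- d[length(d)]
  if (N < 3L) stop("at least 3 phase steps are required")
  dim(frames) <- c(prod(d[-length(d)]), N)
  w <- exp(-2i * pi * (seq_len(N) - 1L) / N)
  I0 <- rowMeans(frames)
  a1 <- (2 / N) * as.vector(frames %*% w)
  invalid <- I0 == 0
  V <- ifelse(invalid, NA_real_, Mod(a1) / I0)
  psi <- Arg(a1)
  psi[psi <= -pi] <- pi
  shape <- d[-length(d)]
  list(I0 = array(I0, shape), psi = array(psi, shape),
       V = array(V, shape), invalid = array(invalid, shape))
}

#' Flat-field correction of retrieval triplets
#'
#' Divides out the instrument structure using a no-sample reference
#' retrieval: trans = I0_s / I0_r, dphase = wrap(psi_s - psi_r) to
#' (-pi, pi], visRatio = V_s / V_r.  Invalid pixels (zero reference
#' intensity) propagate as NA.
#'
#' @param sample retrieval list from [retrieveStepping()]
#' @param reference retrieval list of the matching flat stack
#' @return list of `trans`, `dphase`, `visRatio`, `invalid`
#' @export
flatCorrect <- function(sample, reference) {
  if (!identical(dim(sample$I0), dim(reference$I0)))
    stop("sample and reference shapes differ")
  invalid <- sample$invalid | reference$invalid | reference$I0 == 0
  trans <- sample$I0 / reference$I0
  trans[invalid] <- NA_real_
  dphase <- .wrapPhase(sample$psi - reference$psi)
  dphase[invalid] <- NA_real_
  visRatio <- sample$V / reference$V
  visRatio[invalid] <- NA_real_
  list(trans = trans, dphase = dphase, visRatio = visRatio,
       invalid = invalid)
}

#' Retrieve and flat-correct a full stepping stack
#'
#' Runs [retrieveStepping()] per angle on the sample and reference frames
#' of a [SteppingStack-class] and flat-corrects each angle against its own
#' reference (the simulator's references are per-angle; with measured data
#' the nearest-in-angle flat block plays this role).
#'
#' @param stack a [SteppingStack-class]
#' @return a [RetrievedProjectionSet-class]
#' @export
retrieveStack <- function(stack) {
  stopifnot(is(stack, "SteppingStack"))
  d <- dim(stack@frames)
  na <- d[4]
  trans <- dph <- vr <- array(NA_real_, dim = c(d[1], d[2], na))
  for (a in seq_len(na)) {
    s <- retrieveStepping(stack@frames[, , , a])
    r <- retrieveStepping(stack@reference[, , , a])
    fc <- flatCorrect(s, r)
    trans[, , a] <- fc$trans
    dph[, , a] <- fc$dphase
    vr[, , a] <- fc$visRatio
  }
  new("RetrievedProjectionSet", trans = trans, dphase = dph, visRatio = vr,
      angles = stack@angles, pixelSize = stack@pixelSize,
      talbotDistance = stack@talbotDistance, g2Pitch = stack@g2Pitch)
}

#' 1-D phase unwrapping along the differential axis
#'
#' Adjusts successive differences along each row (the differential axis)
#' by multiples of 2 pi whenever they exceed pi in magnitude.  Maps with
#' no wraps are returned unchanged.
#'
#' @param dphase 2-D map or 3-D stack; the first dimension is the
#'   differential axis
#' @return the unwrapped map, same shape
#' @export
unwrapRows <- function(dphase) {
  d <- dim(dphase)
  x <- dphase
  if (is.null(d) || length(d) == 1L) {
    dif <- diff(x)
    corr <- cumsum(-2 * pi * round(dif / (2 * pi)))
    return(c(x[1], x[-1] + corr))
  }
  dim(x) <- c(d[1], prod(d[-1]))
  dif <- x[-1, , drop = FALSE] - x[-d[1], , drop = FALSE]
  corr <- apply(-2 * pi * round(dif / (2 * pi)), 2, cumsum)
  x[-1, ] <- x[-1, , drop = FALSE] + corr
  dim(x) <- d
  x
}
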