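# On-the-fly acquisition scheduling: the sample rotates continuously while
# the analyser grating steps repetitively; the camera is triggered at a
# uniform interval and flat-field blocks are inserted at a fixed rotation
# interval.

#' Construct a ScanProtocol
#'
#' @param nProjections number of projections Y over 180 degrees
#' @param nSteps phase steps per projection (>= 3)
#' @param exposure exposure time per frame (s)
#' @param readout camera readout time (s)
#' @param settle analyser-step settle delay (s)
#' @param pulsesPer180 motor pulses per 180 degree rotation
#' @param pulseResolution degrees per pulse (must satisfy
#'   pulsesPer180 * pulseResolution = 180)
#' @param flatInterval rotation between flat-field blocks (deg)
#' @param flatFrames frames per flat block
#' @return a [ScanProtocol-class]
#' @examples
#' mouseProtocol <- scanProtocol(600, 5, 0.5, flatInterval = 36)
#' rotationSpeed(mouseProtocol)   # 51 pulses/s
#' @export
scanProtocol <- function(nProjections, nSteps = 5L, exposure = 0.5,
                         readout = 0.05, settle = 0.03,
                         pulsesPer180 = 90000L, pulseResolution = 0.002,
                         flatInterval = 36, flatFrames = 5L) {
  new("ScanProtocol", nProjections = as.integer(nProjections),
      nSteps = as.integer(nSteps), exposure = exposure, readout = readout,
      settle = settle, pulsesPer180 = as.integer(pulsesPer180),
      pulseResolution = pulseResolution, flatInterval = flatInterval,
      flatFrames = as.integer(flatFrames))
}

#' Phase-stepping period
#'
#' T = N_step x (exposure + readout + settle): the time for one complete
#' stepping series, i.e. one projection.
#'
#' @param protocol a [ScanProtocol-class]
#' @return period T (s)
#' @export
stepPeriod <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  protocol@nSteps * (protocol@exposure + protocol@readout + protocol@settle)
}

#' Rotation speed in motor pulses per second
#'
#' X_proj = X_total / Y pulses must be consumed in one stepping period T,
#' so the speed is X_proj / T, truncated to an integer number of pulses per
#' second (the motor controller convention; the documented truncation also
#' reproduces the quoted 51 pulses/s for the 600 x 5 x 0.58 s protocol).
#'
#' @param protocol a [ScanProtocol-class]
#' @param truncate integer-truncate the speed (default TRUE)
#' @return pulses per second
#' @export
rotationSpeed <- function(protocol, truncate = TRUE) {
  stopifnot(is(protocol, "ScanProtocol"))
  T <- stepPeriod(protocol)
  if (T <= 0) stop("stepping period must be > 0")
  if (protocol@nProjections < 1L) stop("nProjections must be >= 1")
  xproj <- protocol@pulsesPer180 / protocol@nProjections
  s <- xproj / T
  if (truncate) floor(s) else s
}

#' Total measurement time
#'
#' Rotation-limited duration X_total / speed.  With the integer-truncated
#' speed this reproduces quoted wall-clock times; with `roundSpeed = FALSE`
#' it equals Y x T exactly, so the three-step/five-step time ratio is
#' exactly 3/5 for otherwise identical protocols.  Flat-field block time
#' can be added on request (blocks x frames x trigger spacing, plus a
#' per-block overhead).
#'
#' @param protocol a [ScanProtocol-class]
#' @param includeFlats add flat-field block time
#' @param flatOverhead extra seconds per flat block (stage translation);
#'   default 0
#' @param roundSpeed use the integer-truncated rotation speed
#' @return total time (s)
#' @export
totalTime <- function(protocol, includeFlats = FALSE, flatOverhead = 0,
                      roundSpeed = TRUE) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (protocol@nProjections < 1L) return(0)
  spacing <- protocol@exposure + protocol@readout + protocol@settle
  if (spacing == 0) return(0)
  t <- protocol@pulsesPer180 / rotationSpeed(protocol, truncate = roundSpeed)
  if (includeFlats) {
    nblocks <- .flatBlockCount(protocol) + 1L   # interior + initial
    t <- t + nblocks * (protocol@flatFrames * spacing + flatOverhead)
  }
  t
}

.flatBlockCount <- function(protocol) {
  # interior blocks: one per completed flatInterval of rotation
  as.integer(floor(180 / protocol@flatInterval + 1e-9))
}

#' Build the trigger timeline
#'
#' Events at a uniform trigger spacing (exposure + readout + settle): a
#' `g2_step` precedes each `trigger`; one flat block (`flat_block_start`
#' followed by `flat_frames` x `flat_frame`) at t = 0 plus one after every
#' completed `flatInterval` of rotation.  If the interval does not divide
#' 180 degrees the trailing partial interval gets no block (with a
#' warning).
#'
#' @param protocol a [ScanProtocol-class]
#' @param initialFlat include the flat block at t = 0 (default TRUE)
#' @return a [Schedule-class]
#' @export
buildSchedule <- function(protocol, initialFlat = TRUE) {
  stopifnot(is(protocol, "ScanProtocol"))
  spacing <- protocol@exposure + protocol@readout + protocol@settle
  Y <- protocol@nProjections
  N <- protocol@nSteps
  if (Y < 1L) {
    ev <- data.frame(time_s = numeric(), kind = character(),
                     proj = integer(), step = integer(),
                     stringsAsFactors = FALSE)
    return(new("Schedule", events = ev, totalTime = 0, rotationSpeed = 0))
  }
  if (abs(180 / protocol@flatInterval -
          round(180 / protocol@flatInterval)) > 1e-9)
    warning("flatInterval does not divide 180 degrees; ",
            "the last partial interval gets no flat block")
  speed <- rotationSpeed(protocol)
  projSpan <- 180 / Y                      # degrees per projection
  nInterior <- .flatBlockCount(protocol)
  # projection index after which interior flat block k is inserted
  flatAfter <- vapply(seq_len(nInterior), function(k)
    as.integer(ceiling(k * protocol@flatInterval / projSpan - 1e-9)), 1L)
  flatAfter <- pmin(flatAfter, Y)

  times <- kinds <- projs <- steps <- vector("list", 2L * Y + nInterior + 2L)
  i <- 0L; t <- 0
  emitFlat <- function(t) {
    tt <- c(t, t + spacing * (seq_len(protocol@flatFrames) - 1L))
    list(time = tt,
         kind = c("flat_block_start", rep("flat_frame", protocol@flatFrames)),
         proj = rep(NA_integer_, length(tt)),
         step = c(NA_integer_, seq_len(protocol@flatFrames)),
         tend = t + spacing * protocol@flatFrames)
  }
  add <- function(e) {
    i <<- i + 1L
    times[[i]] <<- e$time; kinds[[i]] <<- e$kind
    projs[[i]] <<- e$proj; steps[[i]] <<- e$step
  }
  if (initialFlat && protocol@flatFrames > 0L) {
    f <- emitFlat(t); add(f); t <- f$tend
  }
  nextFlat <- 1L
  for (p in seq_len(Y)) {
    tt <- t + spacing * (seq_len(N) - 1L)
    add(list(time = rep(tt, each = 2L),
             kind = rep(c("g2_step", "trigger"), N),
             proj = rep(p, 2L * N),
             step = rep(seq_len(N), each = 2L)))
    t <- t + spacing * N
    while (nextFlat <= nInterior && flatAfter[nextFlat] == p) {
      if (protocol@flatFrames > 0L) { f <- emitFlat(t); add(f); t <- f$tend }
      nextFlat <- nextFlat + 1L
    }
  }
  ev <- data.frame(time_s = unlist(times[seq_len(i)]),
                   kind = unlist(kinds[seq_len(i)]),
                   proj = unlist(projs[seq_len(i)]),
                   step = unlist(steps[seq_len(i)]),
                   stringsAsFactors = FALSE)
  new("Schedule", events = ev, totalTime = t, rotationSpeed = speed)
}

#' Export a schedule as CSV
#'
#' @param schedule a [Schedule-class]
#' @param path output CSV path (columns time_s, kind, proj, step)
#' @return the path, invisibly
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "Schedule"))
  write.csv(schedule@events, path, row.names = FALSE)
  invisible(path)
}
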