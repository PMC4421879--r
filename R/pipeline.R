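# Configuration handling and the end-to-end pipeline driver:
# phantom -> simulate -> retrieve -> reconstruct -> report, re-entrant
# from on-disk artifacts and deterministic for a fixed seed.

.defaultConfig <- function() {
  list(
    instrument = list(
      energy_keV = 25, wavelength_rounding = "3sf",
      flux_density = 1.2e8,
      g1 = list(pitch_um = 10, design_energy_keV = 18.8,
                design_phase = pi / 2, extent_mm = 25, tilt_deg = 0),
      g2 = list(pitch_um = 10, extent_mm = 25, tilt_deg = 45),
      talbot_order = 3,
      detector = list(native_pixel_um = 6.5, magnification = 0.425,
                      n_pixels = 2048, readout_s = 0.05,
                      effective_pixel_um = 15.5, gain = 7)),
    scan = list(n_projections = 600, n_steps = 5, exposure_s = 0.5,
                readout_s = 0.05, settle_s = 0.03, pulses_per_180 = 90000,
                pulse_resolution_deg = 0.002, flat_interval_deg = 36,
                flat_frames = 5),
    phantom = list(scenario = "fetus_fresh", grid_n = 64, voxel_size_mm = 0.1,
                   medium_density = 1.005, z_over_m = 0.55),
    simulation = list(photon_budget = Inf, visibility = 0.3,
                      profile = "sine", gain = 1, n_angles = 180),
    reconstruction = list(method = "hilbert", window = TRUE),
    densitometry = list(calibration = 1.0, bin_width = 0.002),
    seed = 1)
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration with blocks `instrument`, `scan`,
#' `phantom`, `simulation`, `reconstruction`, `densitometry` and a global
#' `seed`; missing keys fall back to the built-in defaults (the reference
#' instrument at 25 keV, the 600 x 5 x 0.5 s protocol, a 64^3 fetus
#' phantom).
#'
#' @param path YAML/JSON file, or NULL for the pure defaults
#' @return the merged configuration list
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.list(user)) stop("unparseable config: ", path)
    cfg <- .mergeConfig(cfg, user)
  }
  cfg
}

#' Validate a run configuration
#'
#' Checks unit sanity and protocol consistency; returns findings rather
#' than stopping, so a driver can refuse to start any compute on errors.
#'
#' @param config a configuration list (from [readRunConfig()]) or a file
#'   path
#' @return data.frame(level, message); zero rows when clean
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  find <- list()
  bad <- function(msg) find[[length(find) + 1L]] <<- c("error", msg)
  warn <- function(msg) find[[length(find) + 1L]] <<- c("warning", msg)
  ins <- config$instrument
  if (ins$energy_keV <= 0) bad("instrument energy must be positive")
  p <- ins$talbot_order
  if (p < 1 || p %% 2 == 0) bad("talbot order must be odd")
  if (ins$g2$tilt_deg < 0 || ins$g2$tilt_deg > 90)
    bad("g2 tilt must lie in [0, 90] degrees")
  sc <- config$scan
  if (sc$n_steps < 3) bad("n_steps must be >= 3")
  if (sc$exposure_s < 0 || sc$readout_s < 0 || sc$settle_s < 0)
    bad("scan times must be >= 0")
  if (abs(sc$pulses_per_180 * sc$pulse_resolution_deg - 180) > 1e-6)
    bad("pulses_per_180 x pulse_resolution_deg must equal 180")
  r <- 180 / sc$flat_interval_deg
  if (abs(r - round(r)) > 1e-9)
    warn("flat interval does not divide 180 degrees")
  if (config$phantom$voxel_size_mm <= 0) bad("voxel size must be positive")
  sim <- config$simulation
  if (sim$visibility < 0 || sim$visibility > 1)
    bad("visibility must lie in [0, 1]")
  if (!sim$profile %in% c("sine", "triangle"))
    bad("profile must be sine or triangle")
  if (length(find) == 0L)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, find)
  data.frame(level = out[, 1], message = out[, 2],
             stringsAsFactors = FALSE)
}

# deterministic per-stage seed derived from the config seed and a stable
# stage label; kept below 2^31
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000L)) %% 2147483647L
}

.instrumentFromConfig <- function(cfg) {
  ins <- cfg$instrument
  beam <- beamSpec(ins$energy_keV, ins$flux_density,
                   rounding = ins$wavelength_rounding)
  g1 <- gratingSpec(ins$g1$pitch_um, "phase",
                    designEnergy = ins$g1$design_energy_keV,
                    designPhaseShift = ins$g1$design_phase,
                    extent = ins$g1$extent_mm, tilt = ins$g1$tilt_deg)
  g2 <- gratingSpec(ins$g2$pitch_um, "absorption",
                    extent = ins$g2$extent_mm, tilt = ins$g2$tilt_deg)
  det <- detectorSpec(ins$detector$native_pixel_um,
                      ins$detector$magnification,
                      ins$detector$n_pixels,
                      ifelse(is.null(ins$detector$effective_pixel_um),
                             NA_real_, ins$detector$effective_pixel_um),
                      ins$detector$readout_s,
                      ifelse(is.null(ins$detector$gain), 1,
                             ins$detector$gain))
  geom <- geometrySpec(beam, g1, g2, order = ins$talbot_order)
  list(beam = beam, g1 = g1, g2 = g2, detector = det, geometry = geom)
}

.protocolFromConfig <- function(cfg) {
  sc <- cfg$scan
  scanProtocol(sc$n_projections, sc$n_steps, sc$exposure_s, sc$readout_s,
               sc$settle_s, sc$pulses_per_180, sc$pulse_resolution_deg,
               sc$flat_interval_deg, sc$flat_frames)
}

#' Instrument-design summary
#'
#' The closed-form design numbers for a configuration: wavelength, Talbot
#' distance, tilted-G2 half-span, achromaticity, detector geometry,
#' stepping period, rotation speed and scan time.
#'
#' @param config configuration list or path
#' @return named list of design quantities
#' @export
designSummary <- function(config = NULL) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  parts <- .instrumentFromConfig(cfg)
  prot <- .protocolFromConfig(cfg)
  eg <- effectiveGeometry(parts$detector)
  sh <- achromaticShift(parts$geometry@deltaZ,
                        parts$geometry@talbotDistance,
                        parts$beam@wavelength)
  list(energy_keV = parts$beam@energy,
       wavelength_nm = parts$beam@wavelength,
       talbot_distance_mm = parts$geometry@talbotDistance,
       delta_z_mm = parts$geometry@deltaZ,
       relative_wavelength_shift = sh$relativeShift,
       delta_lambda_nm = sh$deltaLambda,
       g1_phase_shift_rad = gratingPhaseShift(parts$g1, parts$beam@energy),
       effective_pixel_um = eg$effectivePixel,
       fov_mm = eg$fovReported,
       step_period_s = stepPeriod(prot),
       rotation_speed_pps = rotationSpeed(prot),
       total_time_s = totalTime(prot))
}

#' Run the simulation-to-report pipeline
#'
#' Executes phantom -> simulate -> retrieve -> reconstruct -> report (or a
#' subset of consecutive stages, consuming artifacts written by earlier
#' runs in `out`) and writes a manifest JSON listing every artifact with
#' its MD5 checksum.  All randomness derives from the single config seed,
#' split deterministically per stage, so a rerun with the same seed
#' reproduces every artifact bit-identically.
#'
#' @param config configuration list or path
#' @param out output directory (created if needed)
#' @param stages character subset of
#'   c("phantom", "simulate", "retrieve", "reconstruct", "report")
#' @param quiet suppress per-stage messages
#' @return the manifest list, invisibly
#' @export
runPipeline <- function(config = NULL, out = tempfile("phasect"),
                        stages = c("phantom", "simulate", "retrieve",
                                   "reconstruct", "report"),
                        quiet = FALSE) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  v <- validateConfig(cfg)
  if (any(v$level == "error"))
    stop("invalid config: ", paste(v$message[v$level == "error"],
                                   collapse = "; "))
  all_stages <- c("phantom", "simulate", "retrieve", "reconstruct",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  parts <- .instrumentFromConfig(cfg)
  manifest <- list(seed = cfg$seed, stages = stages, artifacts = list())
  note <- function(stage, path) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<-
      list(stage = stage, file = basename(path),
           md5 = unname(tools::md5sum(path)))
  }
  say <- function(...) if (!quiet) message(...)
  p <- function(f) file.path(out, f)
  needs <- function(f, stage) {
    if (!file.exists(p(f)))
      stop("missing upstream artifact '", f, "' for stage ", stage)
  }

  if ("phantom" %in% stages) {
    say("stage phantom")
    par <- scenarioParams(cfg$phantom$scenario, n = cfg$phantom$grid_n,
                          voxelSize = cfg$phantom$voxel_size_mm,
                          mediumDensity = cfg$phantom$medium_density,
                          zOverM = cfg$phantom$z_over_m,
                          seed = .stageSeed(cfg$seed, "phantom"))
    ph <- if (par$scenario == "aorta_stretch") makeAortaPhantom(par)
          else makeFetusPhantom(par)
    writePhantom(ph, p("phantom.tif"))
    note("phantom", p("phantom.tif"))
    note("phantom", p("phantom_labels.tif"))
  }
  if ("simulate" %in% stages) {
    say("stage simulate")
    needs("phantom.tif", "simulate")
    ph <- readPhantom(p("phantom.tif"))
    opt <- densityToOptical(ph, parts$beam)
    na <- cfg$simulation$n_angles
    ang <- seq(0, 180, length.out = na + 1L)[seq_len(na)]
    proj <- projectVolume(opt, parts$geometry,
                          cfg$instrument$g2$pitch_um, ang)
    stack <- simulateStepping(proj,
                              photonBudget = cfg$simulation$photon_budget,
                              visibility = cfg$simulation$visibility,
                              nSteps = cfg$scan$n_steps,
                              profile = cfg$simulation$profile,
                              gain = cfg$simulation$gain,
                              seed = .stageSeed(cfg$seed, "simulate"))
    d <- dim(stack@frames)
    writeVolumeTiff(array(stack@frames, dim = c(d[1], d[2], d[3] * d[4])),
                    p("frames.tif"),
                    meta = list(unit = "counts", n_steps = d[3],
                                angles = ang,
                                pixel_size_mm = stack@pixelSize,
                                talbot_distance_mm = stack@talbotDistance,
                                g2_pitch_um = stack@g2Pitch,
                                visibility = stack@visibility,
                                profile = stack@profile,
                                gain = stack@gain,
                                budget = cfg$simulation$photon_budget,
                                seed = .stageSeed(cfg$seed, "simulate")),
                    bits = 32L)
    writeVolumeTiff(array(stack@reference,
                          dim = c(d[1], d[2], d[3] * d[4])),
                    p("reference.tif"), meta = list(unit = "counts"),
                    bits = 32L)
    note("simulate", p("frames.tif"))
    note("simulate", p("reference.tif"))
  }
  if ("retrieve" %in% stages) {
    say("stage retrieve")
    needs("frames.tif", "retrieve")
    fr <- readVolumeTiff(p("frames.tif"))
    rf <- readVolumeTiff(p("reference.tif"))
    m <- fr$meta
    ns <- m$n_steps
    na <- length(m$angles)
    d <- dim(fr$grid)
    stack <- new("SteppingStack",
                 frames = array(fr$grid, dim = c(d[1], d[2], ns, na)),
                 reference = array(rf$grid, dim = c(d[1], d[2], ns, na)),
                 angles = m$angles, photonBudget = as.numeric(m$budget),
                 visibility = m$visibility, gain = m$gain,
                 profile = m$profile, pixelSize = m$pixel_size_mm,
                 talbotDistance = m$talbot_distance_mm,
                 g2Pitch = m$g2_pitch_um)
    ret <- retrieveStack(stack)
    meta <- list(angles = m$angles, pixel_size_mm = m$pixel_size_mm,
                 talbot_distance_mm = m$talbot_distance_mm,
                 g2_pitch_um = m$g2_pitch_um)
    writeVolumeTiff(ret@trans, p("trans.tif"), meta)
    writeVolumeTiff(ret@dphase, p("dphase.tif"), c(meta, unit = "rad"))
    writeVolumeTiff(ret@visRatio, p("visratio.tif"), meta)
    for (f in c("trans.tif", "dphase.tif", "visratio.tif"))
      note("retrieve", p(f))
  }
  if ("reconstruct" %in% stages) {
    say("stage reconstruct")
    needs("dphase.tif", "reconstruct")
    dp <- readVolumeTiff(p("dphase.tif"))
    tr <- readVolumeTiff(p("trans.tif"))
    vr <- readVolumeTiff(p("visratio.tif"))
    m <- dp$meta
    ret <- new("RetrievedProjectionSet", trans = tr$grid,
               dphase = dp$grid, visRatio = vr$grid, angles = m$angles,
               pixelSize = m$pixel_size_mm,
               talbotDistance = m$talbot_distance_mm,
               g2Pitch = m$g2_pitch_um)
    dvol <- fbpDpc(ret, method = cfg$reconstruction$method,
                   window = cfg$reconstruction$window,
                   wavelength = parts$beam@wavelength)
    writeVolumeTiff(dvol@grid, p("delta.tif"),
                    meta = list(unit = "delta_diff",
                                voxel_size_mm = dvol@voxelSize,
                                wavelength_nm = parts$beam@wavelength))
    note("reconstruct", p("delta.tif"))
  }
  if ("report" %in% stages) {
    say("stage report")
    needs("delta.tif", "report")
    dv <- readVolumeTiff(p("delta.tif"))
    dvol <- new("DeltaVolume", grid = dv$grid,
                voxelSize = dv$meta$voxel_size_mm,
                wavelength = dv$meta$wavelength_nm)
    conv <- densityConversion(parts$beam@wavelength,
                              cfg$phantom$z_over_m,
                              calibration = cfg$densitometry$calibration,
                              mediumDensity = cfg$phantom$medium_density)
    rho <- deltaToDensity(dvol, conv)
    ph <- readPhantom(p("phantom.tif"))
    labs <- setdiff(sort(unique(as.vector(ph@labels))), 0L)
    rows <- lapply(labs, function(l) {
      vm <- volumeMass(rho, ph@labels == l)
      data.frame(label = l, n_voxels = vm$n, volume_mm3 = vm$volume_mm3,
                 mean_density = vm$meanDensity, sd_density =
                   roiStats(rho, ph@labels == l)$sd, mass_g = vm$mass_g)
    })
    rep <- do.call(rbind, rows)
    write.csv(rep, p("report.csv"), row.names = FALSE)
    hst <- densityHistogram(rho, ph@labels > 0,
                            binWidth = cfg$densitometry$bin_width)
    write.csv(data.frame(bin_center = hst$mids, count = hst$counts),
              p("histogram.csv"), row.names = FALSE)
    bg <- densityResolution(rho, ph@labels == 0L &
                              .edgeTrimMask(dim(ph@grid)))
    jsonlite::write_json(list(background_resolution_mg_cm3 = bg,
                              labels = labs),
                         p("report.json"), auto_unbox = TRUE, digits = NA)
    for (f in c("report.csv", "histogram.csv", "report.json"))
      note("report", p(f))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# interior mask dropping a 10% margin, used for background statistics
.edgeTrimMask <- function(d) {
  m <- array(FALSE, dim = d)
  i <- function(n) max(1L, ceiling(0.1 * n)):min(n, floor(0.9 * n))
  m[i(d[1]), i(d[2]), i(d[3])] <- TRUE
  m
}
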