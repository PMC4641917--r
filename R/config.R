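# Configuration, run commands and standard-format export.

#' Default run configuration
#'
#' A flat key-value record covering instrument, scene and pipeline
#' parameters. Every key has a default; [parse_config()] rejects unknown
#' keys.
#'
#' @return a named list of defaults.
#' @export
default_config <- function() {
  list(
    # instrument
    dac_level = 255, pga_gain = 44, post_filter_gain = 5.1,
    f_mod = 3125, t_dr = 18.5e-6, t_df = 7.2e-6,
    lp_order = 3, lp_cutoff = 100,
    adc_bits = 16, adc_v_max = 2.5, conversion_time = 0.0803,
    dwell_time = 0.024,
    # probe / optics
    n_channels = 2, distance_cm = 3.5, dpf = 6.0, tissue_loss_db = 60,
    # scene
    n_trials = 30, scene_fs = 12.5, pulse_freq = 1.2, pulse_amplitude = 1.0,
    slow_freq = 0.1, slow_amplitude = 0.3, noise_sd = 0.3,
    drift_slope = 0.001, hbo_amplitude = 1.0, hbr_amplitude = -0.3,
    long_rest_duration = 60,
    # pipeline
    cv_folds = 10,
    # seeds
    seed = 0
  )
}

#' Parse a flat key-value configuration document
#'
#' Accepts YAML text (`key: value` per line). Unknown keys and out-of-range
#' values are rejected with the offending key named; missing keys take their
#' defaults.
#'
#' @param text configuration text (character scalar), or `NULL`/empty for
#'   all defaults.
#' @return a validated `run_config` list.
#' @export
parse_config <- function(text = NULL) {
  cfg <- default_config()
  if (!is.null(text) && nzchar(trimws(paste(text, collapse = "\n")))) {
    user <- yaml::yaml.load(paste(text, collapse = "\n"))
    if (!is.list(user)) stop_input("configuration must be a key-value document")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L) {
      stop_input("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  # range validation with the key named (constructors re-validate downstream)
  if (!any(abs(cfg$pga_gain - PGA_GAINS) < 1e-9)) {
    stop_input("config key `pga_gain` = %s is not an allowed PGA step (0.6875-88)",
               format(cfg$pga_gain))
  }
  for (key in c("f_mod", "lp_cutoff", "scene_fs", "dwell_time",
                "conversion_time", "n_trials", "n_channels", "cv_folds")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop_input("config key `%s` must be a positive number", key)
    }
  }
  if (cfg$dac_level < 0 || cfg$dac_level > 255) {
    stop_input("config key `dac_level` must be within 0-255")
  }
  structure(cfg, class = "run_config")
}

config_to_objects <- function(cfg) {
  list(
    instrument = instrument_config(
      emitter = emitter_config(cfg$dac_level),
      detector = detector_config(),
      gain = gain_chain(cfg$pga_gain, cfg$post_filter_gain),
      lockin = lockin_config(cfg$f_mod, cfg$t_dr, cfg$t_df,
                             cfg$lp_order, cfg$lp_cutoff),
      adc = adc_config(cfg$adc_bits, 0, cfg$adc_v_max, cfg$conversion_time)),
    constants = optical_constants(dpf = cfg$dpf, distance = cfg$distance_cm,
                                  tissue_loss_db = cfg$tissue_loss_db),
    schedule = build_tdm_schedule(1, cfg$n_channels, cfg$dwell_time,
                                  cfg$conversion_time),
    hrf = hrf_params(hbo_amplitude = cfg$hbo_amplitude,
                     hbr_amplitude = cfg$hbr_amplitude)
  )
}

#' Export a hemodynamic series as a CSV/JSON bundle
#'
#' Writes the timecourses as a plain CSV (one column per
#' channel x chromophore plus time) and the probe metadata — wavelengths
#' (750/850 nm), source-detector distance (35 mm), optode labels
#' (Fp1/Fp2 sources, AFz detector) and sampling rate — as a JSON sidecar
#' (`<path>.json`). [import_series_csv()] round-trips the numbers.
#'
#' @param series a [hemo_series()].
#' @param path CSV output path.
#' @param sources,detector optode labels for the metadata record.
#' @return `path`, invisibly.
#' @export
export_series_csv <- function(series, path,
                              sources = c("Fp1", "Fp2"), detector = "AFz") {
  stopifnot(inherits(series, "hemo_series"))
  n_ch <- ncol(series$hbo)
  df <- data.frame(time = series$t)
  for (ch in seq_len(n_ch)) df[[paste0("hbo_ch", ch)]] <- series$hbo[, ch]
  for (ch in seq_len(n_ch)) df[[paste0("hbr_ch", ch)]] <- series$hbr[, ch]
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    fs_hz = series$fs, n_channels = n_ch,
    wavelengths_nm = c(750, 850),
    source_detector_distance_mm = 35,
    sources = sources[seq_len(min(n_ch, length(sources)))],
    detector = detector,
    units = "micromolar")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Re-import a series bundle written by [export_series_csv()]
#'
#' @param path the CSV path.
#' @return a `hemo_series` with a `meta` attribute.
#' @export
import_series_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hbo_cols <- grep("^hbo_ch", names(df), value = TRUE)
  hbr_cols <- grep("^hbr_ch", names(df), value = TRUE)
  s <- hemo_series(as.matrix(df[hbo_cols]), as.matrix(df[hbr_cols]),
                   fs = meta$fs_hz, t = df$time)
  attr(s, "meta") <- meta
  s
}

#' Run a named instrument command
#'
#' The four entry points of the digital twin, also exposed by the
#' command-line script in `inst/cli/fnirsim`:
#'
#' * `simulate` — generate the default synthetic study (scene + TDM
#'   acquisition) and write the scene series bundle plus the raw packet CSV.
#' * `characterize` — compute the bench characterization report and write it
#'   as CSV.
#' * `analyze` — read a packet CSV, run the full BCI pipeline, write the
#'   feature table, cross-validation result (JSON) and average responses.
#' * `protocol-trace` — encode the TDM schedule to control events, decode
#'   them back and write the channel activation timeline.
#'
#' All outputs are deterministic given the configuration and seed.
#'
#' @param name one of `"simulate"`, `"characterize"`, `"analyze"`,
#'   `"protocol-trace"`.
#' @param config a [parse_config()] result (default: all defaults).
#' @param out_dir output directory (created if missing).
#' @param input input packet CSV for `analyze` (defaults to the file
#'   `simulate` writes into `out_dir`).
#' @param verbose print per-stage progress.
#' @return a named list of the artifacts written (paths and key results),
#'   invisibly.
#' @export
run_command <- function(name = c("simulate", "characterize", "analyze",
                                 "protocol-trace"),
                        config = parse_config(), out_dir = ".",
                        input = NULL, verbose = FALSE) {
  name <- match.arg(name)
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_to_objects(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  if (name == "simulate") {
    protocol <- generate_protocol(cfg$n_trials,
                                  long_rest_duration = cfg$long_rest_duration,
                                  seed = cfg$seed)
    scene <- build_scene(protocol, obj$hrf, cfg$n_channels, cfg$scene_fs,
                         cfg$pulse_freq, cfg$pulse_amplitude,
                         cfg$slow_freq, cfg$slow_amplitude,
                         cfg$noise_sd, cfg$drift_slope, seed = cfg$seed)
    say("scene: %d samples x %d channels", nrow(scene$hbo), ncol(scene$hbo))
    rec <- simulate_acquisition(scene, obj$schedule, obj$instrument,
                                obj$constants, seed = cfg$seed + 1)
    say("recording: %d packets", nrow(rec))
    scene_path <- file.path(out_dir, "scene.csv")
    export_series_csv(hemo_series(scene$hbo, scene$hbr, scene$fs, scene$t),
                      scene_path)
    pkt_path <- file.path(out_dir, "packets.csv")
    write_packets(rec, pkt_path)
    proto_path <- file.path(out_dir, "protocol.csv")
    write.csv(as.data.frame(protocol), proto_path, row.names = FALSE)
    invisible(list(scene = scene_path, packets = pkt_path,
                   protocol = proto_path))
  } else if (name == "characterize") {
    report <- characterize(
      timing = timing_measurement(cfg$t_dr, cfg$t_df, 1 / cfg$f_mod),
      tissue_loss_db = cfg$tissue_loss_db)
    path <- file.path(out_dir, "characterization.csv")
    write.csv(as.data.frame(report), path, row.names = FALSE)
    say("characterization written to %s", path)
    invisible(list(report = report, csv = path))
  } else if (name == "analyze") {
    if (is.null(input)) input <- file.path(out_dir, "packets.csv")
    if (!file.exists(input)) stop_input("input packet file `%s` not found", input)
    packets <- parse_packets(input)
    if (nrow(packets) == 0L) stop_input("packet file `%s` is empty", input)
    rec <- structure(packets,
                     config = obj$instrument,
                     sample_rate = obj$schedule$sample_rate,
                     class = c("raw_recording", "data.frame"))
    proto_path <- file.path(out_dir, "protocol.csv")
    protocol <- if (file.exists(proto_path)) {
      ev <- read.csv(proto_path)
      structure(ev, total_duration = max(ev$onset + ev$duration),
                class = c("experiment_protocol", "data.frame"))
    } else {
      generate_protocol(cfg$n_trials,
                        long_rest_duration = cfg$long_rest_duration,
                        seed = cfg$seed)
    }
    res <- run_bci_pipeline(rec, protocol, obj$constants,
                            k = cfg$cv_folds, seed = cfg$seed)
    say("mean CV accuracy %.3f (p = %.3g)", res$cv$mean_accuracy, res$cv$p_value)
    feat_path <- file.path(out_dir, "features.csv")
    write.csv(as.data.frame(res$features), feat_path, row.names = FALSE)
    cv_path <- file.path(out_dir, "cv_result.json")
    jsonlite::write_json(
      list(fold_accuracy = res$cv$fold_accuracy,
           mean_accuracy = res$cv$mean_accuracy,
           p_value = res$cv$p_value),
      cv_path, auto_unbox = TRUE, digits = NA)
    avg_path <- file.path(out_dir, "average_response.csv")
    avg_df <- do.call(rbind, lapply(names(res$avg), function(cond) {
      a <- res$avg[[cond]]
      data.frame(condition = cond, t = a$t,
                 hbo_mean_ch1 = a$hbo$mean[, 1], hbo_se_ch1 = a$hbo$se[, 1],
                 hbr_mean_ch1 = a$hbr$mean[, 1], hbr_se_ch1 = a$hbr$se[, 1])
    }))
    write.csv(avg_df, avg_path, row.names = FALSE)
    invisible(list(cv = res$cv, features = feat_path, cv_json = cv_path,
                   average_response = avg_path))
  } else {  # protocol-trace
    events <- encode_control(obj$schedule, n_frames = 1L)
    timeline <- decode_control(events)
    path <- file.path(out_dir, "protocol_trace.csv")
    write.csv(timeline, path, row.names = FALSE)
    say("decoded %d state changes", nrow(timeline))
    invisible(list(timeline = timeline, csv = path))
  }
}
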