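#' Default run configuration
#'
#' The full configuration tree with every default matching the published
#' constants: 95/105 bpm boundaries, 9.13 bpm band-2 offset, scenario-2
#' initial 10 s within \[5, 15\] s, scenario-3 initial 0.366 with 0.1 steps
#' capped at 5 x 0.366, the 80 bpm / 20 s test-scenario rule, and 1 Hz
#' sampling.
#'
#' @return A nested list of class `run_config` with sections `signal`,
#'   `engine`, `sim`, `eval`, `io`.
#' @export
default_run_config <- function() {
  structure(list(
    signal = list(
      scale = list(hr_lo = 60, hr_hi = 200),
      calibration = list(band2_offset_bpm = 9.13, outlier_floor_bpm = 40,
                         outlier_ceiling_bpm = 220)),
    engine = list(
      thresholds = list(hr_threshold = 95, hr_upper = 105,
                        hysteresis_enabled = FALSE),
      scenario1 = list(vh = 10, deltaD = 100, vh_range = c(1, 100),
                       deltaD_range = c(1, 10000)),
      scenario2 = list(allotted = 10),
      scenario3 = list(gen_rate = 0.366, step = 0.1, rate_cap = 5 * 0.366,
                       rate_floor = 0.1),
      test_scenario = list(speed = 1, cadence_s = 20, hr_cut = 80),
      mode = "intent", interpretation = "rate", warmup = 5),
    sim = list(
      n_participants = 30, master_seed = 1,
      protocol = list(play_duration_s = 600, rest_duration_s = 600,
                      sampling_hz = 1),
      participant = list(tau = 30, effort_gain = 0.35, noise_sd = 2),
      arm_effect_bpm = 0),
    eval = list(conf_level = 0.95),
    io = list(format = "csv")),
    class = "run_config")
}

deep_merge <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- deep_merge(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads the YAML file, merges it over [default_run_config()] (so partial
#' configurations are fine) and validates the result.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- structure(deep_merge(unclass(cfg), user), class = "run_config")
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks structural and numeric invariants and reports the path of the
#' first failure.
#'
#' @param cfg A `run_config`.
#' @return The config, invisibly usable; stops on violation.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(ok, path) {
    if (!isTRUE(ok)) stop("invalid config at ", path)
  }
  chk(cfg$signal$scale$hr_lo < cfg$signal$scale$hr_hi, "signal.scale")
  chk(cfg$signal$calibration$outlier_floor_bpm <
        cfg$signal$calibration$outlier_ceiling_bpm, "signal.calibration")
  chk(is.finite(cfg$signal$calibration$band2_offset_bpm),
      "signal.calibration.band2_offset_bpm")
  chk(cfg$engine$thresholds$hr_threshold <= cfg$engine$thresholds$hr_upper,
      "engine.thresholds")
  chk(cfg$engine$scenario2$allotted >= 5 && cfg$engine$scenario2$allotted <= 15,
      "engine.scenario2.allotted")
  chk(cfg$engine$scenario3$rate_floor < cfg$engine$scenario3$rate_cap,
      "engine.scenario3")
  chk(cfg$engine$mode %in% c("intent", "literal"), "engine.mode")
  chk(cfg$engine$interpretation %in% c("rate", "period"),
      "engine.interpretation")
  chk(cfg$sim$protocol$play_duration_s > 0 &&
        cfg$sim$protocol$rest_duration_s > 0 &&
        cfg$sim$protocol$sampling_hz > 0, "sim.protocol")
  chk(cfg$sim$participant$tau > 0, "sim.participant.tau")
  cfg
}

#' Write a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

thresholds_from_config <- function(cfg) {
  thresholds(cfg$engine$thresholds$hr_threshold,
             cfg$engine$thresholds$hr_upper,
             cfg$engine$thresholds$hysteresis_enabled)
}

#' Simulate a cohort and write its logs (CLI backend)
#'
#' Simulates the configured crossover cohort and writes one CSV + events
#' JSONL per participant-arm (named `<id>_<arm>`) plus a `manifest.json`
#' stamping the run id, engine mode, interpretation and seeds, then echoes
#' a one-line summary.
#'
#' @param out_dir Output directory.
#' @param config Path to a YAML config, a `run_config`, or `NULL` for
#'   defaults.
#' @param n,seed Optional overrides of `sim.n_participants` and
#'   `sim.master_seed`.
#' @return Invisibly, a list with `status` (0 on success), `manifest` and
#'   the output paths.
#' @export
cmd_simulate <- function(out_dir, config = NULL, n = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) validate_run_config(config)
         else load_run_config(config)
  if (!is.null(n)) cfg$sim$n_participants <- n
  if (!is.null(seed)) cfg$sim$master_seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proto <- protocol_config(cfg$sim$protocol$play_duration_s,
                           cfg$sim$protocol$rest_duration_s,
                           cfg$sim$protocol$sampling_hz)
  cohort <- simulate_cohort(
    n = cfg$sim$n_participants, master_seed = cfg$sim$master_seed, protocol = proto,
    arm_effect_bpm = cfg$sim$arm_effect_bpm,
    thr = thresholds_from_config(cfg), mode = cfg$engine$mode,
    interpretation = cfg$engine$interpretation,
    warmup = cfg$engine$warmup,
    tau = cfg$sim$participant$tau,
    effort_gain = cfg$sim$participant$effort_gain,
    noise_sd = cfg$sim$participant$noise_sd)
  files <- character(0)
  for (el in cohort) {
    for (arm in c("UAS", "CIS")) {
      stem <- file.path(out_dir, sprintf("%s_%s", el$participant$id, arm))
      write_session_log(el[[arm]], stem)
      files <- c(files, paste0(stem, ".csv"))
    }
  }
  manifest <- list(run = sprintf("hradapt-sim-seed%d", cfg$sim$master_seed),
                   n = cfg$sim$n_participants, master_seed = cfg$sim$master_seed,
                   mode = cfg$engine$mode,
                   interpretation = cfg$engine$interpretation,
                   sessions = basename(files))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("simulated %d participants x 2 arms -> %d session logs in %s",
                  length(cohort), length(files), out_dir))
  invisible(list(status = 0L, manifest = mpath, files = files,
                 cohort = cohort))
}

#' Replay a recorded session through the engine (regression harness)
#'
#' Re-runs the adaptation engine over the session's recorded calibrated HR
#' stream and per-tick inputs (presses and block outcomes are embedded in
#' each row's state snapshot) and verifies that the recomputed window
#' statistics and controller state match the recorded trace bit-for-bit.
#'
#' @param log A [session_log()] or a path to one.
#' @param thr A [thresholds()].
#' @param mode,interpretation Engine options the replay runs under; a
#'   mismatch with the options the log was recorded under is reported as a
#'   divergence at the first affected tick.
#' @param warmup Window fill below which controllers do not adapt.
#' @param arm_adaptive Override adaptivity (default from the log's arm).
#' @return List with `ok` and, when `FALSE`, `first_divergence` (row
#'   number) and `detail`.
#' @export
replay_session <- function(log, thr = thresholds(),
                           mode = c("intent", "literal"),
                           interpretation = c("rate", "period"),
                           warmup = 5L, arm_adaptive = NULL) {
  if (is.character(log)) log <- read_session_log(log)
  mode <- match.arg(mode)
  interpretation <- match.arg(interpretation)
  adaptive <- if (is.null(arm_adaptive)) log$arm == "UAS" else arm_adaptive
  r <- log$rows
  win <- scaled_window()
  scfg <- scale_config()
  state <- NULL; cur <- ""
  for (i in seq_len(nrow(r))) {
    key <- as.character(r$scenario[i])
    if (!identical(key, cur)) {
      cur <- key
      state <- switch(key,
        "1" = scenario1_state(mode = mode),
        "2" = scenario2_state(),
        "3" = scenario3_state(interpretation = interpretation),
        "test" = test_scenario_state(),
        stop("unknown scenario id in log: ", key))
    }
    win <- push_sample(win, r$hr_cal[i], scfg)
    wv <- window_weight(win)
    av <- avg_hr(win)
    if (wv != r$w[i] || av != r$avg_hr[i]) {
      return(list(ok = FALSE, first_divergence = i,
                  detail = "window statistics differ"))
    }
    inputs <- NULL
    if (length(win$values) >= warmup) {
      rec <- jsonlite::fromJSON(r$state_json[i])
      if (key == "1") {
        state <- step_scenario1(state, av, wv, thr, adaptive)
      } else if (key == "2") {
        press <- isTRUE(rec$press == 1)
        state <- step_scenario2(state, press, av, 1, thr, adaptive)
        inputs <- list(press = as.integer(press))
      } else if (key == "3") {
        blocks <- if (is.null(rec$blocks)) "" else rec$blocks
        if (nzchar(blocks)) {
          for (ch in strsplit(blocks, "")[[1]]) {
            hit <- ch == "p"
            state <- step_scenario3(state, hit, hit, av, thr, adaptive)
          }
        }
        inputs <- list(blocks = blocks)
      } else if (key == "test") {
        state <- step_test_scenario(state, r$hr_cal[i], 1, adaptive)
      }
    }
    got <- state_to_json(state, inputs)
    if (!identical(got, r$state_json[i])) {
      return(list(ok = FALSE, first_divergence = i,
                  detail = sprintf("state trace differs: got %s, recorded %s",
                                   got, r$state_json[i])))
    }
  }
  list(ok = TRUE, first_divergence = NA_integer_, detail = "trace matches")
}

#' Replay command (CLI backend)
#'
#' @param session_csv Path to a session CSV written by
#'   [write_session_log()].
#' @param config Path to a YAML config, a `run_config`, or `NULL`.
#' @param mode,interpretation Optional engine-option overrides.
#' @return Invisibly, list with `status` (0 match, 1 divergence) and the
#'   [replay_session()] result.
#' @export
cmd_replay <- function(session_csv, config = NULL, mode = NULL,
                       interpretation = NULL) {
  cfg <- if (inherits(config, "run_config")) validate_run_config(config)
         else load_run_config(config)
  if (!is.null(mode)) cfg$engine$mode <- mode
  if (!is.null(interpretation)) cfg$engine$interpretation <- interpretation
  res <- replay_session(session_csv, thr = thresholds_from_config(cfg),
                        mode = cfg$engine$mode,
                        interpretation = cfg$engine$interpretation,
                        warmup = cfg$engine$warmup)
  if (res$ok) {
    message("replay: state trace matches bit-for-bit")
  } else {
    message(sprintf("replay: divergence at tick %d (%s)",
                    res$first_divergence, res$detail))
  }
  invisible(list(status = if (res$ok) 0L else 1L, result = res))
}

#' Evaluate sessions or printed summaries (CLI backend)
#'
#' Given a directory of session logs (named `<id>_<arm>.csv`), builds the
#' per-participant scenario-level variables, runs the paired tests and
#' renders the descriptive + inferential tables. Given a summaries CSV
#' (columns `label,mean_diff,sd_diff,n`, e.g. the packaged worked-example
#' rows), reproduces the inferential table directly from the summaries.
#'
#' @param input Directory of session CSVs, or a summaries CSV path.
#' @param out_dir Output directory for the rendered tables.
#' @param conf_level Confidence level (default 0.95).
#' @return Invisibly, list with `status`, `tests` and rendered paths.
#' @export
cmd_evaluate <- function(input, out_dir, conf_level = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (dir.exists(input)) {
    csvs <- list.files(input, pattern = "_(UAS|CIS)\\.csv$",
                       full.names = TRUE)
    if (length(csvs) == 0L) stop("nothing analyzable in ", input)
    pids <- unique(sub("_(UAS|CIS)\\.csv$", "", basename(csvs)))
    cohort <- lapply(pids, function(pid) {
      el <- list(participant = list(id = pid))
      for (arm in c("UAS", "CIS")) {
        f <- file.path(input, sprintf("%s_%s.csv", pid, arm))
        if (file.exists(f)) el[[arm]] <- read_session_log(f)
      }
      el
    })
    vars <- build_variables(cohort)
    tests <- paired_tests(vars, conf_level)
    paths <- render_tables(vars, tests, out_dir)
  } else if (file.exists(input)) {
    summaries <- read_paired_summaries(input)
    tests <- lapply(summaries, paired_t_from_summary,
                    conf_level = conf_level)
    paths <- render_tables(NULL, tests, out_dir)
  } else {
    stop("input not found: ", input)
  }
  message(sprintf("evaluated %d paired variables -> %s", length(tests),
                  out_dir))
  invisible(list(status = 0L, tests = tests, paths = paths))
}
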