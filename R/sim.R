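#' Synthetic child participant
#'
#' Parameters of the first-order exertion surrogate used to close the
#' control loop. Heart rate relaxes toward a demand-dependent target with
#' time constant `tau`; the target interpolates between resting HR and a
#' fraction `effort_gain` of the heart-rate reserve, the reserve being
#' `hr_max - resting_hr` with the age-capped maximum `220 - age`. Gaussian
#' measurement/physiological noise is added per sample. The calorie
#' surrogate is linear in HR above rest: `max(0, c0 + c1*(hr - resting))`
#' kcal per second, with defaults chosen so a few minutes of moderate play
#' accumulate single-digit-to-low-teens kcal per scenario.
#'
#' @param age Age in years, within \[5, 7\].
#' @param resting_hr Resting HR in bpm (the 70-90 band for this age).
#' @param hr_max Maximal HR in bpm, default `220 - age`.
#' @param tau HR response time constant in seconds (default 30).
#' @param effort_gain Fraction of the HR reserve recruited at maximal game
#'   demand, in (0, 1\] (default 0.35).
#' @param noise_sd Per-sample noise standard deviation in bpm (default 2).
#' @param skill Press-success parameters: list with `p_max` (success
#'   probability at minimal difficulty) and `p_min` (at maximal), default
#'   0.95 and 0.45.
#' @param kcal_c0,kcal_c1 Calorie surrogate constants, kcal/s and
#'   kcal/s/bpm (defaults 0.01 and 0.0012).
#' @param distraction Probability that a press attempt is abandoned (field
#'   adherence knob; default 0, off).
#' @param seed RNG seed for this participant's sessions.
#' @param id Participant identifier.
#' @return A list of class `sim_participant`.
#' @export
sim_participant <- function(age = 6, resting_hr = 80, hr_max = 220 - age,
                            tau = 30, effort_gain = 0.35, noise_sd = 2,
                            skill = list(p_max = 0.95, p_min = 0.45),
                            kcal_c0 = 0.01, kcal_c1 = 0.0012,
                            distraction = 0, seed = 1L, id = "P1") {
  stopifnot(age >= 5, age <= 7, resting_hr < hr_max, tau > 0,
            effort_gain > 0, effort_gain <= 1, noise_sd >= 0,
            skill$p_max >= skill$p_min, skill$p_min >= 0, skill$p_max <= 1,
            distraction >= 0, distraction < 1)
  structure(list(age = age, resting_hr = resting_hr, hr_max = hr_max,
                 tau = tau, effort_gain = effort_gain, noise_sd = noise_sd,
                 skill = skill, kcal_c0 = kcal_c0, kcal_c1 = kcal_c1,
                 distraction = distraction, seed = as.integer(seed),
                 id = as.character(id)),
            class = "sim_participant")
}

#' Crossover session protocol
#'
#' Each participant plays one arm for 10 minutes, rests for 10 minutes to
#' let HR return to baseline, then plays the other arm for 10 minutes.
#' Play time is split into equal thirds across the session's scenarios
#' (the published protocol gives no per-scenario split).
#'
#' @param play_duration_s Play time per arm, seconds (default 600).
#' @param rest_duration_s Rest between arms, seconds (default 600).
#' @param sampling_hz Sampling rate, Hz (default 1).
#' @param arms_order Character vector giving the arm order (default
#'   `c("CIS", "UAS")`).
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(play_duration_s = 600, rest_duration_s = 600,
                            sampling_hz = 1, arms_order = c("CIS", "UAS")) {
  stopifnot(play_duration_s > 0, rest_duration_s > 0, sampling_hz > 0,
            setequal(arms_order, c("CIS", "UAS")))
  structure(list(play_duration_s = play_duration_s,
                 rest_duration_s = rest_duration_s,
                 sampling_hz = sampling_hz, arms_order = arms_order),
            class = "protocol_config")
}

#' Map a controller state to game demand in [0, 1]
#'
#' Demand normalises each controller's difficulty variable over its own
#' clamp range, so demand lies in \[0, 1\] by construction: scenario 1 uses
#' the speed `vh` over its clamp range, scenario 2 uses `(15 - allotted)/10`,
#' scenario 3 uses the generation rate over `[rate_floor, rate_cap]`, and
#' the test scenario normalises its speed over a ten-unit band above the
#' floor. Rest demand is 0.
#'
#' @param state A scenario state, or `NULL` for rest.
#' @return Demand in \[0, 1\].
#' @export
demand_for_state <- function(state) {
  if (is.null(state)) return(0)
  d <- if (inherits(state, "scenario1_state")) {
    (state$vh - state$vh_range[1]) / diff(state$vh_range)
  } else if (inherits(state, "scenario2_state")) {
    (15 - state$allotted) / 10
  } else if (inherits(state, "scenario3_state")) {
    (state$gen_rate - state$rate_floor) / (state$rate_cap - state$rate_floor)
  } else if (inherits(state, "test_scenario_state")) {
    (state$speed - state$floor) / 10
  } else stop("unknown state type")
  min(1, max(0, d))
}

#' One Euler step of the first-order heart-rate response
#'
#' `hr` moves toward `resting + demand * effort_gain * (hr_max - resting)`
#' at rate `dt / tau`, with additive Gaussian noise of standard deviation
#' `noise_sd * sqrt(dt)`, clamped to \[40, hr_max\].
#'
#' @param hr Current HR, bpm.
#' @param demand Game demand in \[0, 1\].
#' @param p A [sim_participant()].
#' @param dt Step size in seconds (> 0).
#' @param z Standard-normal noise draw (default a fresh draw; pass 0 for
#'   the deterministic skeleton).
#' @return The next HR in bpm.
#' @export
hr_step <- function(hr, demand, p, dt = 1, z = stats::rnorm(1)) {
  stopifnot(demand >= 0, demand <= 1, dt > 0)
  target <- p$resting_hr + demand * p$effort_gain * (p$hr_max - p$resting_hr)
  hr <- hr + (target - hr) * dt / p$tau + p$noise_sd * sqrt(dt) * z
  min(p$hr_max, max(40, hr))
}

#' Calorie increment for one step
#'
#' Linear-in-HR-reserve surrogate: `max(0, c0 + c1*(hr - resting_hr)) * dt`.
#'
#' @param hr Current HR, bpm.
#' @param p A [sim_participant()].
#' @param dt Step size in seconds (> 0).
#' @return Non-negative kcal increment.
#' @export
kcal_step <- function(hr, p, dt = 1) {
  stopifnot(dt > 0)
  max(0, p$kcal_c0 + p$kcal_c1 * (hr - p$resting_hr)) * dt
}

#' Press-success probability at a given difficulty
#'
#' Linear interpolation from `p_max` at zero demand to `p_min` at maximal
#' demand, times `(1 - distraction)`.
#'
#' @param demand Demand in \[0, 1\].
#' @param p A [sim_participant()].
#' @return Success probability in \[0, 1\].
#' @export
press_success_prob <- function(demand, p) {
  stopifnot(demand >= 0, demand <= 1)
  (p$skill$p_max - (p$skill$p_max - p$skill$p_min) * demand) *
    (1 - p$distraction)
}

#' Draw one press outcome for the current scenario state
#'
#' Success probability decreases linearly with the state's demand
#' ([demand_for_state()], [press_success_prob()]); the latency is the
#' fraction of the available time at which the press lands, drawn uniformly
#' on \[0.2, 0.8\].
#'
#' @param state A scenario state.
#' @param p A [sim_participant()].
#' @return List with `success` (logical) and `latency_frac` in \[0.2, 0.8\].
#' @export
press_behavior <- function(state, p) {
  prob <- press_success_prob(demand_for_state(state), p)
  list(success = stats::runif(1) < prob,
       latency_frac = stats::runif(1, 0.2, 0.8))
}

# deterministic %.17g serialisation of a controller state + tick inputs
state_to_json <- function(state, inputs = NULL) {
  g <- function(x) {
    if (is.finite(x) && x == floor(x) && abs(x) < 1e15) sprintf("%.0f", x)
    else sprintf("%.17g", x)
  }
  core <- if (inherits(state, "scenario1_state")) {
    sprintf('"s":"1","d":%s,"deltaD":%s,"vh":%s',
            g(state$d), g(state$deltaD), g(state$vh))
  } else if (inherits(state, "scenario2_state")) {
    sprintf('"s":"2","allotted":%s,"timer":%s,"points":%d',
            g(state$allotted), g(state$timer), state$points)
  } else if (inherits(state, "scenario3_state")) {
    sprintf('"s":"3","gen_rate":%s,"points":%d', g(state$gen_rate),
            state$points)
  } else if (inherits(state, "test_scenario_state")) {
    sprintf('"s":"test","speed":%s,"elapsed":%s', g(state$speed),
            g(state$elapsed))
  } else stop("unknown state type")
  inp <- if (is.null(inputs) || length(inputs) == 0L) "" else {
    paste0(",", paste(vapply(names(inputs), function(k) {
      v <- inputs[[k]]
      if (is.character(v)) sprintf('"%s":"%s"', k, v)
      else sprintf('"%s":%s', k, g(as.numeric(v)))
    }, character(1)), collapse = ","))
  }
  paste0("{", core, inp, "}")
}

# split n ticks into equal thirds (remainder to the last segment)
segment_bounds <- function(n_ticks, scenarios) {
  k <- length(scenarios)
  per <- n_ticks %/% k
  starts <- (seq_len(k) - 1L) * per + 1L
  ends <- starts + per - 1L
  ends[k] <- n_ticks
  data.frame(scenario = as.character(scenarios), start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Simulate one participant-arm play session
#'
#' Runs the closed loop at the sampling cadence: the active controller's
#' state sets the game demand, HR relaxes toward the demand-dependent
#' target ([hr_step()]), the 20-sample window yields `w` and `avgHR`, and
#' the controller consumes them to update difficulty. The adaptive arm
#' (`"UAS"`) uses adaptive controllers; the conventional arm (`"CIS"`)
#' uses frozen ones. Scenarios run in equal-length segments; the HR window
#' persists across segments, controllers and cumulative kcal reset at each
#' `activityStarted`. Controllers do not adapt until the window holds at
#' least `warmup` samples. Deterministic given the participant's seed.
#'
#' @param p A [sim_participant()].
#' @param arm `"UAS"` or `"CIS"`.
#' @param scenarios Scenario ids played in order (default `c(1, 2, 3)`).
#' @param protocol A [protocol_config()].
#' @param thr A [thresholds()].
#' @param mode Scenario-1 sign mode, `"intent"` or `"literal"`.
#' @param interpretation Scenario-3 unit reading, `"rate"` or `"period"`.
#' @param warmup Minimum window fill before controllers adapt (default 5).
#' @param arm_effect_bpm Measurement-level HR offset added to the recorded
#'   signal of the UAS arm only; used by recovery experiments where the
#'   true between-arm effect must be known exactly (default 0).
#' @param adaptive Override the arm's adaptivity (default: `arm == "UAS"`);
#'   lets recovery experiments run both arms frozen.
#' @return A [session_log()].
#' @export
simulate_session <- function(p, arm = c("UAS", "CIS"),
                             scenarios = c(1, 2, 3),
                             protocol = protocol_config(),
                             thr = thresholds(),
                             mode = c("intent", "literal"),
                             interpretation = c("rate", "period"),
                             warmup = 5L, arm_effect_bpm = 0,
                             adaptive = NULL) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  interpretation <- match.arg(interpretation)
  if (is.null(adaptive)) adaptive <- arm == "UAS"
  set.seed(p$seed * 2L + (arm == "UAS"))
  dt <- 1 / protocol$sampling_hz
  n_ticks <- round(protocol$play_duration_s * protocol$sampling_hz)
  segs <- segment_bounds(n_ticks, scenarios)

  t_col <- numeric(n_ticks); raw <- numeric(n_ticks); cal <- numeric(n_ticks)
  avg <- numeric(n_ticks); w_col <- numeric(n_ticks)
  scen_col <- character(n_ticks); sj <- character(n_ticks)
  pts <- integer(n_ticks); kcal_col <- numeric(n_ticks)
  events <- list()
  add_event <- function(e) events[[length(events) + 1L]] <<- e
  add_event(game_event("signalActivation", 0, scenarios[1]))

  win <- scaled_window()
  scfg <- scale_config()
  hr <- p$resting_hr
  offset <- if (arm == "UAS") arm_effect_bpm else 0
  i <- 0L
  for (s in seq_len(nrow(segs))) {
    key <- segs$scenario[s]
    ctrl <- make_controller(key, adaptive = adaptive, thr = thr,
      init = if (key == "1") scenario1_state(mode = mode)
             else if (key == "3") scenario3_state(interpretation = interpretation)
             else NULL)
    state <- ctrl$state
    add_event(game_event("activityStarted", (segs$start[s] - 1L) * dt, key))
    kcal <- 0
    # scenario-2 round plan; scenario-3 spawn accumulator
    round_tick <- 0L; plan <- NULL; acc <- 0
    if (key == "2") plan <- plan_round(state, p)
    for (tick in segs$start[s]:segs$end[s]) {
      i <- i + 1L
      demand <- demand_for_state(state)
      hr <- hr_step(hr, demand, p, dt)
      measured <- hr + offset
      win <- push_sample(win, measured, scfg)
      wv <- window_weight(win)
      av <- avg_hr(win)
      adapt_ok <- length(win$values) >= warmup
      inputs <- NULL
      if (adapt_ok) {
        if (key == "1") {
          state <- step_scenario1(state, av, wv, thr, adaptive)
        } else if (key == "2") {
          round_tick <- round_tick + 1L
          press <- isTRUE(plan$success) && round_tick == plan$press_at
          before <- state$allotted
          state <- step_scenario2(state, press, av, dt, thr, adaptive)
          inputs <- list(press = as.integer(press))
          if (state$timer == state$allotted) {  # terminal event: new round
            plan <- plan_round(state, p)
            round_tick <- 0L
          }
        } else if (key == "3") {
          acc <- acc + state$gen_rate * dt
          outcomes <- character(0)
          while (acc >= 1) {
            acc <- acc - 1
            hit <- stats::runif(1) < press_success_prob(
              demand_for_state(state), p)
            state <- step_scenario3(state, hit, hit, av, thr, adaptive)
            outcomes <- c(outcomes, if (hit) "p" else "m")
          }
          inputs <- list(blocks = paste(outcomes, collapse = ""))
        } else if (key == "test") {
          state <- step_test_scenario(state, measured, dt, adaptive)
        }
      }
      kcal <- kcal + kcal_step(measured, p, dt)
      t_col[i] <- (tick - 1L) * dt
      raw[i] <- measured; cal[i] <- measured
      avg[i] <- av; w_col[i] <- wv
      scen_col[i] <- key
      sj[i] <- state_to_json(state, inputs)
      pts[i] <- if (!is.null(state$points)) state$points else 0L
      kcal_col[i] <- kcal
    }
    tend <- segs$end[s] * dt
    add_event(game_event("activityFinished", tend, key,
                         list(completed = TRUE)))
    add_event(game_event("scoreObtained", tend, key,
                         list(score = if (!is.null(state$points))
                           state$points else 0L)))
  }
  rows <- data.frame(t = t_col, hr_raw = raw, hr_cal = cal, avg_hr = avg,
                     w = w_col, scenario = scen_col, state_json = sj,
                     points = pts, kcal = kcal_col, stringsAsFactors = FALSE)
  session_log(p$id, arm, rows, events)
}

# draw one scenario-2 round plan: outcome + the tick (1-based within the
# round) at which a successful press lands, always leaving timer > 0
plan_round <- function(state, p) {
  b <- press_behavior(state, p)
  horizon <- max(1L, as.integer(floor(state$allotted)) - 1L)
  press_at <- max(1L, min(horizon, as.integer(ceiling(b$latency_frac *
                                                        state$allotted))))
  list(success = b$success, press_at = press_at)
}

#' Draw a cohort of synthetic participants
#'
#' Ages are drawn uniformly from \{5, 6, 7\}, resting HR uniformly from the
#' 70-90 bpm band; per-participant seeds are derived reproducibly from the
#' master seed.
#'
#' @param n Number of participants (>= 2).
#' @param master_seed Master RNG seed.
#' @param ... Overrides passed to every [sim_participant()] (e.g. `tau`,
#'   `effort_gain`).
#' @return List of `sim_participant`s.
#' @export
draw_participants <- function(n, master_seed = 1L, ...) {
  stopifnot(n >= 2)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max %/% 4L, n)
  ages <- sample(5:7, n, replace = TRUE)
  rest <- stats::runif(n, 70, 90)
  lapply(seq_len(n), function(i) {
    sim_participant(age = ages[i], resting_hr = rest[i], seed = seeds[i],
                    id = sprintf("P%02d", i), ...)
  })
}

#' Simulate a paired crossover cohort
#'
#' Each participant plays both arms with identical physiological parameters
#' and independent noise streams, mirroring the within-subject crossover
#' design (the rest period returns HR to baseline, so each session starts
#' at resting HR).
#'
#' @param n Number of participants.
#' @param master_seed Master RNG seed.
#' @param protocol A [protocol_config()].
#' @param scenarios Scenario ids per session.
#' @param arm_effect_bpm See [simulate_session()].
#' @param adaptive_uas If `FALSE`, the UAS-labelled arm also runs frozen
#'   controllers (recovery experiments).
#' @param thr,mode,interpretation,warmup Engine options passed to
#'   [simulate_session()] for both arms.
#' @param participants Optional pre-built list of [sim_participant()]s
#'   (overrides `n`/`master_seed` draws).
#' @param ... Overrides passed to [draw_participants()].
#' @return List of class `cohort`: one element per participant with fields
#'   `participant`, `UAS`, `CIS` (the two [session_log()]s).
#' @export
simulate_cohort <- function(n = 30, master_seed = 1L,
                            protocol = protocol_config(),
                            scenarios = c(1, 2, 3), arm_effect_bpm = 0,
                            adaptive_uas = TRUE, thr = thresholds(),
                            mode = "intent", interpretation = "rate",
                            warmup = 5L, participants = NULL, ...) {
  if (is.null(participants)) {
    participants <- draw_participants(n, master_seed, ...)
  }
  out <- lapply(participants, function(p) {
    list(participant = p,
         UAS = simulate_session(p, "UAS", scenarios, protocol, thr = thr,
                                mode = mode,
                                interpretation = interpretation,
                                warmup = warmup,
                                arm_effect_bpm = arm_effect_bpm,
                                adaptive = adaptive_uas),
         CIS = simulate_session(p, "CIS", scenarios, protocol, thr = thr,
                                mode = mode,
                                interpretation = interpretation,
                                warmup = warmup))
  })
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants x 2 arms (%d session logs)\n",
              length(x), 2L * length(x)))
  invisible(x)
}
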