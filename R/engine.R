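#' Heart-rate boundaries used by the difficulty controllers
#'
#' The adaptation rules compare the running average heart rate against a
#' lower boundary of 95 bpm; an upper boundary of 105 bpm was also defined
#' for this age group but does not appear in the published update rules. It
#' is stored here and only used when the optional hysteresis mode is
#' enabled, in which case difficulty hardens only below the lower boundary
#' and eases only above the upper one (the band in between holds difficulty
#' steady).
#'
#' Ties at the lower boundary (avgHR exactly equal) take the high-exertion
#' branch: the published branches use strict inequalities on both sides,
#' leaving equality undefined, and easing difficulty is the safer reading
#' for the target population.
#'
#' @param hr_threshold Lower HR boundary in bpm (default 95).
#' @param hr_upper Upper HR boundary in bpm (default 105).
#' @param hysteresis_enabled Enable the dead-band mode (default `FALSE`).
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(hr_threshold = 95, hr_upper = 105,
                       hysteresis_enabled = FALSE) {
  if (hr_threshold > hr_upper) stop("hr_threshold must not exceed hr_upper")
  structure(list(hr_threshold = hr_threshold, hr_upper = hr_upper,
                 hysteresis_enabled = isTRUE(hysteresis_enabled)),
            class = "thresholds")
}

# Exertion side of the boundary: +1 harden (low HR), -1 ease (high HR),
# 0 hold (inside the hysteresis dead band).
exertion_side <- function(avgHR, thr) {
  if (!is.finite(avgHR)) stop("avgHR must be finite")
  if (thr$hysteresis_enabled) {
    if (avgHR < thr$hr_threshold) 1L else if (avgHR >= thr$hr_upper) -1L else 0L
  } else {
    if (avgHR < thr$hr_threshold) 1L else -1L
  }
}

clamp <- function(x, lo, hi) min(hi, max(lo, x))

#' State of the scenario-1 (flying character) controller
#'
#' The character moves horizontally at speed `vh`; each controller tick
#' advances the travelled distance `d` by one unit until the current goal
#' distance `deltaD` is spanned, at which point both the goal distance and
#' the speed are re-scaled by the smoothing weight `w`.
#'
#' The published update for the goal-completion branch under low heart rate
#' prints a speed *decrement* while the accompanying prose describes an
#' increment. `mode = "intent"` (default) follows the prose (+); `mode =
#' "literal"` reproduces the printed sign (-). Both are first-class.
#'
#' @param d Travelled distance, game units (>= 0).
#' @param deltaD Current goal distance, game units (> 0), clamped to
#'   `deltaD_range`.
#' @param vh Displacement speed, game units, clamped to `vh_range`.
#' @param mode `"intent"` or `"literal"`.
#' @param vh_range,deltaD_range Positive clamp ranges for `vh` and `deltaD`.
#' @return A list of class `scenario1_state`.
#' @export
scenario1_state <- function(d = 0, deltaD = 100, vh = 10,
                            mode = c("intent", "literal"),
                            vh_range = c(1, 100),
                            deltaD_range = c(1, 10000)) {
  mode <- match.arg(mode)
  stopifnot(d >= 0, deltaD > 0, vh > 0,
            length(vh_range) == 2L, vh_range[1] > 0, vh_range[1] < vh_range[2],
            length(deltaD_range) == 2L, deltaD_range[1] > 0,
            deltaD_range[1] < deltaD_range[2])
  structure(list(d = d, deltaD = deltaD, vh = vh, mode = mode,
                 vh_range = as.numeric(vh_range),
                 deltaD_range = as.numeric(deltaD_range)),
            class = "scenario1_state")
}

#' One tick of the scenario-1 speed controller
#'
#' Exactly one branch fires per tick:
#' \itemize{
#'   \item distance not yet spanned and avgHR below threshold: `d` advances
#'     by one unit;
#'   \item distance spanned and avgHR below threshold: `d` resets, the goal
#'     grows (`deltaD <- deltaD + deltaD*w`), then the speed is updated with
#'     the *updated* goal (`vh <- vh + deltaD*w` in intent mode, `-` in
#'     literal mode) — the update order follows the published statement
#'     order;
#'   \item avgHR at or above threshold: `d` resets and both the goal and the
#'     speed shrink (`deltaD <- deltaD - deltaD*w`, `vh <- vh - vh*w`).
#' }
#' `deltaD` and `vh` are clamped to their configured positive ranges after
#' every update.
#'
#' @param state A [scenario1_state()].
#' @param avgHR Running average heart rate, bpm.
#' @param w Smoothing weight in \[0, 1\] ([window_weight()]).
#' @param thr A [thresholds()].
#' @param adaptive If `FALSE` (the non-adaptive arm), `deltaD` and `vh` are
#'   frozen; only `d` cycles.
#' @return The updated `scenario1_state`.
#' @export
step_scenario1 <- function(state, avgHR, w, thr = thresholds(),
                           adaptive = TRUE) {
  stopifnot(inherits(state, "scenario1_state"))
  if (!is.finite(w) || w < 0 || w > 1) stop("w must lie in [0, 1]")
  side <- exertion_side(avgHR, thr)
  if (side > 0L && state$d < state$deltaD) {
    state$d <- state$d + 1
    return(state)
  }
  state$d <- 0
  if (!adaptive || side == 0L) return(state)
  if (side > 0L) {
    state$deltaD <- clamp(state$deltaD + state$deltaD * w,
                          state$deltaD_range[1], state$deltaD_range[2])
    dv <- state$deltaD * w
    state$vh <- clamp(if (state$mode == "intent") state$vh + dv
                      else state$vh - dv,
                      state$vh_range[1], state$vh_range[2])
  } else {
    state$deltaD <- clamp(state$deltaD - state$deltaD * w,
                          state$deltaD_range[1], state$deltaD_range[2])
    state$vh <- clamp(state$vh - state$vh * w,
                      state$vh_range[1], state$vh_range[2])
  }
  state
}

#' State of the scenario-2 (bathtub countdown) controller
#'
#' Each round the player must cover a 6 m round trip and press the on-screen
#' button before a countdown expires. The *allotted* time per round starts
#' at 10 s and adapts within \[5, 15\] s; `timer` is the time remaining in
#' the current round. The adapted quantity is the allotted time, not the
#' running timer: the published timeout branch (increment from zero) is only
#' coherent under that split.
#'
#' @param allotted Allotted round time in seconds, within \[5, 15\]
#'   (initially 10).
#' @param timer Seconds remaining in the current round (defaults to
#'   `allotted`).
#' @param points Integer score (may go negative).
#' @param round_distance_m Round-trip distance metadata, metres (6).
#' @return A list of class `scenario2_state`.
#' @export
scenario2_state <- function(allotted = 10, timer = allotted, points = 0L,
                            round_distance_m = 6) {
  stopifnot(allotted >= 5, allotted <= 15, timer <= allotted)
  structure(list(allotted = allotted, timer = timer,
                 points = as.integer(points),
                 round_distance_m = round_distance_m),
            class = "scenario2_state")
}

#' One tick of the scenario-2 countdown controller
#'
#' The timer decreases by `dt`. A press with time still remaining scores
#' +1 and adapts the allotted time: one second *less* (floor 5 s) when
#' avgHR is below the threshold — the published rule tightens the budget to
#' demand more effort — and one second *more* (ceiling 15 s) otherwise.
#' A timeout scores -1 and always relaxes the budget by one second
#' (ceiling 15 s). After either terminal event a new round starts with
#' `timer = allotted`.
#'
#' @param state A [scenario2_state()].
#' @param button_pressed Was the button pressed during this tick?
#' @param avgHR Running average heart rate, bpm.
#' @param dt Tick duration in seconds (> 0), default 1.
#' @param thr A [thresholds()].
#' @param adaptive If `FALSE`, `allotted` is frozen; rounds and scoring
#'   proceed identically.
#' @return The updated `scenario2_state`.
#' @export
step_scenario2 <- function(state, button_pressed, avgHR, dt = 1,
                           thr = thresholds(), adaptive = TRUE) {
  stopifnot(inherits(state, "scenario2_state"), dt > 0)
  state$timer <- state$timer - dt
  if (isTRUE(button_pressed) && state$timer > 0) {
    state$points <- state$points + 1L
    if (adaptive) {
      side <- exertion_side(avgHR, thr)
      if (side > 0L) {
        state$allotted <- max(5, state$allotted - 1)
      } else if (side < 0L) {
        state$allotted <- min(15, state$allotted + 1)
      }
    }
    state$timer <- state$allotted
  } else if (state$timer <= 0) {
    state$points <- state$points - 1L
    if (adaptive) state$allotted <- min(15, state$allotted + 1)
    state$timer <- state$allotted
  }
  state
}

#' State of the scenario-3 (falling blocks) controller
#'
#' Blocks fall from a tree at generation rate `gen_rate`, initially 0.366
#' blocks per second; the player must press the matching mat button before
#' a block leaves the screen. The rate adapts in 0.1 steps and is clamped
#' globally to \[`rate_floor`, 5 x 0.366 = 1.83\]: the published per-branch
#' bound placement cannot be honoured literally under either unit reading,
#' so a global clamp — the only reading consistent with both printed
#' bounds — is applied. Under `interpretation = "period"` the same state
#' variable is read as the spawn interval in seconds and the adaptation
#' signs reverse (a shorter interval means more frequent blocks), with the
#' same bounds applied to the interval.
#'
#' @param gen_rate Blocks per second (or seconds per block under the period
#'   interpretation), initially 0.366.
#' @param step Adaptation step (0.1).
#' @param rate_cap Upper clamp (5 x 0.366 = 1.83).
#' @param rate_floor Lower clamp (default 0.1).
#' @param points Integer score.
#' @param interpretation `"rate"` (default) or `"period"`.
#' @return A list of class `scenario3_state`.
#' @export
scenario3_state <- function(gen_rate = 0.366, step = 0.1,
                            rate_cap = 5 * 0.366, rate_floor = 0.1,
                            points = 0L,
                            interpretation = c("rate", "period")) {
  interpretation <- match.arg(interpretation)
  stopifnot(rate_floor < rate_cap, gen_rate >= rate_floor,
            gen_rate <= rate_cap, step > 0)
  structure(list(gen_rate = gen_rate, step = step, rate_cap = rate_cap,
                 rate_floor = rate_floor, points = as.integer(points),
                 interpretation = interpretation),
            class = "scenario3_state")
}

#' One block resolution of the scenario-3 generation-rate controller
#'
#' Called once per resolved block. A correct press while the block is on
#' screen scores +1 and adapts the rate: +0.1 blocks/s (capped at 1.83)
#' when avgHR is below the threshold — blocks come more frequently,
#' demanding more effort — and -0.1 blocks/s (floored) otherwise. A block
#' that leaves the screen unpressed scores -1 and leaves the rate
#' unchanged. A press with no block on screen is a no-op. Under the period
#' interpretation the signs reverse.
#'
#' @param state A [scenario3_state()].
#' @param s_pressed Was the matching button pressed?
#' @param s_onscreen Is the block still on screen?
#' @param avgHR Running average heart rate, bpm.
#' @param thr A [thresholds()].
#' @param adaptive If `FALSE`, `gen_rate` is frozen; scoring proceeds
#'   identically.
#' @return The updated `scenario3_state`.
#' @export
step_scenario3 <- function(state, s_pressed, s_onscreen, avgHR,
                           thr = thresholds(), adaptive = TRUE) {
  stopifnot(inherits(state, "scenario3_state"))
  if (isTRUE(s_pressed) && isTRUE(s_onscreen)) {
    state$points <- state$points + 1L
    if (adaptive) {
      side <- exertion_side(avgHR, thr)
      if (state$interpretation == "period") side <- -side
      if (side > 0L) {
        state$gen_rate <- min(state$rate_cap, state$gen_rate + state$step)
      } else if (side < 0L) {
        state$gen_rate <- max(state$rate_floor, state$gen_rate - state$step)
      }
    }
  } else if (!isTRUE(s_onscreen)) {
    state$points <- state$points - 1L
  }
  state
}

#' State of the architecture-test controller
#'
#' The integration test scenario moves a single block horizontally; its
#' speed steps by one unit every 20 s, upward while the last raw HR reading
#' is below 80 bpm and downward otherwise, clamped below at `floor`.
#'
#' @param speed Block speed, game units.
#' @param cadence_s Update cadence in seconds (20).
#' @param hr_cut Decision boundary on the last reading, bpm (80).
#' @param elapsed Seconds accumulated since the last update.
#' @param floor Lower clamp on the speed (default 0).
#' @return A list of class `test_scenario_state`.
#' @export
test_scenario_state <- function(speed = 1, cadence_s = 20, hr_cut = 80,
                                elapsed = 0, floor = 0) {
  stopifnot(cadence_s > 0, speed >= floor)
  structure(list(speed = speed, cadence_s = cadence_s, hr_cut = hr_cut,
                 elapsed = elapsed, floor = floor),
            class = "test_scenario_state")
}

#' One tick of the architecture-test controller
#'
#' Accumulates elapsed time; for every full cadence consumed, the speed
#' steps +1 if the last HR reading is below the 80 bpm cut and -1
#' otherwise, clamped at the floor.
#'
#' @param state A [test_scenario_state()].
#' @param last_hr Last raw HR reading, bpm.
#' @param dt Tick duration in seconds (> 0).
#' @param adaptive If `FALSE`, the speed is frozen.
#' @return The updated `test_scenario_state`.
#' @export
step_test_scenario <- function(state, last_hr, dt = 1, adaptive = TRUE) {
  stopifnot(inherits(state, "test_scenario_state"), dt > 0)
  state$elapsed <- state$elapsed + dt
  while (state$elapsed >= state$cadence_s) {
    state$elapsed <- state$elapsed - state$cadence_s
    if (adaptive) {
      delta <- if (last_hr < state$hr_cut) 1 else -1
      state$speed <- max(state$floor, state$speed + delta)
    }
  }
  state
}

#' Build a controller for one game scenario
#'
#' Bundles a scenario's initial state and step function into a controller
#' object. `adaptive = FALSE` yields the conventional (non-adaptive) arm:
#' timers, rounds and scoring behave identically but the difficulty
#' variables (`vh`, `allotted`, `gen_rate`, test speed) stay frozen at
#' their initial values.
#'
#' @param scenario One of `1`, `2`, `3` or `"test"`.
#' @param adaptive Adaptive (`TRUE`, default) or frozen difficulty.
#' @param thr A [thresholds()].
#' @param init Optional initial state (defaults to the scenario's default
#'   state constructor).
#' @return A list of class `controller` with fields `scenario`, `adaptive`,
#'   `state` and `step(state, ...)`.
#' @export
make_controller <- function(scenario, adaptive = TRUE, thr = thresholds(),
                            init = NULL) {
  key <- as.character(scenario)
  if (!key %in% c("1", "2", "3", "test")) {
    stop("unknown scenario id: ", key)
  }
  state <- if (!is.null(init)) init else switch(key,
    "1" = scenario1_state(),
    "2" = scenario2_state(),
    "3" = scenario3_state(),
    "test" = test_scenario_state())
  step <- switch(key,
    "1" = function(state, avgHR, w)
      step_scenario1(state, avgHR, w, thr, adaptive),
    "2" = function(state, button_pressed, avgHR, dt = 1)
      step_scenario2(state, button_pressed, avgHR, dt, thr, adaptive),
    "3" = function(state, s_pressed, s_onscreen, avgHR)
      step_scenario3(state, s_pressed, s_onscreen, avgHR, thr, adaptive),
    "test" = function(state, last_hr, dt = 1)
      step_test_scenario(state, last_hr, dt, adaptive))
  structure(list(scenario = key, adaptive = isTRUE(adaptive),
                 state = state, step = step),
            class = "controller")
}

#' Controller with difficulty frozen (conventional interactive system)
#'
#' Convenience wrapper around [make_controller()] with `adaptive = FALSE`:
#' the same scenario logic with pre-defined rules applied uniformly,
#' difficulty never changing from its initial values.
#'
#' @inheritParams make_controller
#' @return A `controller`.
#' @export
make_cis_controller <- function(scenario, thr = thresholds(), init = NULL) {
  make_controller(scenario, adaptive = FALSE, thr = thr, init = init)
}

#' @export
print.controller <- function(x, ...) {
  cat(sprintf("<controller> scenario %s (%s)\n", x$scenario,
              if (x$adaptive) "adaptive" else "frozen difficulty"))
  invisible(x)
}
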