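test_that("the HR response has the documented fixed point, step and asymptote", {
  p <- quiet_participant()
  # resting is a fixed point at zero demand
  expect_equal(hr_step(p$resting_hr, 0, p, z = 0), p$resting_hr)
  # exact Euler step: one step from 80 toward 120 with tau 30
  p2 <- sim_participant(resting_hr = 80, effort_gain = 1, noise_sd = 0)
  d <- (120 - 80) / (1 * (p2$hr_max - 80))  # demand whose target is 120
  expect_equal(hr_step(80, d, p2, dt = 1, z = 0), 80 + (120 - 80) / 30)
  # t -> Inf at demand 1 converges to resting + gain * reserve
  hr <- p$resting_hr
  for (i in 1:5000) hr <- hr_step(hr, 1, p, z = 0)
  expect_equal(hr, p$resting_hr + p$effort_gain * (p$hr_max - p$resting_hr),
               tolerance = 1e-6)
})

test_that("steady-state HR increases strictly with effort_gain", {
  steady <- function(gain) {
    p <- sim_participant(resting_hr = 80, effort_gain = gain, noise_sd = 0)
    hr <- 80
    for (i in 1:2000) hr <- hr_step(hr, 0.8, p, z = 0)
    hr
  }
  gains <- c(0.2, 0.4, 0.6, 0.8)
  ss <- vapply(gains, steady, numeric(1))
  expect_true(all(diff(ss) > 0))
})

test_that("the calorie surrogate is linear in HR reserve and non-negative", {
  p <- quiet_participant()
  p0 <- sim_participant(resting_hr = 80, kcal_c0 = 0, noise_sd = 0)
  expect_equal(kcal_step(80, p0), 0)
  # 600 s at constant HR equals the closed-form sum
  rate <- max(0, p$kcal_c0 + p$kcal_c1 * (110 - p$resting_hr))
  total <- sum(vapply(1:600, function(i) kcal_step(110, p), numeric(1)))
  expect_equal(total, 600 * rate)
  # below-rest HR cannot give a negative increment
  expect_gte(kcal_step(40, p0), 0)
  # cumulative kcal never decreases within a simulated scenario
  log <- simulate_session(sim_participant(seed = 10), "UAS",
                          protocol = short_protocol(90))
  for (sc in unique(log$rows$scenario)) {
    seg <- log$rows$kcal[log$rows$scenario == sc]
    expect_true(all(diff(seg) >= 0))
  }
})

test_that("press success tracks the configured probability and difficulty", {
  p <- quiet_participant()
  # limits: perfect skill at minimal difficulty
  p1 <- sim_participant(skill = list(p_max = 1, p_min = 0.3))
  expect_equal(press_success_prob(0, p1), 1)
  # strict monotonicity across the demand range
  expect_lt(press_success_prob(1, p), press_success_prob(0, p))
  # Monte-Carlo at mid difficulty matches the configured value
  st <- scenario2_state(allotted = 10)  # demand 0.5
  target <- press_success_prob(0.5, p)
  set.seed(123)
  hits <- mean(vapply(1:1000, function(i) press_behavior(st, p)$success,
                      logical(1)))
  expect_within(hits, target, 3 * sqrt(target * (1 - target) / 1000))
  # distraction scales attempts down
  pd <- sim_participant(distraction = 0.5)
  expect_equal(press_success_prob(0, pd), 0.95 * 0.5)
})

test_that("simulated sessions are deterministic and physiologically bounded", {
  p <- sim_participant(seed = 77)
  a <- simulate_session(p, "UAS", protocol = short_protocol(120))
  b <- simulate_session(p, "UAS", protocol = short_protocol(120))
  expect_identical(a, b)
  expect_true(all(is.finite(a$rows$hr_cal)))
  expect_true(all(a$rows$hr_cal >= 40 & a$rows$hr_cal <= p$hr_max))
  # byte-identical on disk too
  s1 <- tempfile(); s2 <- tempfile()
  write_session_log(a, s1); write_session_log(b, s2)
  expect_identical(readLines(paste0(s1, ".csv")),
                   readLines(paste0(s2, ".csv")))
})

test_that("the frozen arm never moves its difficulty columns", {
  p <- sim_participant(seed = 21)
  log <- simulate_session(p, "CIS", protocol = short_protocol(120))
  states <- lapply(log$rows$state_json, jsonlite::fromJSON)
  for (sc in c("1", "2", "3")) {
    seg <- states[log$rows$scenario == sc]
    if (sc == "1") {
      expect_true(all(vapply(seg, function(s) s$vh, numeric(1)) == 10))
    } else if (sc == "2") {
      expect_true(all(vapply(seg, function(s) s$allotted, numeric(1)) == 10))
    } else {
      expect_true(all(vapply(seg, function(s) s$gen_rate,
                             numeric(1)) == 0.366))
    }
  }
})

test_that("controllers hold off until the warm-up fill is reached", {
  p <- quiet_participant(seed = 31)
  log <- simulate_session(p, "UAS", scenarios = 2,
                          protocol = short_protocol(30), warmup = 5)
  states <- lapply(log$rows$state_json, jsonlite::fromJSON)
  timers <- vapply(states[1:4], function(s) s$timer, numeric(1))
  expect_true(all(timers == 10))  # round clock not yet running
  expect_lt(states[[6]]$timer, 10)
})

test_that("cohorts are reproducible and sized as the crossover design implies", {
  coh <- simulate_cohort(n = 3, master_seed = 5, protocol = short_protocol(60))
  expect_length(coh, 3)
  rows <- sum(vapply(coh, function(el)
    nrow(el$UAS$rows) + nrow(el$CIS$rows), numeric(1)))
  expect_equal(rows, 3 * 2 * 60)
  coh2 <- simulate_cohort(n = 3, master_seed = 5,
                          protocol = short_protocol(60))
  expect_identical(coh, coh2)
  # paired arms share physiology
  expect_equal(coh[[1]]$UAS$participant, coh[[1]]$CIS$participant)
  ids <- vapply(coh, function(el) el$participant$id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("scenario-2 allotted time stays bounded in noisy closed-loop play", {
  p <- sim_participant(seed = 55, noise_sd = 4)
  log <- simulate_session(p, "UAS", scenarios = 2,
                          protocol = short_protocol(300))
  allotted <- vapply(lapply(log$rows$state_json, jsonlite::fromJSON),
                     function(s) s$allotted, numeric(1))
  expect_true(all(allotted >= 5 & allotted <= 15))
})
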