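test_that("scenario 1 advances distance while under the HR threshold", {
  st <- scenario1_state(d = 3, deltaD = 5, vh = 10)
  out <- step_scenario1(st, avgHR = 90, w = 0.5)
  expect_equal(out$d, 4)
  expect_equal(out$deltaD, 5)
  expect_equal(out$vh, 10)
})

test_that("scenario 1 goal completion rescales distance then speed, in that order", {
  st <- scenario1_state(d = 6, deltaD = 5, vh = 10)
  out <- step_scenario1(st, avgHR = 90, w = 0.5)
  expect_equal(out$d, 0)
  expect_equal(out$deltaD, 7.5)
  expect_equal(out$vh, 13.75)  # vh update consumes the updated deltaD

  lit <- scenario1_state(d = 6, deltaD = 5, vh = 10, mode = "literal")
  outl <- step_scenario1(lit, avgHR = 90, w = 0.5)
  expect_equal(outl$deltaD, 7.5)
  expect_equal(outl$vh, 10 - 7.5 * 0.5)  # printed sign, regression surface
})

test_that("scenario 1 eases off above the threshold", {
  st <- scenario1_state(d = 6, deltaD = 5, vh = 10)
  out <- step_scenario1(st, avgHR = 100, w = 0.5)
  expect_equal(out$d, 0)
  expect_equal(out$deltaD, 2.5)
  expect_equal(out$vh, 5)
  # tie at the threshold takes the high-exertion branch
  tie <- step_scenario1(scenario1_state(d = 2, deltaD = 5, vh = 10), 95, 0.5)
  expect_equal(tie$d, 0)
  expect_equal(tie$vh, 5)
})

test_that("zero weight leaves scenario-1 difficulty untouched in rescale branches", {
  for (hr in c(90, 100)) {
    st <- scenario1_state(d = 9, deltaD = 5, vh = 10)
    out <- step_scenario1(st, avgHR = hr, w = 0)
    expect_equal(out$d, 0)
    expect_equal(out$deltaD, 5)
    expect_equal(out$vh, 10)
  }
  expect_error(step_scenario1(scenario1_state(), 90, 1.2), "\\[0, 1\\]")
})

test_that("scenario 2 adapts the allotted time within [5, 15]", {
  st <- scenario2_state(allotted = 10, timer = 6)
  hit <- step_scenario2(st, TRUE, avgHR = 90)
  expect_equal(hit$points, 1L)
  expect_equal(hit$allotted, 9)
  expect_equal(hit$timer, 9)  # new round starts with the adapted budget

  low <- step_scenario2(scenario2_state(allotted = 5, timer = 3), TRUE, 90)
  expect_equal(low$allotted, 5)

  easy <- step_scenario2(scenario2_state(allotted = 10, timer = 6), TRUE, 100)
  expect_equal(easy$allotted, 11)

  to <- step_scenario2(scenario2_state(allotted = 10, timer = 1), FALSE, 90)
  expect_equal(to$points, -1L)
  expect_equal(to$allotted, 11)
  expect_equal(to$timer, 11)

  cap <- step_scenario2(scenario2_state(allotted = 15, timer = 1), FALSE, 90)
  expect_equal(cap$allotted, 15)
})

test_that("scenario 3 adapts the generation rate within its global clamp", {
  st <- scenario3_state()
  hit <- step_scenario3(st, TRUE, TRUE, avgHR = 90)
  expect_equal(hit$points, 1L)
  expect_equal(hit$gen_rate, 0.466)

  capped <- step_scenario3(scenario3_state(gen_rate = 1.83), TRUE, TRUE, 90)
  expect_equal(capped$gen_rate, 1.83)  # cap = 5 x 0.366

  miss <- step_scenario3(scenario3_state(gen_rate = 0.8), FALSE, FALSE, 90)
  expect_equal(miss$points, -1L)
  expect_equal(miss$gen_rate, 0.8)

  floor <- step_scenario3(scenario3_state(gen_rate = 0.1), TRUE, TRUE, 100)
  expect_equal(floor$gen_rate, 0.1)

  # period interpretation reverses the adaptation signs
  per <- step_scenario3(scenario3_state(interpretation = "period"),
                        TRUE, TRUE, 90)
  expect_equal(per$gen_rate, 0.366 - 0.1)
})

test_that("the architecture-test controller steps speed every 20 s", {
  st <- test_scenario_state(speed = 3)
  up <- step_test_scenario(st, last_hr = 75, dt = 20)
  expect_equal(up$speed, 4)
  down <- step_test_scenario(st, last_hr = 85, dt = 20)
  expect_equal(down$speed, 2)
  hold <- step_test_scenario(st, last_hr = 75, dt = 10)
  expect_equal(hold$speed, 3)
  expect_equal(hold$elapsed, 10)
  # floor clamp
  low <- step_test_scenario(test_scenario_state(speed = 0), 85, dt = 20)
  expect_equal(low$speed, 0)
})

test_that("frozen controllers keep difficulty at initial values but score identically", {
  cis <- make_cis_controller(2)
  st <- cis$state
  set.seed(7)
  for (i in 1:100) {
    st <- cis$step(st, runif(1) < 0.5, runif(1, 70, 120))
  }
  expect_equal(st$allotted, 10)

  cis3 <- make_cis_controller(3)
  st3 <- cis3$state
  for (i in 1:50) st3 <- cis3$step(st3, TRUE, TRUE, 90)
  expect_equal(st3$gen_rate, 0.366)

  # same press/timeout sequence: frozen and adaptive-disabled agree exactly
  set.seed(8)
  presses <- runif(200) < 0.6
  hrs <- runif(200, 70, 120)
  a <- make_controller(2, adaptive = FALSE)$state
  b <- make_cis_controller(2)$state
  for (i in 1:200) {
    a <- step_scenario2(a, presses[i], hrs[i], adaptive = FALSE)
    b <- step_scenario2(b, presses[i], hrs[i], adaptive = FALSE)
  }
  expect_identical(a, b)
  expect_error(make_controller("9"), "unknown scenario")
})

test_that("step functions are pure and exactly one branch fires per step", {
  st <- scenario1_state(d = 4, deltaD = 5, vh = 10)
  expect_identical(step_scenario1(st, 92, 0.4), step_scenario1(st, 92, 0.4))
  set.seed(9)
  for (i in 1:200) {
    st <- scenario1_state(d = sample(0:10, 1), deltaD = runif(1, 1, 10),
                          vh = runif(1, 2, 50))
    hr <- runif(1, 60, 130); w <- runif(1)
    out <- step_scenario1(st, hr, w)
    advanced <- out$d == st$d + 1 && out$deltaD == st$deltaD &&
      out$vh == st$vh
    rescaled <- out$d == 0
    expect_true(xor(advanced, rescaled))
  }
})

test_that("high exertion monotonically eases difficulty until clamped", {
  st1 <- scenario1_state(d = 0, deltaD = 50, vh = 50)
  out1 <- step_scenario1(st1, 100, 0.3)
  expect_lt(out1$vh, 50)
  st3 <- scenario3_state(gen_rate = 1)
  expect_lt(step_scenario3(st3, TRUE, TRUE, 100)$gen_rate, 1)
  st2 <- scenario2_state(allotted = 10, timer = 5)
  expect_gt(step_scenario2(st2, TRUE, 100)$allotted, 10)
  # and the low-exertion side moves each the opposite way (for scenario 1
  # the speed only changes on goal completion, d >= deltaD)
  st1b <- scenario1_state(d = 50, deltaD = 50, vh = 50)
  expect_gt(step_scenario1(st1b, 90, 0.3)$vh, 50)
  expect_gt(step_scenario3(st3, TRUE, TRUE, 90)$gen_rate, 1)
  expect_lt(step_scenario2(st2, TRUE, 90)$allotted, 10)
})

test_that("hysteresis mode holds difficulty inside the 95-105 dead band", {
  thr <- thresholds(hysteresis_enabled = TRUE)
  st <- scenario2_state(allotted = 10, timer = 5)
  mid <- step_scenario2(st, TRUE, 100, thr = thr)
  expect_equal(mid$allotted, 10)
  expect_equal(mid$points, 1L)
  hi <- step_scenario2(st, TRUE, 106, thr = thr)
  expect_equal(hi$allotted, 11)
  lo <- step_scenario2(st, TRUE, 90, thr = thr)
  expect_equal(lo$allotted, 9)
  st3 <- scenario3_state(gen_rate = 1)
  expect_equal(step_scenario3(st3, TRUE, TRUE, 100, thr = thr)$gen_rate, 1)
  expect_error(thresholds(110, 105), "exceed")
})
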