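test_that("descriptive statistics match direct-formula and e1071 oracles", {
  set.seed(42)
  for (n in c(5, 12, 29)) {
    x <- rnorm(n, 80, 10)
    d <- describe(x)
    # brute-force two-pass oracle
    m <- sum(x) / n
    m2 <- sum((x - m)^2) / n
    g1 <- (sum((x - m)^3) / n) / m2^1.5
    g2 <- (sum((x - m)^4) / n) / m2^2 - 3
    expect_equal(d$mean, m)
    expect_equal(d$sd, sqrt(sum((x - m)^2) / (n - 1)))
    expect_equal(d$variance, d$sd^2)
    expect_equal(d$asymmetry, g1 * sqrt(n * (n - 1)) / (n - 2))
    expect_equal(d$kurtosis, ((n + 1) * g2 + 6) * (n - 1) /
                   ((n - 2) * (n - 3)))
    expect_equal(d$interval, max(x) - min(x))
    # independent implementation of the same (bias-corrected) convention
    expect_equal(d$asymmetry, e1071::skewness(x, type = 2))
    expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2))
  }
})

test_that("degenerate inputs are flagged, not fabricated", {
  d <- describe(rep(7, 5))
  expect_equal(d$sd, 0)
  expect_equal(d$interval, 0)
  expect_true(is.na(d$asymmetry))
  d1 <- describe(3)
  expect_true(is.na(d1$sd))
  d3 <- describe(c(1, 2, 4))
  expect_true(is.na(d3$kurtosis))      # needs n >= 4
  expect_true(is.na(d3$kurtosis_se))
  expect_error(describe(c(1, NA)), "finite")
})

test_that("the kurtosis standard error closed form gives 0.85 at n = 29", {
  set.seed(1)
  d <- describe(rnorm(29))
  expect_equal(round(d$kurtosis_se, 2), 0.85)
  # identity against its published components, for a spread of n
  for (n in c(5, 10, 29, 100)) {
    se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
    expect_equal(kurtosis_se(n),
                 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5))))
  }
})

test_that("the raw paired-t route agrees with the t.test oracle", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 90, 8); y <- rnorm(n, 85, 8)
    mine <- paired_t_from_raw(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value)
    expect_equal(c(mine$ci_lower, mine$ci_upper),
                 as.numeric(ref$conf.int))
  }
  expect_error(paired_t_from_raw(1:3, 1:4), "equal length")
  expect_error(paired_t_from_raw(1, 2), "two pairs")
})

test_that("edge cases of the paired t are handled explicitly", {
  x <- c(80, 85, 90)
  same <- paired_t_from_raw(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- paired_t_from_summary(paired_summary(3, 0, 5))
  expect_true(is.infinite(degen$t))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  sym <- paired_t_from_summary(paired_summary(0, 2, 10))
  expect_equal(sym$t, 0)
  expect_equal(sym$ci_lower, -sym$ci_upper)
})

test_that("CI excludes zero exactly when p < 0.05", {
  set.seed(99)
  for (i in 1:200) {
    s <- paired_summary(runif(1, -5, 5), runif(1, 0.5, 10),
                        sample(3:50, 1))
    r <- paired_t_from_summary(s)
    excludes <- r$ci_lower > 0 || r$ci_upper < 0
    expect_equal(excludes, r$p < 0.05)
  }
})

test_that("published pilot and field paired rows are reproduced from summaries", {
  for (f in c("pilot_paired_summaries.csv", "field_paired_summaries.csv")) {
    path <- system.file("extdata", f, package = "hradapt")
    df <- utils::read.csv(path)
    for (i in seq_len(nrow(df))) {
      r <- paired_t_from_summary(paired_summary(df$mean_diff[i],
                                                df$sd_diff[i], df$n[i]))
      expect_within(r$t, df$t_ref[i], 0.02)
      expect_equal(r$df, df$df_ref[i])
      expect_within(r$ci_lower, df$lower_ref[i], 0.02)
      expect_within(r$ci_upper, df$upper_ref[i], 0.02)
    }
  }
})

test_that("scenario-level variables are extracted per participant, scenario and arm", {
  coh <- simulate_cohort(n = 3, master_seed = 9,
                         protocol = short_protocol(60))
  vars <- build_variables(coh)
  expect_length(vars, 12)  # 2 measures x 3 scenarios x 2 arms
  expect_true(all(vapply(vars, length, integer(1)) == 3))
  # a constant-HR log yields exactly that HR as the scenario mean
  one <- coh[[1]]
  one$UAS$rows$hr_cal <- 90
  vars1 <- build_variables(list(one))
  expect_equal(unname(vars1$HrateP1UAS), 90)
  # a participant missing an arm is excluded with a reason
  broken <- coh
  broken[[2]]$CIS <- NULL
  vars2 <- build_variables(broken)
  expect_equal(length(vars2$HrateP1UAS), 2)
  expect_match(attr(vars2, "excluded"), "missing arm")
})

test_that("rendered tables round-trip and the pipeline runs end to end", {
  coh <- simulate_cohort(n = 3, master_seed = 13,
                         protocol = short_protocol(60))
  vars <- build_variables(coh)
  tests <- paired_tests(vars)
  expect_length(tests, 6)
  out <- tempfile()
  paths <- render_tables(vars, tests, out)
  expect_true(all(file.exists(paths)))
  desc <- utils::read.csv(paths[1], check.names = FALSE)
  expect_equal(ncol(desc), 13)  # Statistics + 12 variables
  tt <- utils::read.csv(paths[2], check.names = FALSE)
  expect_equal(nrow(tt), 6)
  expect_equal(tt$t, round(vapply(tests, function(x) x$t, numeric(1)), 2))
  expect_equal(tt$Average,
               round(vapply(tests, function(x) x$mean_diff, numeric(1)), 2))
})
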