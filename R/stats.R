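#' Descriptive summary of a measurement series
#'
#' Computes the descriptive statistics used for the per-scenario HR and
#' caloric-expenditure variables: n, mean, standard deviation, variance,
#' bias-corrected (sample-adjusted) skewness and excess kurtosis with the
#' kurtosis standard error, and the interval (range, max - min). Skewness
#' and kurtosis follow the classical small-sample convention of mainstream
#' statistics packages (SPSS/PSPP type): for skewness
#' `g1 * sqrt(n(n-1)) / (n-2)` and for kurtosis
#' `((n+1)*g2 + 6) * (n-1) / ((n-2)(n-3))` where `g1`, `g2` are the moment
#' estimators. Statistics whose sample-size requirement is not met are
#' returned as `NA` rather than fabricated (sd needs n >= 2, skewness
#' n >= 3, kurtosis n >= 4).
#'
#' @param x Numeric vector of finite values.
#' @param name Optional series label.
#' @return A list of class `descriptive_summary` with fields `name`, `n`,
#'   `mean`, `sd`, `variance`, `asymmetry`, `kurtosis`, `kurtosis_se`,
#'   `interval`.
#' @export
describe <- function(x, name = NULL) {
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 1L) stop("need at least one observation")
  m <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  g1 <- g2 <- NA_real_
  if (n >= 2L && s > 0) {
    m2 <- mean((x - m)^2)
    g1 <- mean((x - m)^3) / m2^1.5
    g2 <- mean((x - m)^4) / m2^2 - 3
  }
  skew <- if (n >= 3L && !is.na(g1)) g1 * sqrt(n * (n - 1)) / (n - 2)
          else NA_real_
  kurt <- if (n >= 4L && !is.na(g2)) {
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else NA_real_
  structure(list(name = name, n = n, mean = m, sd = s,
                 variance = if (is.na(s)) NA_real_ else s^2,
                 asymmetry = skew, kurtosis = kurt,
                 kurtosis_se = kurtosis_se(n),
                 interval = diff(range(x))),
            class = "descriptive_summary")
}

#' Standard error of the sample kurtosis
#'
#' Closed form depending only on n:
#' `2 * se_skew * sqrt((n^2 - 1) / ((n - 3)(n + 5)))` with
#' `se_skew = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))`. Requires n >= 4; `NA`
#' otherwise.
#'
#' @param n Sample size.
#' @return The kurtosis standard error, or `NA` when n < 4.
#' @export
kurtosis_se <- function(n) {
  if (n < 4L) return(NA_real_)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Paired-sample summary
#'
#' The three quantities a paired t-test needs: the mean and standard
#' deviation of the within-pair differences, and the number of pairs.
#'
#' @param mean_diff Mean within-pair difference.
#' @param sd_diff Standard deviation of the differences (>= 0).
#' @param n Number of pairs (>= 2).
#' @param label Optional variable label.
#' @return A list of class `paired_summary`.
#' @export
paired_summary <- function(mean_diff, sd_diff, n, label = NULL) {
  stopifnot(is.finite(mean_diff), sd_diff >= 0, n >= 2)
  structure(list(label = label, mean_diff = mean_diff, sd_diff = sd_diff,
                 n = as.integer(n)),
            class = "paired_summary")
}

#' Paired t-test from summary statistics
#'
#' Computes `t = mean_diff / (sd_diff / sqrt(n))` with `df = n - 1`, the
#' two-tailed p-value and the 95% confidence interval
#' `mean_diff +- t[0.975, df] * se`. This route reproduces every published
#' inferential row directly from its printed (mean, sd, n) triple. Zero
#' `sd_diff` with a nonzero mean yields an infinite t, flagged in the
#' result; zero mean with zero sd yields t = 0.
#'
#' @param s A [paired_summary()].
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `paired_test_result` with fields `label`, `t`,
#'   `df`, `p`, `se`, `ci_lower`, `ci_upper`, `mean_diff`, `degenerate`.
#' @export
paired_t_from_summary <- function(s, conf_level = 0.95) {
  stopifnot(inherits(s, "paired_summary"))
  n <- s$n
  se <- s$sd_diff / sqrt(n)
  degenerate <- se == 0
  tval <- if (degenerate) {
    if (s$mean_diff == 0) 0 else sign(s$mean_diff) * Inf
  } else s$mean_diff / se
  df <- n - 1L
  p <- if (is.infinite(tval)) 0 else 2 * stats::pt(-abs(tval), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(label = s$label, t = tval, df = df, p = p, se = se,
                 ci_lower = s$mean_diff - q * se,
                 ci_upper = s$mean_diff + q * se,
                 mean_diff = s$mean_diff, degenerate = degenerate),
            class = "paired_test_result")
}

#' Paired t-test from raw paired measurements
#'
#' Forms the within-pair differences `x_uas - x_cis`, summarises them and
#' delegates to [paired_t_from_summary()], so the raw and summary routes
#' are identical by construction.
#'
#' @param x_uas,x_cis Paired numeric vectors of equal length >= 2, ordered
#'   by participant.
#' @param label Optional variable label.
#' @param conf_level Confidence level (default 0.95).
#' @return A `paired_test_result`.
#' @export
paired_t_from_raw <- function(x_uas, x_cis, label = NULL,
                              conf_level = 0.95) {
  if (length(x_uas) != length(x_cis)) {
    stop("paired vectors must have equal length")
  }
  if (length(x_uas) < 2L) stop("need at least two pairs")
  d <- x_uas - x_cis
  paired_t_from_summary(
    paired_summary(mean(d), stats::sd(d), length(d), label = label),
    conf_level = conf_level)
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s t(%d) = %.3f, p = %.4f, 95%% CI [%.3f, %.3f]\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$df, x$t, x$p, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("%s n=%d mean=%.2f sd=%.2f skew=%.2f kurt=%.2f (se %.2f) interval=%.2f\n",
              if (is.null(x$name)) "" else paste0(x$name, ":"),
              x$n, x$mean, x$sd, x$asymmetry, x$kurtosis, x$kurtosis_se,
              x$interval))
  invisible(x)
}

#' Build per-participant scenario-level variables from session logs
#'
#' For every participant x scenario x arm, computes the mean calibrated HR
#' over the scenario segment (`Hrate<P?><arm>`) and the final cumulative
#' caloric expenditure (`Gcalorico<?><arm>`), following the study's naming
#' convention. Participants missing an arm, or whose logs fail validation,
#' are excluded with a logged reason (attribute `excluded`).
#'
#' @param cohort A `cohort` from [simulate_cohort()], or any list whose
#'   elements have `participant`, `UAS` and `CIS` fields.
#' @return A named list of numeric vectors (one per variable, each of
#'   length = number of retained participants), with attributes
#'   `participants` and `excluded`.
#' @export
build_variables <- function(cohort) {
  keep <- list(); excluded <- character(0)
  for (el in cohort) {
    pid <- el$participant$id
    ok <- !is.null(el$UAS) && !is.null(el$CIS) &&
      inherits(el$UAS, "session_log") && inherits(el$CIS, "session_log")
    if (ok) {
      ok <- !inherits(try(validate_session_log(el$UAS), silent = TRUE),
                      "try-error") &&
        !inherits(try(validate_session_log(el$CIS), silent = TRUE),
                  "try-error")
      if (!ok) excluded <- c(excluded, sprintf("%s: invalid log", pid))
    } else {
      excluded <- c(excluded, sprintf("%s: missing arm", pid))
    }
    if (ok) keep[[length(keep) + 1L]] <- el
  }
  if (length(keep) == 0L) stop("nothing analyzable: no complete arm pairs")
  scen <- unique(keep[[1]]$UAS$rows$scenario)
  out <- list()
  for (sc in scen) {
    for (arm in c("UAS", "CIS")) {
      hr <- vapply(keep, function(el) {
        r <- el[[arm]]$rows
        mean(r$hr_cal[r$scenario == sc])
      }, numeric(1))
      kc <- vapply(keep, function(el) {
        r <- el[[arm]]$rows
        seg <- r[r$scenario == sc, ]
        seg$kcal[nrow(seg)]
      }, numeric(1))
      out[[sprintf("HrateP%s%s", sc, arm)]] <- hr
      out[[sprintf("Gcalorico%s%s", sc, arm)]] <- kc
    }
  }
  attr(out, "participants") <- vapply(keep, function(el)
    el$participant$id, character(1))
  attr(out, "excluded") <- excluded
  out
}

#' Paired tests for every scenario-level variable
#'
#' Runs [paired_t_from_raw()] on each UAS/CIS variable pair produced by
#' [build_variables()].
#'
#' @param vars Output of [build_variables()].
#' @param conf_level Confidence level (default 0.95).
#' @return List of `paired_test_result`s, one per UAS/CIS pair.
#' @export
paired_tests <- function(vars, conf_level = 0.95) {
  uas_names <- grep("UAS$", names(vars), value = TRUE)
  lapply(uas_names, function(nm) {
    cis <- sub("UAS$", "CIS", nm)
    if (!cis %in% names(vars)) stop("missing CIS counterpart for ", nm)
    paired_t_from_raw(vars[[nm]], vars[[cis]],
                      label = paste0(nm, "-", cis),
                      conf_level = conf_level)
  })
}

#' Render descriptive and inferential tables
#'
#' Writes the study-style report: a descriptive table (one column per
#' variable, rows N/Mean/Std. Dev/Variance/Kurtosis/K. Std. Err/Asymmetry/
#' Interval) and an inferential table (one row per paired test with
#' Average, Std. Dev, Av. Sta. Err, Lower, Higher, t, df, Sign), as CSV
#' files plus a combined markdown report. No multiple-testing correction
#' is applied; the report footer says so.
#'
#' @param vars Output of [build_variables()] (or `NULL` to skip the
#'   descriptive table).
#' @param tests List of `paired_test_result`s (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"table"`).
#' @return Paths written, invisibly.
#' @export
render_tables <- function(vars, tests, out_dir, prefix = "table") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  md <- character(0)
  if (!is.null(vars)) {
    ds <- lapply(names(vars), function(nm) describe(vars[[nm]], name = nm))
    stat_rows <- c("N", "Mean", "Std. Dev", "Variance", "Kurtosis",
                   "K. Stad. Err.", "Asymmetry", "Interval")
    m <- vapply(ds, function(d) c(d$n, d$mean, d$sd, d$variance, d$kurtosis,
                                  d$kurtosis_se, d$asymmetry, d$interval),
                numeric(8))
    tab <- data.frame(Statistics = stat_rows, round(m, 2),
                      check.names = FALSE)
    names(tab)[-1] <- names(vars)
    p1 <- file.path(out_dir, paste0(prefix, "_descriptive.csv"))
    utils::write.csv(tab, p1, row.names = FALSE)
    paths <- c(paths, p1)
    md <- c(md, "## Descriptive statistics", "",
            paste(names(tab), collapse = " | "),
            paste(rep("---", ncol(tab)), collapse = " | "),
            apply(tab, 1, paste, collapse = " | "), "")
  }
  if (!is.null(tests) && length(tests) > 0L) {
    tt <- data.frame(
      `Dependent Variables` = vapply(tests, function(x) x$label, character(1)),
      Average = round(vapply(tests, function(x) x$mean_diff, numeric(1)), 2),
      `Std. Dev` = round(vapply(tests, function(x)
        x$se * sqrt(x$df + 1), numeric(1)), 2),
      `Av. Sta. Err` = round(vapply(tests, function(x) x$se, numeric(1)), 2),
      Lower = round(vapply(tests, function(x) x$ci_lower, numeric(1)), 2),
      Higher = round(vapply(tests, function(x) x$ci_upper, numeric(1)), 2),
      t = round(vapply(tests, function(x) x$t, numeric(1)), 2),
      df = vapply(tests, function(x) x$df, integer(1)),
      Sign = round(vapply(tests, function(x) x$p, numeric(1)), 3),
      check.names = FALSE)
    p2 <- file.path(out_dir, paste0(prefix, "_paired_t.csv"))
    utils::write.csv(tt, p2, row.names = FALSE)
    paths <- c(paths, p2)
    md <- c(md, "## Paired t-tests", "",
            paste(names(tt), collapse = " | "),
            paste(rep("---", ncol(tt)), collapse = " | "),
            apply(tt, 1, paste, collapse = " | "), "")
  }
  md <- c(md, "No multiple-testing correction applied.")
  pm <- file.path(out_dir, paste0(prefix, "_report.md"))
  writeLines(md, pm)
  invisible(c(paths, pm))
}

#' Read paired summaries from a CSV
#'
#' Expects columns `label,mean_diff,sd_diff,n`; extra columns (e.g.
#' reference values) are ignored.
#'
#' @param path CSV path.
#' @return List of [paired_summary()]s.
#' @export
read_paired_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mean_diff", "sd_diff", "n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("summaries CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    paired_summary(df$mean_diff[i], df$sd_diff[i], df$n[i],
                   label = df$label[i])
  })
}
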