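# Method-comparison statistics: night matching, paired t, Bland-Altman,
# satisfactory-range coverage, Pearson correlation, gender subgroup tests.
#
# Sign convention throughout: difference = reference - device, so a negative
# bias means the device overestimates the reference and a positive bias an
# underestimation.

#' Match device nights to reference nights
#'
#' Inner join on (subject, night). Per-parameter signed differences
#' (`d_tst`, `d_waso`, `d_se`, `d_sol`) are reference minus device.
#' Duplicate (subject, night) keys within either table are an error.
#'
#' @param reference,device NightParams tibbles (one device each).
#' @return A tibble of matched nights with reference columns suffixed
#'   `_ref`, device columns suffixed `_dev`, and difference columns.
#'   Attribute `unmatched` counts reference and device nights without a
#'   partner.
#' @export
match_nights <- function(reference, device) {
  for (tb in list(reference, device)) {
    if (anyDuplicated(tb[, c("subject", "night")])) {
      stop("duplicate (subject, night) rows for device '", tb$device[1],
           "'", call. = FALSE)
    }
  }
  keep <- c("subject", "night", "tib", "tst", "waso", "se", "sol")
  ref <- reference[, keep]
  dev <- device[, keep]
  m <- dplyr::inner_join(ref, dev, by = c("subject", "night"),
                         suffix = c("_ref", "_dev"))
  for (p in c("tst", "waso", "se", "sol")) {
    m[[paste0("d_", p)]] <- m[[paste0(p, "_ref")]] - m[[paste0(p, "_dev")]]
  }
  attr(m, "unmatched") <- c(reference = nrow(ref) - nrow(m),
                            device = nrow(dev) - nrow(m))
  m
}

paired_t_core <- function(mean_diff, sd_diff, n) {
  df <- n - 1L
  se <- sd_diff / sqrt(n)
  zero_var <- sd_diff == 0
  if (zero_var) {
    t <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    p <- if (mean_diff == 0) 1 else 0
    ci <- c(mean_diff, mean_diff)
  } else {
    t <- mean_diff / se
    p <- 2 * pt(-abs(t), df)
    ci <- mean_diff + c(-1, 1) * qt(0.975, df) * se
  }
  structure(list(t = t, df = df, p = p, mean_diff = mean_diff,
                 sd_diff = sd_diff, n = as.integer(n), ci95 = ci,
                 zero_variance = zero_var),
            class = "paired_t")
}

#' Two-tailed paired t test on per-night differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`, two-sided p from the
#' t distribution, and a 95% CI using the t critical value. With zero
#' variance and a nonzero mean the p value is reported as 0 and flagged
#' `zero_variance`.
#'
#' @param differences Numeric vector of paired differences (reference minus
#'   device); `NA`s are dropped.
#' @return An object of class `paired_t`.
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  if (length(d) < 2) stop("need at least 2 paired differences", call. = FALSE)
  paired_t_core(mean(d), sd(d), length(d))
}

#' Paired t test from printed summary statistics
#'
#' Recomputes the paired t statistic from a reported mean difference, SD of
#' differences, and sample size - the recomputation mode used when only
#' printed summaries of a study are available. Agrees exactly with
#' [paired_t()] applied to the raw differences.
#'
#' @param mean_diff,sd_diff,n Summary statistics of the differences.
#' @return An object of class `paired_t`.
#' @export
t_from_summary <- function(mean_diff, sd_diff, n) {
  check_scalar(n, "n", function(v) v >= 2)
  check_scalar(sd_diff, "sd_diff", function(v) v >= 0)
  paired_t_core(mean_diff, sd_diff, n)
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.2f, p = %.3g\n", x$df, x$t, x$p))
  cat(sprintf("  mean diff %.2f (SD %.2f), n = %d, 95%% CI [%.2f, %.2f]\n",
              x$mean_diff, x$sd_diff, x$n, x$ci95[1], x$ci95[2]))
  invisible(x)
}

bland_altman_core <- function(bias, sd_diff, n, k, n_outside = NA_integer_) {
  se <- sd_diff / sqrt(n)
  ci <- if (sd_diff == 0) c(bias, bias) else bias + c(-1, 1) * qt(0.975, n - 1) * se
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - k * sd_diff,
                 loa_upper = bias + k * sd_diff,
                 bias_ci95 = ci, k = k, n = as.integer(n),
                 n_outside_loa = n_outside),
            class = "bland_altman")
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference; the limits of agreement are
#' `bias +/- k * sd(d)` (default multiplier 1.96); the 95% CI of the bias
#' uses the t critical value. The number of differences outside the limits
#' is counted.
#'
#' @param differences Numeric vector of reference-minus-device differences;
#'   `NA`s are dropped.
#' @param k Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `bland_altman`.
#' @seealso [ba_from_summary()] for the printed-summary mode.
#' @export
bland_altman <- function(differences, k = 1.96) {
  d <- differences[!is.na(differences)]
  if (length(d) < 2) stop("need at least 2 differences", call. = FALSE)
  res <- bland_altman_core(mean(d), sd(d), length(d), k)
  res$n_outside_loa <- sum(d < res$loa_lower | d > res$loa_upper)
  res
}

#' Bland-Altman limits from printed summary statistics
#'
#' @param bias,sd_diff,n Reported mean difference, SD of differences, and
#'   sample size.
#' @param k Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `bland_altman` (outside-limit count unknown).
#' @export
ba_from_summary <- function(bias, sd_diff, n, k = 1.96) {
  check_scalar(n, "n", function(v) v >= 2)
  check_scalar(sd_diff, "sd_diff", function(v) v >= 0)
  bland_altman_core(bias, sd_diff, n, k)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f (SD %.2f), n = %d\n",
              x$bias, x$sd_diff, x$n))
  cat(sprintf("  limits of agreement [%.2f, %.2f] (k = %.2f)\n",
              x$loa_lower, x$loa_upper, x$k))
  cat(sprintf("  bias 95%% CI [%.2f, %.2f]", x$bias_ci95[1], x$bias_ci95[2]))
  if (!is.na(x$n_outside_loa)) cat(sprintf("; %d outside limits",
                                           x$n_outside_loa))
  cat("\n")
  invisible(x)
}

#' Satisfactory-range coverage of paired differences
#'
#' The satisfactory absolute difference is 30 min or less for TST and WASO
#' (boundary inclusive) and strictly less than 5 percentage points for SE.
#'
#' @param differences Numeric vector of differences; `NA`s are dropped.
#' @param parameter One of `"tst"`, `"waso"`, `"se"`.
#' @return A list of class `coverage`: `parameter`, `threshold`,
#'   `inclusive`, `n_within`, `n_total`, `percent`.
#' @export
coverage <- function(differences, parameter = c("tst", "waso", "se")) {
  parameter <- match.arg(parameter)
  d <- differences[!is.na(differences)]
  if (length(d) == 0) stop("no differences to assess", call. = FALSE)
  if (parameter == "se") {
    threshold <- 5
    within <- abs(d) < threshold
    inclusive <- FALSE
  } else {
    threshold <- 30
    within <- abs(d) <= threshold
    inclusive <- TRUE
  }
  coverage_from_counts(sum(within), length(d), parameter, threshold,
                       inclusive)
}

#' Satisfactory-range coverage from printed counts
#'
#' @param n_within,n_total Counts of nights within the satisfactory range
#'   and in total.
#' @param parameter Parameter name (for display only).
#' @param threshold,inclusive Range definition (for display only).
#' @return A list of class `coverage`.
#' @export
coverage_from_counts <- function(n_within, n_total, parameter = "tst",
                                 threshold = 30, inclusive = TRUE) {
  stopifnot(n_within <= n_total, n_total > 0)
  structure(list(parameter = parameter, threshold = threshold,
                 inclusive = inclusive, n_within = as.integer(n_within),
                 n_total = as.integer(n_total),
                 percent = 100 * n_within / n_total),
            class = "coverage")
}

#' @export
print.coverage <- function(x, ...) {
  cat(sprintf("Coverage (%s, |d| %s %g): %.1f%% (%d/%d)\n",
              toupper(x$parameter), if (x$inclusive) "<=" else "<",
              x$threshold, x$percent, x$n_within, x$n_total))
  invisible(x)
}

#' Pearson correlation between paired device measurements
#'
#' Standard product-moment correlation with a two-sided p value. Zero
#' variance in either vector yields an `NA` correlation with a
#' `zero_variance` flag instead of an error.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` are dropped.
#' @return A list of class `correlation`: `r`, `p`, `n`, `zero_variance`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = length(x),
                          zero_variance = TRUE), class = "correlation"))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 zero_variance = FALSE), class = "correlation")
}

#' @export
print.correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.2f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

welch_core <- function(m1, s1, n1, m2, s2, n2, variance_model) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (variance_model == "welch") {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sample subgroup test on per-night difference scores
#'
#' Compares the mean device-agreement difference between two groups
#' (typically women vs men) with a two-sample t test on the per-night
#' difference scores; Welch's unequal-variance model is the default, the
#' pooled-variance model optional. Degrees of freedom follow the
#' conventional formulas.
#'
#' @param differences Numeric vector of per-night differences.
#' @param group Factor/character vector (two levels) aligned with
#'   `differences`.
#' @param variance_model `"welch"` (default) or `"pooled"`.
#' @return A list of class `subgroup_test` with per-group summaries and
#'   `t`, `df`, `p`.
#' @seealso [subgroup_from_summary()] for the printed-summary mode.
#' @export
subgroup_test <- function(differences, group,
                          variance_model = c("welch", "pooled")) {
  variance_model <- match.arg(variance_model)
  ok <- !is.na(differences) & !is.na(group)
  d <- differences[ok]
  g <- as.character(group[ok])
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("exactly two groups are required", call. = FALSE)
  n <- table(factor(g, levels = lev))
  if (any(n < 2)) stop("each group needs at least 2 observations",
                       call. = FALSE)
  d1 <- d[g == lev[1]]
  d2 <- d[g == lev[2]]
  subgroup_from_summary(mean(d1), sd(d1), length(d1),
                        mean(d2), sd(d2), length(d2),
                        variance_model, labels = lev)
}

#' Subgroup test from printed per-group summaries
#'
#' @param m1,s1,n1,m2,s2,n2 Per-group mean, SD, and size of the difference
#'   scores.
#' @param variance_model `"welch"` (default) or `"pooled"`.
#' @param labels Group labels (display only).
#' @return A list of class `subgroup_test`.
#' @export
subgroup_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                  variance_model = c("welch", "pooled"),
                                  labels = c("F", "M")) {
  variance_model <- match.arg(variance_model)
  res <- welch_core(m1, s1, n1, m2, s2, n2, variance_model)
  structure(list(
    groups = tibble(group = labels, mean = c(m1, m2), sd = c(s1, s2),
                    n = as.integer(c(n1, n2))),
    t = res$t, df = res$df, p = res$p, variance_model = variance_model
  ), class = "subgroup_test")
}

#' @export
print.subgroup_test <- function(x, ...) {
  cat(sprintf("Subgroup test (%s): t(%.1f) = %.2f, p = %.3g\n",
              x$variance_model, x$df, x$t, x$p))
  for (i in 1:2) {
    cat(sprintf("  %s: mean %.2f (SD %.2f), n = %d\n", x$groups$group[i],
                x$groups$mean[i], x$groups$sd[i], x$groups$n[i]))
  }
  invisible(x)
}
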