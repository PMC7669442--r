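# End-to-end orchestration: simulate -> score -> process -> validate, with
# summary tables, Bland-Altman plots, and discard accounting.

#' Agreement analysis of one device against the actigraphy reference
#'
#' For each requested parameter: paired t test, Bland-Altman analysis,
#' satisfactory-range coverage (TST/WASO/SE only), Pearson correlation, and
#' (when a gender table is supplied) a subgroup test on the difference
#' scores.
#'
#' @param reference Actigraphy NightParams.
#' @param device Device NightParams (ring or watch).
#' @param params Parameters to analyse (subset of `tst`, `waso`, `se`,
#'   `sol`).
#' @param subjects Optional tibble `subject`, `gender` enabling the
#'   subgroup tests.
#' @param k Limits-of-agreement multiplier.
#' @return A list of class `device_validation`: `device`, `matched`,
#'   `tables` (one tibble row per parameter), and per-parameter result
#'   objects in `details`.
#' @export
validate_device <- function(reference, device,
                            params = c("tst", "waso", "se", "sol"),
                            subjects = NULL, k = 1.96) {
  params <- match.arg(params, c("tst", "waso", "se", "sol"),
                      several.ok = TRUE)
  dev_name <- device$device[1]
  m <- match_nights(reference, device)
  if (!is.null(subjects)) {
    m <- dplyr::left_join(m, subjects, by = "subject")
  }
  details <- list()
  rows <- list()
  for (p in params) {
    d <- m[[paste0("d_", p)]]
    d_ok <- d[!is.na(d)]
    if (length(d_ok) < 2) next
    tt <- paired_t(d)
    ba <- bland_altman(d, k = k)
    cov <- if (p %in% c("tst", "waso", "se")) coverage(d, p) else NULL
    use <- !is.na(d) & !is.na(m[[paste0(p, "_ref")]])
    corr <- if (sum(use) >= 3) {
      pearson_cor(m[[paste0(p, "_ref")]][use], m[[paste0(p, "_dev")]][use])
    } else {
      NULL
    }
    sg <- NULL
    if (!is.null(subjects) && length(unique(stats::na.omit(m$gender))) == 2) {
      sg <- tryCatch(subgroup_test(d, m$gender), error = function(e) NULL)
    }
    details[[p]] <- list(paired_t = tt, bland_altman = ba, coverage = cov,
                         correlation = corr, subgroup = sg)
    rows[[p]] <- tibble(
      device = dev_name, parameter = p, n = tt$n,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      bias_ci_lower = ba$bias_ci95[1], bias_ci_upper = ba$bias_ci95[2],
      n_outside_loa = ba$n_outside_loa,
      t = tt$t, df = tt$df, p_value = tt$p,
      coverage_pct = if (is.null(cov)) NA_real_ else cov$percent,
      r = if (is.null(corr)) NA_real_ else corr$r,
      r_p = if (is.null(corr)) NA_real_ else corr$p,
      gender_t = if (is.null(sg)) NA_real_ else sg$t,
      gender_df = if (is.null(sg)) NA_real_ else sg$df,
      gender_p = if (is.null(sg)) NA_real_ else sg$p
    )
  }
  structure(list(device = dev_name, matched = m,
                 tables = dplyr::bind_rows(rows), details = details),
            class = "device_validation")
}

#' @export
print.device_validation <- function(x, ...) {
  cat("Device validation:", x$device, "vs actigraphy;",
      nrow(x$matched), "matched nights\n")
  tb <- x$tables
  for (i in seq_len(nrow(tb))) {
    cat(sprintf(
      "  %-4s bias %7.2f (SD %6.2f)  LoA [%7.2f, %7.2f]  t(%d) = %6.2f%s\n",
      toupper(tb$parameter[i]), tb$bias[i], tb$sd_diff[i], tb$loa_lower[i],
      tb$loa_upper[i], tb$df[i], tb$t[i],
      if (!is.na(tb$coverage_pct[i])) {
        sprintf("  coverage %.1f%%", tb$coverage_pct[i])
      } else {
        ""
      }
    ))
  }
  invisible(x)
}

#' Run the full synthetic validation pipeline
#'
#' Simulates a study, runs the actigraphy scoring/detection/cleaning
#' pipeline, parses the ring records, processes the watch streams through
#' the validation cascade, matches nights per device, and computes the full
#' agreement battery. The run is deterministic given `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @param devices Devices to validate (subset of `"ring"`, `"watch"`).
#' @param params Parameters to analyse.
#' @param out_dir Optional directory; when given, night parameters and
#'   agreement tables are written as tab-separated text and Bland-Altman
#'   plots as PDF files.
#' @return A list of class `validation_report`: `config`, `study`,
#'   `night_params` (all devices), per-device `device_validation` objects in
#'   `devices`, `agreement` (combined table), and `accounting` (watch
#'   discard accounting and actigraphy night counts).
#' @export
run_pipeline <- function(config = sim_config(),
                         devices = c("ring", "watch"),
                         params = c("tst", "waso", "se", "sol"),
                         out_dir = NULL) {
  devices <- match.arg(devices, c("ring", "watch"), several.ok = TRUE)
  study <- simulate_study(config)
  window <- range(study$truth$night)
  acti <- actigraphy_nights(study$counts, study$logs, window)
  np <- list(acti)
  res <- list()
  accounting <- list(
    actigraphy_nights = nrow(acti),
    truth_nights = nrow(study$truth)
  )
  if ("ring" %in% devices) {
    ring <- parse_ring(study$ring)
    np <- c(np, list(ring))
    res$ring <- validate_device(acti, ring, params, study$subjects)
    accounting$ring_nights <- nrow(ring)
    accounting$ring_matched <- nrow(res$ring$matched)
  }
  if ("watch" %in% devices) {
    watch <- watch_nights(study$watch)
    np <- c(np, list(watch))
    res$watch <- validate_device(acti, watch, params, study$subjects)
    accounting$watch_nights <- nrow(watch)
    accounting$watch_streams <- length(study$watch)
    accounting$watch_removed <- length(study$watch) - nrow(watch)
    accounting$watch_matched <- nrow(res$watch$matched)
    accounting$watch_cascade <- attr(watch, "accounting")
  }
  night_params <- dplyr::bind_rows(np)
  agreement <- dplyr::bind_rows(lapply(res, function(v) v$tables))
  report <- structure(list(config = config, study = study,
                           night_params = night_params, devices = res,
                           agreement = agreement, accounting = accounting),
                      class = "validation_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Sleep wearable validation report\n")
  cat(sprintf("  %d subjects x %d nights; %d actigraphy nights detected\n",
              x$config$n_subjects, x$config$nights_per_subject,
              x$accounting$actigraphy_nights))
  if (!is.null(x$accounting$watch_removed)) {
    cat(sprintf("  watch nights removed as invalid: %d/%d (%.1f%%)\n",
                x$accounting$watch_removed, x$accounting$watch_streams,
                100 * x$accounting$watch_removed /
                  x$accounting$watch_streams))
  }
  for (v in x$devices) print(v)
  invisible(x)
}

#' Bland-Altman plot for one device and parameter
#'
#' Differences (reference minus device) are plotted against the reference
#' value, with solid lines at the bias and the limits of agreement and
#' dashed lines at the satisfactory range (for TST/WASO/SE). Plotting
#' against the reference value (rather than the pair mean) follows the
#' benchmark study's figures; classic Bland-Altman uses the pair mean.
#'
#' @param validation A `device_validation` object.
#' @param parameter One of `"tst"`, `"waso"`, `"se"`, `"sol"`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(validation, parameter = "tst") {
  stopifnot(inherits(validation, "device_validation"))
  ba <- validation$details[[parameter]]$bland_altman
  if (is.null(ba)) stop("parameter not analysed: ", parameter, call. = FALSE)
  m <- validation$matched
  df <- tibble(x = m[[paste0(parameter, "_ref")]],
               y = m[[paste0("d_", parameter)]])
  df <- df[!is.na(df$x) & !is.na(df$y), ]
  unit <- if (parameter == "se") "%" else "min"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        colour = "steelblue", linetype = "longdash") +
    ggplot2::labs(
      x = sprintf("Actigraphy %s (%s)", toupper(parameter), unit),
      y = sprintf("Actigraphy - %s (%s)", validation$device, unit),
      title = sprintf("%s: bias %.2f, LoA [%.2f, %.2f]",
                      toupper(parameter), ba$bias, ba$loa_lower,
                      ba$loa_upper)
    ) +
    ggplot2::theme_minimal()
  if (parameter %in% c("tst", "waso", "se")) {
    lim <- if (parameter == "se") 5 else 30
    p <- p + ggplot2::geom_hline(yintercept = c(-lim, lim),
                                 colour = "grey40", linetype = "dashed")
  }
  p
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$night_params,
                   file.path(out_dir, "night_params.tsv"))
  readr::write_tsv(report$agreement, file.path(out_dir, "agreement.tsv"))
  for (v in report$devices) {
    for (p in names(v$details)) {
      f <- file.path(out_dir, sprintf("bland_altman_%s_%s.pdf",
                                      v$device, p))
      ggplot2::ggsave(f, plot_bland_altman(v, p), width = 6, height = 4)
    }
  }
  invisible(out_dir)
}
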