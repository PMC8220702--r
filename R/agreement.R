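# Radiologist-agreement evaluation battery: symmetric percent differences,
# Bland-Altman limits of agreement, pixel-difference metrics, ICC(2,1)
# (two-way random effects, absolute agreement, single measurement) with
# F-based confidence intervals, and Bonferroni-corrected pairwise group
# comparisons.

#' Symmetric percent difference between two measurements
#'
#' `200 * (m_dl - m_human) / (m_dl + m_human)`, antisymmetric under swapping
#' the arguments and bounded in (-200, 200) for positive inputs.
#'
#' @param m_dl,m_human Measurements (cm); vectorized.
#' @return Percent difference(s).
#' @examples
#' percent_difference(2, 1)  # 66.67%
#' @export
percent_difference <- function(m_dl, m_human) {
  s <- m_dl + m_human
  if (any(s <= 0))
    stop_lesionruler("measurement sum must be > 0", "lesionruler_parameter_error")
  200 * (m_dl - m_human) / s
}

#' Bland-Altman analysis of percent differences
#'
#' Per-pair symmetric percent differences; limits of agreement at
#' `mean +/- 1.96 * SD` (sample SD, n-1 denominator); outliers are pairs
#' strictly outside the closed LOA interval.
#'
#' @param m_dl,m_human Paired measurement vectors (cm), length >= 2.
#' @return List with `mean_pct_diff`, `sd_pct_diff`, `loa` (lower, upper),
#'   `outside_indices`, `pct_diffs`, `n`.
#' @export
bland_altman <- function(m_dl, m_human) {
  if (length(m_dl) != length(m_human) || length(m_dl) < 2)
    stop_lesionruler("need >= 2 measurement pairs", "lesionruler_insufficient_data")
  d <- percent_difference(m_dl, m_human)
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(lower = m - 1.96 * s, upper = m + 1.96 * s)
  list(mean_pct_diff = m, sd_pct_diff = s, loa = loa,
       outside_indices = which(d < loa[1] | d > loa[2]),
       pct_diffs = d, n = length(d))
}

#' Percent measurement difference implied by a pixel difference
#'
#' `100 * (diff_px * spacing_cm) / size_cm`: how large a given pixel
#' discrepancy is relative to the lesion size.  A 5-pixel difference at
#' 0.1 cm/px is 10% of a 5 cm lesion but 25% of a 2 cm lesion, which is why
#' percent differences rather than raw pixel differences are the primary
#' agreement currency.
#'
#' @param diff_px Measurement difference in pixels.
#' @param spacing_cm Pixel spacing, cm/px (> 0).
#' @param size_cm Lesion size, cm (> 0).
#' @return Percent difference.
#' @examples
#' pixel_difference_percent(5, 0.1, 5)  # 10%
#' pixel_difference_percent(5, 0.1, 2)  # 25%
#' @export
pixel_difference_percent <- function(diff_px, spacing_cm, size_cm) {
  if (any(spacing_cm <= 0) || any(size_cm <= 0))
    stop_lesionruler("spacing_cm and size_cm must be > 0", "lesionruler_parameter_error")
  100 * (diff_px * spacing_cm) / size_cm
}

#' Mean pixel difference between paired measurements
#'
#' Converts each pair's measurement difference into pixels via its own
#' spacing and summarizes with mean and sample SD.  Absolute differences by
#' default; `signed = TRUE` keeps the sign.
#'
#' @param m_dl,m_human Paired measurements (cm), length >= 2.
#' @param spacing_cm Per-pair pixel spacing (cm/px), recycled if length 1.
#' @param signed Use signed differences instead of magnitudes.
#' @return List with `mean_px`, `sd_px`, `n`.
#' @export
mean_pixel_difference <- function(m_dl, m_human, spacing_cm, signed = FALSE) {
  if (length(m_dl) != length(m_human) || length(m_dl) < 2)
    stop_lesionruler("need >= 2 measurement pairs", "lesionruler_insufficient_data")
  if (any(spacing_cm <= 0))
    stop_lesionruler("spacing_cm must be > 0", "lesionruler_parameter_error")
  d <- (m_dl - m_human) / spacing_cm
  if (!signed) d <- abs(d)
  list(mean_px = mean(d), sd_px = stats::sd(d), n = length(d))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' From the two-way ANOVA decomposition of an `n x k` matrix (targets in
#' rows, raters in columns):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' where MSR, MSC and MSE are the row, column and residual mean squares.
#' Absolute agreement penalizes systematic bias between raters.  The
#' confidence interval is the standard F-based interval for this form
#' (Satterthwaite degrees of freedom for the column/error combination).
#'
#' @param m Numeric `n x k` matrix, `n >= 2` targets, `k >= 2` raters, no
#'   missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (lo, hi), the mean squares, and a
#'   `degenerate` flag (identical columns: ICC 1 with no finite CI).
#' @export
icc_two_way_random <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2 || anyNA(m))
    stop_lesionruler("need a complete matrix with >= 2 rows and >= 2 columns",
                     "lesionruler_parameter_error")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || sst < 1e-300) {
    return(list(icc = 1, ci = c(NA_real_, NA_real_), msr = msr, msc = msc,
                mse = mse, n = n, k = k, degenerate = TRUE))
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower, upper), msr = msr, msc = msc, mse = mse,
       n = n, k = k, degenerate = FALSE)
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' Welch two-sample t-tests on percent errors for every unordered pair of
#' groups; p-values are Bonferroni-adjusted (`min(1, p * n_pairs)`) with
#' significance at adjusted p < 0.05.  Groups with fewer than 2 observations
#' are skipped with a warning.
#'
#' @param errors_by_group Named list mapping group label to a numeric vector
#'   of (signed) percent errors.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame with columns `group_i, group_j, raw_p, adjusted_p,
#'   significant`.
#' @export
bonferroni_pairwise <- function(errors_by_group, alpha = 0.05) {
  sizes <- vapply(errors_by_group, length, 0L)
  if (any(sizes < 2)) {
    warning(warningCondition(
      paste("skipping groups with < 2 observations:",
            paste(names(errors_by_group)[sizes < 2], collapse = ", ")),
      class = "lesionruler_group_skipped"))
    errors_by_group <- errors_by_group[sizes >= 2]
  }
  g <- names(errors_by_group)
  if (length(g) < 2)
    stop_lesionruler("need >= 2 groups with >= 2 observations each",
                     "lesionruler_insufficient_data")
  pairs <- utils::combn(g, 2)
  raw <- apply(pairs, 2, function(p)
    stats::t.test(errors_by_group[[p[1]]], errors_by_group[[p[2]]])$p.value)
  adj <- pmin(1, raw * ncol(pairs))
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], raw_p = raw,
             adjusted_p = adj, significant = adj < alpha,
             stringsAsFactors = FALSE)
}

#' Full agreement report for a set of measurement pairs
#'
#' Combines ICC(2,1), Bland-Altman percent-difference analysis and pixel
#' differences, and (when group labels are present) the Bonferroni pairwise
#' group comparison.
#'
#' @param pairs Data frame with columns `m_human_cm`, `m_dl_cm`,
#'   `spacing_cm`, optionally `case_id` and `invasion_group`.
#' @param conf_level Confidence level for the ICC interval.
#' @return An `agreement_report` list: `icc`, `icc_ci`, `mean_pct_diff`,
#'   `sd_pct_diff`, `loa`, `n_outside_loa`, `outside_indices`, `mean_px_diff`,
#'   `sd_px_diff`, `n`, and `group_comparison` when groups were given.
#' @export
agreement_report <- function(pairs, conf_level = 0.95) {
  need <- c("m_human_cm", "m_dl_cm", "spacing_cm")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop_lesionruler(paste("pairs lacks columns:", paste(miss, collapse = ", ")),
                     "lesionruler_format_error")
  if (any(pairs$m_human_cm <= 0) || any(pairs$m_dl_cm <= 0) ||
      any(pairs$spacing_cm <= 0))
    stop_lesionruler("measurements and spacings must be > 0",
                     "lesionruler_parameter_error")
  icc <- icc_two_way_random(cbind(pairs$m_human_cm, pairs$m_dl_cm), conf_level)
  ba <- bland_altman(pairs$m_dl_cm, pairs$m_human_cm)
  px <- mean_pixel_difference(pairs$m_dl_cm, pairs$m_human_cm, pairs$spacing_cm)
  rep <- list(icc = icc$icc, icc_ci = icc$ci,
              mean_pct_diff = ba$mean_pct_diff, sd_pct_diff = ba$sd_pct_diff,
              loa = ba$loa, n_outside_loa = length(ba$outside_indices),
              outside_indices = ba$outside_indices, pct_diffs = ba$pct_diffs,
              mean_px_diff = px$mean_px, sd_px_diff = px$sd_px, n = ba$n)
  if ("invasion_group" %in% names(pairs) &&
      length(unique(pairs$invasion_group)) >= 2) {
    by_group <- split(ba$pct_diffs, pairs$invasion_group)
    rep$group_comparison <- tryCatch(bonferroni_pairwise(by_group),
                                     error = function(e) NULL)
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  ICC(2,1): %.3f (95%% CI %.3f, %.3f)\n", x$icc,
              x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  Mean %% difference: %.2f%% (SD %.2f%%)\n",
              x$mean_pct_diff, x$sd_pct_diff))
  cat(sprintf("  LOA: [%.2f%%, %.2f%%]; %d outside\n",
              x$loa[1], x$loa[2], x$n_outside_loa))
  cat(sprintf("  Mean pixel difference: %.2f (SD %.2f)\n",
              x$mean_px_diff, x$sd_px_diff))
  if (!is.null(x$group_comparison))
    cat(sprintf("  Group comparison: %d pairs, %d significant\n",
                nrow(x$group_comparison), sum(x$group_comparison$significant)))
  invisible(x)
}

#' Simulate human/algorithm measurement pairs for phantoms
#'
#' Fabricates a paired-measurement table from phantom ground truth:
#' `human = truth * (1 + e_h)` and `dl = truth * (1 + bias_g + e_dl)` with
#' independent Gaussian relative errors.  Useful for exercising the
#' agreement battery and for power checks of the group comparison.
#'
#' @param cases List of `phantom_case` objects.
#' @param sd_pct_human,sd_pct_dl Relative error SDs, percent.
#' @param bias_pct_by_group Named vector of per-group systematic biases
#'   (percent) injected into the simulated algorithm measurements.
#' @param rng_seed Integer seed.
#' @return Data frame with `case_id, m_human_cm, m_dl_cm, spacing_cm,
#'   invasion_group`.
#' @export
simulate_measurement_pairs <- function(cases, sd_pct_human = 3, sd_pct_dl = 3,
                                       bias_pct_by_group = NULL, rng_seed = 1) {
  truth <- vapply(cases, `[[`, 0, "true_diameter_cm")
  grp <- vapply(cases, `[[`, "", "invasion_group")
  bias <- rep(0, length(cases))
  if (!is.null(bias_pct_by_group)) {
    hit <- grp %in% names(bias_pct_by_group)
    bias[hit] <- bias_pct_by_group[grp[hit]]
  }
  with_seed(rng_seed, {
    data.frame(
      case_id = vapply(cases, `[[`, "", "case_id"),
      m_human_cm = truth * (1 + stats::rnorm(length(cases), 0, sd_pct_human / 100)),
      m_dl_cm = truth * (1 + bias / 100 + stats::rnorm(length(cases), 0, sd_pct_dl / 100)),
      spacing_cm = vapply(cases, `[[`, 0, "spacing_cm"),
      invasion_group = grp, stringsAsFactors = FALSE)
  })
}

#' Bland-Altman plot
#'
#' Base-graphics Bland-Altman plot: per-pair percent difference against the
#' pair mean, with the systematic difference and limits of agreement drawn.
#'
#' @param m_dl,m_human Paired measurements (cm).
#' @param ... Passed to [graphics::plot()].
#' @return The [bland_altman()] summary, invisibly.
#' @export
plot_bland_altman <- function(m_dl, m_human, ...) {
  ba <- bland_altman(m_dl, m_human)
  avg <- (m_dl + m_human) / 2
  graphics::plot(avg, ba$pct_diffs, xlab = "Mean measurement (cm)",
                 ylab = "Percent difference (%)", ...)
  graphics::abline(h = ba$mean_pct_diff, lwd = 2)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}
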