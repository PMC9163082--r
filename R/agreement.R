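#' Paired EF table
#'
#' Validates a table of paired ejection-fraction estimates: one row per
#' subject with an estimated and a reference EF (percent).
#'
#' @param id Character vector of subject identifiers.
#' @param ef_estimated,ef_reference Numeric EF values, percent.
#' @return A `data.frame` with columns `id`, `ef_estimated`, `ef_reference`.
#' @export
paired_ef <- function(id, ef_estimated, ef_reference) {
  if (length(ef_estimated) != length(ef_reference) ||
      length(id) != length(ef_estimated))
    stopf("id, ef_estimated and ef_reference must have equal length")
  if (any(!is.finite(ef_estimated)) || any(!is.finite(ef_reference)))
    stopf("EF values must be finite")
  data.frame(id = as.character(id), ef_estimated = as.numeric(ef_estimated),
             ef_reference = as.numeric(ef_reference))
}

#' Read a paired EF table from CSV
#'
#' @param path CSV file with columns `id`, `ef_estimated`, `ef_reference`.
#' @return A validated `data.frame` (see [paired_ef()]).
#' @export
read_paired_ef <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "ef_estimated", "ef_reference")
  if (!all(need %in% names(df)))
    stopf("CSV must have columns %s", paste(need, collapse = ", "))
  paired_ef(df$id, df$ef_estimated, df$ef_reference)
}

#' Mean absolute EF difference
#'
#' `MD = mean(|EF_estimated - EF_reference|)` with the sample sd of the
#' absolute differences. With a single pair the sd is reported as 0 with a
#' warning.
#'
#' @param pairs A paired EF table (see [paired_ef()]).
#' @return Named numeric: `md`, `sd`.
#' @export
mean_abs_diff <- function(pairs) {
  if (!nrow(pairs)) stopf("empty input")
  a <- abs(pairs$ef_estimated - pairs$ef_reference)
  s <- if (length(a) < 2) {
    warnf("sd of |differences| undefined for n = 1; reporting 0")
    0
  } else stats::sd(a)
  c(md = mean(a), sd = s)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = estimated - reference`: bias (mean difference), limits of
#' agreement `bias +/- 1.96 sd`, 95% CIs (t-based for the bias;
#' the classical `sd * sqrt(3/n)` approximation for each limit), a
#' proportional-bias check (least-squares slope of d on the pair means, with
#' its p-value), and a flag for a significant bias (0 outside the bias CI).
#'
#' @param pairs A paired EF table with `n >= 3` rows.
#' @param loa_multiplier Multiplier of sd for the limits (default 1.96).
#' @return An object of class `agreement_report`.
#' @export
bland_altman <- function(pairs, loa_multiplier = 1.96) {
  n <- nrow(pairs)
  if (n < 3) stopf("Bland-Altman analysis needs at least 3 pairs")
  d <- pairs$ef_estimated - pairs$ef_reference
  m <- (pairs$ef_estimated + pairs$ef_reference) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_upper <- bias + loa_multiplier * sd_diff
  loa_lower <- bias - loa_multiplier * sd_diff
  tq <- stats::qt(0.975, n - 1)
  ci_bias <- bias + c(-1, 1) * tq * sd_diff / sqrt(n)
  half_loa <- tq * sd_diff * sqrt(3 / n)
  slope_p <- if (sd_diff == 0 || stats::var(m) == 0) NA_real_ else {
    fit <- stats::lm(d ~ m)
    stats::coef(summary(fit))[2, 4]
  }
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_upper = loa_upper, loa_lower = loa_lower,
                 ci_bias = ci_bias,
                 ci_loa_upper = loa_upper + c(-1, 1) * half_loa,
                 ci_loa_lower = loa_lower + c(-1, 1) * half_loa,
                 bias_significant = ci_bias[1] > 0 | ci_bias[2] < 0,
                 slope_p = slope_p,
                 md = unname(mean_abs_diff(pairs)["md"]),
                 md_sd = unname(mean_abs_diff(pairs)["sd"])),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  MD  %.3f +/- %.3f\n", x$md, x$md_sd))
  cat(sprintf("  bias %.3f +/- %.3f (95%% CI %.3f to %.3f)%s\n",
              x$bias, x$sd_diff, x$ci_bias[1], x$ci_bias[2],
              if (isTRUE(x$bias_significant)) " *significant*" else ""))
  cat(sprintf("  LoA  %.3f / %.3f\n", x$loa_lower, x$loa_upper))
  if (!is.na(x$slope_p))
    cat(sprintf("  proportional-bias slope p = %.3g\n", x$slope_p))
  invisible(x)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests of the mean difference against `-margin` and
#' `+margin`; the TOST p-value is the larger of the two one-sided p-values,
#' and equivalence is declared when it is below `alpha`. This is the paired
#' simplification of an equivalence contrast (the study-design version with
#' operator/animal random effects is out of scope); output is labelled
#' accordingly. Zero-variance differences are decided exactly by comparing
#' `|bias|` with the margin.
#'
#' @param pairs A paired EF table with `n >= 3` rows.
#' @param margin Equivalence margin, EF percentage points (default 2).
#' @param alpha Test level (default 0.05).
#' @return List with `p_value`, `equivalent`, `bias`, `margin`, `method`.
#' @export
tost_equivalence <- function(pairs, margin = 2, alpha = 0.05) {
  if (margin <= 0) stopf("margin must be positive")
  n <- nrow(pairs)
  if (n < 3) stopf("equivalence test needs at least 3 pairs")
  d <- pairs$ef_estimated - pairs$ef_reference
  bias <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    p <- if (abs(bias) < margin) 0 else 1
  } else {
    se <- s / sqrt(n)
    t_lo <- (bias + margin) / se  # H0: mean <= -margin
    t_hi <- (bias - margin) / se  # H0: mean >= +margin
    p <- max(stats::pt(t_lo, n - 1, lower.tail = FALSE),
             stats::pt(t_hi, n - 1))
  }
  list(p_value = p, equivalent = p < alpha, bias = bias, margin = margin,
       method = "paired TOST (simplification; no operator/animal random effects)")
}

#' Bland-Altman plot
#'
#' Scatter of differences against pair means with the bias line, limits of
#' agreement, and shaded 95% CIs. Requires ggplot2.
#'
#' @param pairs A paired EF table.
#' @param ... Passed to [bland_altman()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_bland_altman requires the ggplot2 package")
  rep <- bland_altman(pairs, ...)
  df <- data.frame(m = (pairs$ef_estimated + pairs$ef_reference) / 2,
                   d = pairs$ef_estimated - pairs$ef_reference)
  band <- function(lo, hi, fill) ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                                                   ymin = lo, ymax = hi,
                                                   alpha = 0.15, fill = fill)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    band(rep$ci_bias[1], rep$ci_bias[2], "blue") +
    band(rep$ci_loa_upper[1], rep$ci_loa_upper[2], "red") +
    band(rep$ci_loa_lower[1], rep$ci_loa_lower[2], "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "black") +
    ggplot2::geom_hline(yintercept = rep$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(rep$loa_lower, rep$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean EF (%)", y = "Difference (estimated - reference, %)")
}
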