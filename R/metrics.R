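#' Single-measure two-way intraclass correlation, absolute agreement
#'
#' ICC(2,1): two-way random-effects model with subjects and raters (here
#' the automated and the reference measurement) as random factors, single
#' measurement, absolute agreement. Computed from the two-way ANOVA mean
#' squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`
#' raters, where MSR, MSC, MSE are the subject, rater and residual mean
#' squares. The 95% confidence interval uses the F-based bounds of Shrout
#' and Fleiss with a Satterthwaite degrees-of-freedom approximation, and
#' the p-value tests the null of zero ICC with `F = MSR/MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param auto_mm numeric vector of automated measurements (mm).
#' @param ref_mm numeric vector of paired reference measurements (mm).
#' @param conf_level confidence level for the interval.
#' @return object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way_single <- function(auto_mm, ref_mm, conf_level = 0.95) {
  keep <- stats::complete.cases(auto_mm, ref_mm)
  x <- as.double(auto_mm[keep]); y <- as.double(ref_mm[keep])
  n <- length(x)
  if (n < 2 || length(y) != n)
    atk_error("need at least 2 complete measurement pairs",
              "aortrack_degenerate_input")
  m <- cbind(x, y)
  k <- 2L
  if (stats::var(x) == 0 && stats::var(y) == 0)
    atk_error("both columns are constant; ICC undefined",
              "aortrack_degenerate_input")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  fv <- msr / mse
  p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  # Shrout-Fleiss interval for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lb <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ub <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = lb, ci_high = ub, p_value = p,
                 n = n, msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  95%% CI [%.3f, %.3f]  p = %.3g  n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Per-site agreement table
#'
#' Computes [icc_two_way_single] for each measurement site and assembles a
#' table with one row per site (ICC, confidence interval, p-value, number
#' of complete pairs). Sites whose ICC cannot be computed (too few pairs,
#' zero variance) are kept as rows of `NA` with the failure reason.
#'
#' @param sites a data frame with columns `site`, `auto_mm`, `ref_mm`
#'   (one row per paired measurement), or a named list of such
#'   two-column data frames.
#' @return data frame with columns `site`, `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `reason`.
#' @export
agreement_table <- function(sites) {
  if (is.data.frame(sites)) {
    req <- c("site", "auto_mm", "ref_mm")
    if (!all(req %in% names(sites)))
      atk_error("data frame must have columns site, auto_mm, ref_mm",
                "aortrack_format_error")
    sites <- split(sites[c("auto_mm", "ref_mm")], sites$site)
  }
  if (length(sites) == 0)
    atk_error("no sites supplied", "aortrack_degenerate_input")
  rows <- lapply(names(sites), function(nm) {
    d <- sites[[nm]]
    res <- tryCatch(icc_two_way_single(d$auto_mm, d$ref_mm),
                    aortrack_error = function(e) e)
    if (inherits(res, "icc_result"))
      data.frame(site = nm, icc = res$icc, ci_low = res$ci_low,
                 ci_high = res$ci_high, p_value = res$p_value, n = res$n,
                 reason = NA_character_)
    else
      data.frame(site = nm, icc = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 n = sum(stats::complete.cases(d$auto_mm, d$ref_mm)),
                 reason = conditionMessage(res))
  })
  do.call(rbind, rows)
}

#' Read paired site measurements from CSV
#'
#' Expects columns `site`, `auto_mm`, `ref_mm`.
#'
#' @param path CSV path.
#' @return data frame suitable for [agreement_table].
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("site", "auto_mm", "ref_mm")
  if (!all(req %in% names(df)))
    atk_error("CSV must have columns site, auto_mm, ref_mm",
              "aortrack_format_error")
  df
}

#' Flag diameter spikes along a trace
#'
#' Steps whose maximal diameter exceeds a rolling median (window of 15
#' steps) by more than 50% are flagged. Such spikes arise where a
#' measurement plane extends into head-and-neck vessels or crosses
#' segmentation spurs; they are excluded from [peak_diameter] but kept in
#' profile output, where they serve as anatomical orientation cues. Traces
#' shorter than the window are never flagged.
#'
#' @param trace a [centerline_trace][track_centerline].
#' @param window rolling-median window (steps, odd).
#' @param threshold relative excess over the rolling median that flags a
#'   step (0.5 = 50%).
#' @return logical vector, one flag per step.
#' @export
spike_filter <- function(trace, window = 15L, threshold = 0.5) {
  d <- vapply(trace$steps, `[[`, 0.0, "max_diameter")
  n <- length(d)
  if (n == 0)
    atk_error("empty trace", "aortrack_empty_trace")
  if (n < window) return(rep(FALSE, n))
  med <- stats::runmed(d, k = window, endrule = "median")
  d > (1 + threshold) * med
}

#' Peak diameter of a trace
#'
#' Location (arc length) and value of the largest maximal diameter after
#' excluding spike-flagged steps -- the peak of the diameter curve that
#' represents the greatest aneurysmal dilation. Ties resolve to the first
#' occurrence along the trace.
#'
#' @param trace a [centerline_trace][track_centerline].
#' @param ... passed to [spike_filter].
#' @return list with `arc_length_mm`, `diameter_mm`, `step`.
#' @export
peak_diameter <- function(trace, ...) {
  d <- vapply(trace$steps, `[[`, 0.0, "max_diameter")
  if (length(d) == 0)
    atk_error("empty trace", "aortrack_empty_trace")
  excl <- spike_filter(trace, ...)
  if (all(excl))
    atk_error("all steps are spike-flagged; no peak", "aortrack_empty_trace")
  d[excl] <- -Inf
  i <- which.max(d)
  list(arc_length_mm = trace$steps[[i]]$arc_length,
       diameter_mm = d[i], step = i)
}
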