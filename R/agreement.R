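#' Pool paired measurements per metric
#'
#' Builds per-metric paired vectors from two index-aligned sets of
#' measurement records (e.g. human vs automated). Bilateral metrics (MRD1,
#' MRD2, PFH, HPA) contribute two pairs per face — the right and left eye
#' values pooled — while the central metrics (IPD, IICD, OICD) contribute
#' one pair per face.
#'
#' @param records_a,records_b Data frames (rows = faces) with
#'   `measurement_record` columns, or lists of single records.
#' @return Named list of `paired_measurements` objects, one per metric,
#'   each a list with `metric`, `a`, `b`, and `pooling` (`"per-eye"` or
#'   `"per-face"`).
#' @export
pool_bilateral <- function(records_a, records_b) {
  to_df <- function(r) if (is.data.frame(r)) r else do.call(rbind, r)
  A <- to_df(records_a); B <- to_df(records_b)
  if (nrow(A) != nrow(B))
    stop("record lists are misaligned: ", nrow(A), " vs ", nrow(B), " faces")
  m <- measurement_metrics()
  out <- list()
  for (f in m$bilateral) {
    ar <- rbind(cbind(A[[paste0(f, "_right")]], B[[paste0(f, "_right")]]),
                cbind(A[[paste0(f, "_left")]], B[[paste0(f, "_left")]]))
    out[[f]] <- paired_measurements(f, ar[, 1], ar[, 2], pooling = "per-eye")
  }
  for (f in m$central)
    out[[f]] <- paired_measurements(f, A[[f]], B[[f]], pooling = "per-face")
  out
}

#' Paired measurements for one metric
#'
#' @param metric Metric name.
#' @param a,b Numeric vectors of the two raters' values (mm), same length,
#'   no missing values within a pair.
#' @param pooling `"per-eye"` or `"per-face"`.
#' @return A list of class `paired_measurements`.
#' @export
paired_measurements <- function(metric, a, b, pooling = "per-face") {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed within pairs")
  structure(list(metric = metric, a = as.numeric(a), b = as.numeric(b),
                 n = length(a), pooling = pooling),
            class = "paired_measurements")
}

#' Mean absolute error between two raters
#'
#' @param pairs A [paired_measurements()] object.
#' @return List with `mae` (mean of `|a - b|`) and `sd` (sample SD of the
#'   absolute differences).
#' @export
paired_mae <- function(pairs) {
  if (pairs$n < 1) stop("empty paired measurements")
  ad <- abs(pairs$a - pairs$b)
  list(mae = mean(ad), sd = if (pairs$n > 1) sd(ad) else 0)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `a - b`. The bias is their mean, the limits of
#' agreement are bias +/- 1.96 SD, the confidence interval of the bias uses
#' the t distribution (`bias +/- t * s / sqrt(n)`), and each limit's
#' confidence interval uses the standard-error approximation
#' `t * s * sqrt(3 / n)`. With zero variance the limits collapse onto the
#' bias with zero-width intervals.
#'
#' @param pairs A [paired_measurements()] object with n >= 3.
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `bland_altman`: `bias`, `bias_ci`, `loa_lower`,
#'   `loa_lower_ci`, `loa_upper`, `loa_upper_ci`, `sd`, `n`, and `plot_data`
#'   (per-pair means and differences).
#' @export
bland_altman <- function(pairs, ci_level = 0.95) {
  if (pairs$n < 3) stop("Bland-Altman analysis needs at least 3 pairs")
  d <- pairs$a - pairs$b
  n <- pairs$n
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(1 - (1 - ci_level) / 2, n - 1)
  loa_l <- bias - 1.96 * s
  loa_u <- bias + 1.96 * s
  se_loa <- s * sqrt(3 / n)
  structure(list(
    metric = pairs$metric, n = n, bias = bias, sd = s,
    bias_ci = bias + c(-1, 1) * tq * s / sqrt(n),
    loa_lower = loa_l, loa_lower_ci = loa_l + c(-1, 1) * tq * se_loa,
    loa_upper = loa_u, loa_upper_ci = loa_u + c(-1, 1) * tq * se_loa,
    ci_level = ci_level,
    plot_data = data.frame(mean = (pairs$a + pairs$b) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n = %d): bias %.3f [%.3f, %.3f], LoA [%.3f, %.3f]\n",
              x$metric, x$n, x$bias, x$bias_ci[1], x$bias_ci[2],
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  pd <- x$plot_data
  plot(pd$mean, pd$difference, pch = 16, col = "grey30",
       xlab = "Mean of raters (mm)", ylab = "Difference (mm)",
       main = sprintf("Bland-Altman: %s", x$metric), ...)
  abline(h = x$bias, lty = 2, col = "grey20")
  abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  abline(h = c(x$loa_lower_ci, x$loa_upper_ci, x$bias_ci), lty = 3,
         col = "grey60")
  invisible(x)
}

icc_band <- function(icc) {
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

#' Intraclass correlation, single measures, absolute agreement
#'
#' ICC(A,1) from the two-way (subjects x raters) mean squares:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with the F-based confidence interval of McGraw & Wong for this form, and
#' a p-value for H0: ICC = 0 from `F = MSR / MSE` on
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom. The reliability band uses
#' the 0.5 / 0.75 / 0.9 thresholds (poor / moderate / good / excellent).
#'
#' @param pairs A [paired_measurements()] object (k = 2 raters, n >= 3).
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci`, `p`, `band`, plus the
#'   mean squares.
#' @export
icc_absolute_single <- function(pairs, ci_level = 0.95) {
  if (pairs$n < 3) stop("ICC needs at least 3 subjects")
  X <- cbind(pairs$a, pairs$b)
  n <- nrow(X); k <- ncol(X)
  row_m <- rowMeans(X); col_m <- colMeans(X); grand <- mean(X)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= .Machine$double.eps * max(1, abs(grand)))
    stop("degenerate data: zero between-subject variance, ICC undefined")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - ci_level
  if (MSE == 0 && MSC == MSE) {
    ci <- c(1, 1); p <- 0
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
    p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(metric = pairs$metric, icc = icc, ci = ci, p = p,
                 band = icc_band(icc), n = n, k = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 ci_level = ci_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) %s: %.3f [%.3f, %.3f], p %s, %s reliability (n = %d)\n",
              if (is.null(x$metric)) "" else x$metric, x$icc, x$ci[1], x$ci[2],
              format.pval(x$p, digits = 3, eps = 1e-4), x$band, x$n))
  invisible(x)
}

#' Full agreement report for two raters
#'
#' Combines [paired_mae()], [bland_altman()] and [icc_absolute_single()] per
#' metric after [pool_bilateral()] pooling.
#'
#' @inheritParams pool_bilateral
#' @param ci_level Confidence level.
#' @return A list of class `agreement_report`; its `summary` element is a
#'   data frame with one row per metric.
#' @export
agreement_report <- function(records_a, records_b, ci_level = 0.95) {
  pooled <- pool_bilateral(records_a, records_b)
  per_metric <- lapply(pooled, function(p) {
    list(pairs = p, mae = paired_mae(p), ba = bland_altman(p, ci_level),
         icc = icc_absolute_single(p, ci_level))
  })
  summary <- do.call(rbind, lapply(per_metric, function(m) {
    data.frame(metric = m$pairs$metric, n = m$pairs$n,
               mae = m$mae$mae, mae_sd = m$mae$sd,
               bias = m$ba$bias,
               loa_lower = m$ba$loa_lower, loa_upper = m$ba$loa_upper,
               icc = m$icc$icc, icc_lower = m$icc$ci[1],
               icc_upper = m$icc$ci[2], p = m$icc$p, band = m$icc$band)
  }))
  rownames(summary) <- NULL
  structure(list(per_metric = per_metric, summary = summary,
                 ci_level = ci_level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Human vs automated agreement per metric:\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s n=%4d  MAE %.2f (%.2f)  bias %+.3f  LoA [%.2f, %.2f]  ICC %.3f [%.3f, %.3f] %s\n",
                toupper(s$metric[i]), s$n[i], s$mae[i], s$mae_sd[i], s$bias[i],
                s$loa_lower[i], s$loa_upper[i], s$icc[i], s$icc_lower[i],
                s$icc_upper[i], s$band[i]))
  invisible(x)
}
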