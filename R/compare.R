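#' Deming regression
#'
#' Errors-in-variables straight-line fit for comparing two measurement
#' methods that both carry error. With `delta` the ratio of the y-error
#' variance to the x-error variance, the closed-form slope is
#' \deqn{\hat\beta = \frac{S_{yy} - \delta S_{xx} +
#'   \sqrt{(S_{yy} - \delta S_{xx})^2 + 4 \delta S_{xy}^2}}{2 S_{xy}},}
#' and the intercept \eqn{\bar y - \hat\beta \bar x}. As `delta` grows
#' without bound the estimator approaches ordinary least squares of y on x;
#' as it approaches zero, inverse (x on y) least squares. 95% confidence
#' intervals come from a leave-one-out jackknife (default) or a pairs
#' bootstrap.
#'
#' @param x,y paired measurements (>= 3 points).
#' @param variance_ratio `delta`, ratio of error variances (y over x);
#'   default 1.
#' @param ci `"jackknife"`, `"bootstrap"` or `"none"`.
#' @param conf confidence level.
#' @param nboot bootstrap resamples.
#' @param seed RNG seed (bootstrap only).
#' @return an object of class `deming_fit` with `slope`, `intercept` and
#'   their confidence intervals.
#' @export
deming <- function(x, y, variance_ratio = 1,
                   ci = c("jackknife", "bootstrap", "none"),
                   conf = 0.95, nboot = 2000, seed = 1) {
  ci <- match.arg(ci)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_domain("Deming regression needs >= 3 points")
  if (variance_ratio <= 0) stop_domain("variance_ratio must be > 0")
  est <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    sxy <- sum((x - mx) * (y - my))
    if (sxx == 0 && syy == 0) stop_domain("zero variance in x and y")
    d <- variance_ratio
    if (sxy == 0) {
      slope <- if (syy >= d * sxx) Inf else 0
    } else {
      slope <- (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) /
        (2 * sxy)
    }
    c(slope = slope, intercept = my - slope * mx)
  }
  coefs <- est(x, y)
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  if (ci == "jackknife" && n > 3) {
    jack <- t(vapply(seq_len(n), function(i) est(x[-i], y[-i]), numeric(2)))
    pseudo <- matrix(rep(n * coefs, each = n), n) - (n - 1) * jack
    se <- apply(pseudo, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
    slope_ci <- coefs[1] + c(-1, 1) * tq * se[1]
    intercept_ci <- coefs[2] + c(-1, 1) * tq * se[2]
  } else if (ci == "bootstrap") {
    reps <- with_seed(seed, t(vapply(seq_len(nboot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      tryCatch(est(x[idx], y[idx]), error = function(e) c(NA_real_, NA_real_))
    }, numeric(2))))
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    slope_ci <- stats::quantile(reps[, 1], probs, na.rm = TRUE, names = FALSE)
    intercept_ci <- stats::quantile(reps[, 2], probs, na.rm = TRUE,
                                    names = FALSE)
  }
  structure(list(slope = unname(coefs[1]), intercept = unname(coefs[2]),
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 variance_ratio = variance_ratio, n = n, ci_method = ci,
                 conf = conf),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (n = %d, delta = %g)\n", x$n,
              x$variance_ratio))
  cat(sprintf("  slope     %.3f (%.0f%% CI %.3f - %.3f)\n", x$slope,
              100 * x$conf, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.3f (%.0f%% CI %.3f - %.3f)\n", x$intercept,
              100 * x$conf, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (y - x) and 95% limits of agreement
#' `mean +/- 1.96 * SD` of the paired differences; applied on the log10
#' concentration scale in method-comparison studies.
#'
#' @param x,y paired measurements (>= 2 points).
#' @return list with `mean_difference`, `sd_difference`, `loa_lower`,
#'   `loa_upper`, `differences`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop_domain("need >= 2 points")
  d <- y - x
  m <- mean(d); s <- stats::sd(d)
  list(mean_difference = m, sd_difference = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       differences = d)
}

#' Replicate precision as log10 standard deviation
#'
#' Precision of technical replicates measured as the standard deviation of
#' log10-transformed concentrations per dilution level. Zero-result
#' replicates cannot be log-transformed; they are excluded from the SD and
#' counted separately, mirroring the accounting for dilution levels near
#' the detection limit where only some replicates return a nonzero result.
#'
#' @param concs concentrations (copies/uL), possibly with zeros/NA.
#' @param level optional level labels (same length); one row per level.
#' @return data frame with `level`, `n`, `n_nonzero`, `n_zero`,
#'   `mean_log10`, `sd_log10` (NA when fewer than 2 nonzero replicates).
#' @export
replicate_precision <- function(concs, level = NULL) {
  level <- level %||% rep("all", length(concs))
  out <- lapply(split(concs, level), function(v) {
    nz <- v[!is.na(v) & v > 0]
    data.frame(n = length(v), n_nonzero = length(nz),
               n_zero = sum(!is.na(v) & v == 0),
               mean_log10 = if (length(nz)) mean(log10(nz)) else NA_real_,
               sd_log10 = if (length(nz) >= 2) stats::sd(log10(nz)) else NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(level = names(out), res, row.names = NULL)
}

#' Full two-method comparison report
#'
#' Aggregates per-replicate measurements to level means (as done when
#' regressing mean results per dilution level), log10-transforms, and
#' reports Deming regression, Pearson correlation and Bland-Altman
#' agreement between the two methods.
#'
#' @param data data frame with columns `level`, `method_x`, `method_y`
#'   (concentrations, copies/uL; replicate rows allowed).
#' @param log10_transform analyse on the log10 scale (default TRUE).
#' @param aggregate aggregate replicates to level means before comparison.
#' @param variance_ratio passed to [deming()].
#' @param ... further arguments to [deming()].
#' @return an object of class `comparison_report` with elements `deming`,
#'   `pearson` (r, p), `bland_altman`, and the analysed `data`.
#' @export
compare_methods <- function(data, log10_transform = TRUE, aggregate = TRUE,
                            variance_ratio = 1, ...) {
  stopifnot(all(c("level", "method_x", "method_y") %in% names(data)))
  if (aggregate) {
    agg <- stats::aggregate(data[c("method_x", "method_y")],
                            by = list(level = data$level), FUN = mean)
  } else agg <- data
  if (any(agg$method_x <= 0 | agg$method_y <= 0) && log10_transform)
    stop_domain("non-positive values cannot be log10 transformed")
  x <- if (log10_transform) log10(agg$method_x) else agg$method_x
  y <- if (log10_transform) log10(agg$method_y) else agg$method_y
  dm <- deming(x, y, variance_ratio = variance_ratio, ...)
  ct <- stats::cor.test(x, y, method = "pearson")
  ba <- bland_altman(x, y)
  structure(list(deming = dm,
                 pearson = list(r = unname(ct$estimate), p = ct$p.value),
                 bland_altman = ba,
                 data = agg, log10 = log10_transform),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison", if (x$log10) "(log10 scale)" else "", "\n")
  print(x$deming)
  cat(sprintf("  Pearson r = %.4f (p = %.3g)\n", x$pearson$r, x$pearson$p))
  cat(sprintf("  Bland-Altman mean difference %.3f (LoA %.3f to %.3f)\n",
              x$bland_altman$mean_difference, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  invisible(x)
}
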