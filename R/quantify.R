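#' Study design constants
#'
#' Holds the experimental constants needed to convert a Poisson lambda into
#' a sample concentration. Defaults are the study's method-comparison
#' conditions: 90,400 beads incubated with a 16 uL sample, roughly 3,300
#' beads analysed per replicate well, 12 replicates per dilution level, and
#' the reference droplet system's 0.849 nL compartment volume with an
#' overall dilution factor of 5.
#'
#' @param N_B total beads incubated with the sample.
#' @param V_S sample volume, uL.
#' @param V_C compartment (droplet) volume, nL — volume-based mode only.
#' @param D overall dilution factor — volume-based mode only.
#' @param beads_per_replicate beads analysed per replicate well.
#' @param n_replicates replicates per dilution level.
#' @return an object of class `study_design`.
#' @export
study_design <- function(N_B = 90400, V_S = 16, V_C = 0.849, D = 5,
                         beads_per_replicate = 3300, n_replicates = 12) {
  vals <- c(N_B = N_B, V_S = V_S, V_C = V_C, D = D,
            beads_per_replicate = beads_per_replicate,
            n_replicates = n_replicates)
  if (any(vals <= 0))
    stop_domain("study design fields must all be positive: ",
                paste(names(vals)[vals <= 0], collapse = ", "))
  structure(as.list(vals), class = "study_design")
}

#' Sphere volume from diameter
#'
#' Volume of a sphere of the given diameter in micrometres, returned in
#' nanolitres (`1e6 um^3 = 1 nL`). Used for bead and droplet compartment
#' volumes: a 94.8 um bead holds 0.446 nL, a 117.5 um droplet 0.849 nL.
#'
#' @param diameter sphere diameter, um.
#' @return volume in nL.
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter <= 0)) stop_domain("diameter must be > 0")
  (pi / 6) * diameter^3 / 1e6
}

# ---- one-dimensional Gaussian mixture via EM -----------------------------

# k-means initialised EM for a 1-D k-component Gaussian mixture.
# Returns means, sds, weights and the maximised log-likelihood.
gmm_em_1d <- function(x, k, n_init = 5, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  sd_floor <- max(stats::sd(x) * 1e-4, 1e-12)
  best <- NULL
  for (init in seq_len(n_init)) {
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
    mu <- as.numeric(km$centers)
    sds <- vapply(seq_len(k), function(j) {
      xi <- x[km$cluster == j]
      max(stats::sd(xi), sd_floor)
    }, numeric(1))
    sds[is.na(sds)] <- sd_floor
    w <- tabulate(km$cluster, k) / n
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sds[j]), numeric(n))
      if (k == 1) dens <- matrix(dens, ncol = 1)
      rowsum_ <- rowSums(dens)
      rowsum_[rowsum_ == 0] <- .Machine$double.xmin
      ll <- sum(log(rowsum_))
      resp <- dens / rowsum_
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sds <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk)
      sds <- pmax(sds, sd_floor)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(means = mu, sds = sds, weights = w, loglik = ll)
  }
  o <- order(best$means)
  list(means = best$means[o], sds = best$sds[o], weights = best$weights[o],
       loglik = best$loglik)
}

#' Select the modality of a bead intensity distribution
#'
#' Fits one- and two-component Gaussian mixture models to the per-bead
#' detection-channel intensities (EM with k-means initialisation and
#' multiple restarts) and selects the model with the lower Bayesian
#' information criterion, `BIC = p * ln(N) - 2 * ln(L)`. A two-component win
#' is demoted to unimodal when either component weight falls below
#' `min_fraction` (default `5/N`) or the component means are closer than
#' two pooled standard deviations — guards against spurious splits.
#'
#' @param intensities numeric vector of valid-bead intensities.
#' @param min_n minimum number of beads required; below this the result is
#'   flagged indeterminate rather than an error.
#' @param min_fraction minimum component weight for a bimodal call.
#' @param n_init number of EM restarts.
#' @param seed RNG seed for the k-means initialisations.
#' @return an object of class `threshold_result`: `modality` (1, 2 or NA),
#'   `threshold` (set by [find_threshold()] when bimodal), component
#'   `means`, `sds`, `weights`, `BIC_1`, `BIC_2`, `indeterminate`,
#'   `demoted` flags.
#' @export
select_modality <- function(intensities, min_n = 10, min_fraction = NULL,
                            n_init = 5, seed = 1) {
  x <- intensities
  N <- length(x)
  res <- structure(list(modality = NA_integer_, threshold = NA_real_,
                        means = NA_real_, sds = NA_real_, weights = NA_real_,
                        BIC_1 = NA_real_, BIC_2 = NA_real_,
                        indeterminate = TRUE, demoted = FALSE, n = N),
                   class = "threshold_result")
  if (N < min_n) return(res)
  min_fraction <- min_fraction %||% (5 / N)
  if (stats::sd(x) == 0) {
    res$modality <- 1L
    res$means <- mean(x); res$sds <- 0; res$weights <- 1
    res$indeterminate <- FALSE
    return(res)
  }
  with_seed(seed, {
    f1 <- gmm_em_1d(x, 1, n_init = 1)
    f2 <- gmm_em_1d(x, 2, n_init = n_init)
    bic1 <- 2 * log(N) - 2 * f1$loglik
    bic2 <- 5 * log(N) - 2 * f2$loglik
    modality <- if (bic2 < bic1) 2L else 1L
    demoted <- FALSE
    if (modality == 2L) {
      pooled <- sqrt(mean(f2$sds^2))
      if (min(f2$weights) < min_fraction ||
          diff(f2$means) < 2 * pooled) {
        modality <- 1L
        demoted <- TRUE
      }
    }
    fit <- if (modality == 2L) f2 else f1
    res$modality <- modality
    res$means <- fit$means; res$sds <- fit$sds; res$weights <- fit$weights
    res$BIC_1 <- bic1; res$BIC_2 <- bic2
    res$indeterminate <- FALSE
    res$demoted <- demoted
    if (modality == 2L) {
      thr <- find_threshold(x, res)
      res$threshold <- thr
      res$threshold_fallback <- isTRUE(attr(thr, "fallback"))
    }
    res
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$indeterminate) {
    cat("threshold result: indeterminate (n =", x$n, ")\n")
  } else {
    cat(sprintf("threshold result: modality %d (BIC1 %.1f, BIC2 %.1f)\n",
                x$modality, x$BIC_1, x$BIC_2))
    if (x$modality == 2)
      cat(sprintf("  threshold %.1f between means %.1f / %.1f\n",
                  x$threshold, x$means[1], x$means[2]))
  }
  invisible(x)
}

#' Positive/negative intensity threshold from a kernel density estimate
#'
#' For a bimodal intensity distribution, smooths the data with a Gaussian
#' kernel density estimate (Silverman's rule-of-thumb bandwidth) evaluated
#' on a 512-point grid restricted to the interval between the two fitted
#' component means, and places the threshold at the density minimum. Ties
#' break toward the lower intensity. If the density has no interior minimum
#' (monotone between the means), the midpoint of the means is returned with
#' a `fallback` attribute set.
#'
#' @param intensities numeric vector of intensities.
#' @param modality a `threshold_result` with `modality == 2`.
#' @return threshold intensity (numeric scalar).
#' @export
find_threshold <- function(intensities, modality) {
  if (is.na(modality$modality) || modality$modality != 2)
    stop_domain("find_threshold requires a bimodal modality result")
  mu <- sort(modality$means)
  if (mu[1] >= mu[2]) stop_domain("degenerate component means")
  d <- stats::density(intensities, bw = "nrd0", from = mu[1], to = mu[2],
                      n = 512)
  i <- which.min(d$y)  # first minimum -> lower intensity on ties
  if (i == 1 || i == 512) {
    thr <- mean(mu)
    attr(thr, "fallback") <- TRUE
    return(thr)
  }
  d$x[i]
}

#' Mean targets per compartment from the negative fraction
#'
#' Poisson estimator of the mean number of targets per compartment:
#' `lambda = -ln(N_neg / N)`. With no negative compartments the sample is
#' above the measuring range and no finite estimate exists; `NA` is
#' returned with flag `all_positive` and the resolvable lower bound
#' `ln(N)`. With all compartments negative, `lambda = 0` with flag
#' `all_negative`.
#'
#' @param N_neg number of PCR-negative compartments.
#' @param N total number of compartments (>= 1).
#' @return lambda (targets/compartment) with attribute `flags` and, when
#'   above range, `lambda_lower`.
#' @export
poisson_lambda <- function(N_neg, N) {
  if (N < 1) stop_domain("N must be >= 1")
  if (N_neg < 0 || N_neg > N) stop_domain("need 0 <= N_neg <= N")
  if (N_neg == 0) {
    lam <- NA_real_
    attr(lam, "flags") <- "all_positive"
    attr(lam, "lambda_lower") <- log(N)
    return(lam)
  }
  lam <- -log(N_neg / N)
  attr(lam, "flags") <- if (N_neg == N) "all_negative" else character(0)
  lam
}

#' Wilson interval for lambda
#'
#' Optional 95% confidence interval on lambda obtained by propagating a
#' Wilson score interval on the negative fraction `N_neg / N` through
#' `-ln`. This interval is auxiliary plumbing, not part of the published
#' analysis.
#'
#' @param N_neg,N negative and total compartment counts.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)` on the lambda scale.
#' @export
lambda_ci <- function(N_neg, N, conf = 0.95) {
  if (N_neg <= 0 || N_neg > N) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- N_neg / N
  den <- 1 + z^2 / N
  ctr <- (p + z^2 / (2 * N)) / den
  hw <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / den
  p_lo <- max(ctr - hw, 1e-12); p_hi <- min(ctr + hw, 1)
  c(-log(p_hi), -log(p_lo))
}

#' Bead-count-based target concentration
#'
#' Concentration of targets in the original sample from the bead-based
#' partitioning: `c_S = lambda * N_B / V_S`, where `N_B` is the total
#' number of beads incubated with the sample and `V_S` the sample volume.
#' No compartment-volume term enters — only the number of beads matters.
#'
#' @param lambda mean targets per bead (>= 0).
#' @param design a [study_design()].
#' @return concentration in copies/uL.
#' @export
concentration_beads <- function(lambda, design = study_design()) {
  if (any(lambda < 0, na.rm = TRUE)) stop_domain("lambda must be >= 0")
  lambda * design$N_B / design$V_S
}

#' Volume-based target concentration (droplet digital PCR)
#'
#' Conventional compartment-volume dPCR quantification:
#' `C_s = (-ln(N_neg / N) / V_C) * D`, with `V_C` the single-compartment
#' volume and `D` the overall dilution factor.
#'
#' @param N_neg,N negative and total compartment counts.
#' @param design a [study_design()] (`V_C` in nL, `D` dimensionless).
#' @return concentration in copies/uL (NA when above range).
#' @export
concentration_volume <- function(N_neg, N, design = study_design()) {
  lam <- poisson_lambda(N_neg, N)
  if (is.na(lam)) return(NA_real_)
  V_C_uL <- design$V_C * 1e-3
  as.numeric(lam) / V_C_uL * design$D
}

#' Expected targets per replicate and detection rate
#'
#' For a sample of concentration `conc` bound to `N_B` beads from `V_S` uL,
#' the expected number of targets landing on the `beads_analyzed` beads of
#' one replicate is `conc * V_S * beads_analyzed / N_B`; the probability
#' that a replicate detects at least one target (its best achievable
#' detection rate) is `1 - exp(-expected)`.
#'
#' @param conc sample concentration, copies/uL.
#' @param design a [study_design()].
#' @param beads_analyzed beads analysed in the replicate (<= `N_B`).
#' @return list with `expected_targets` and `detection_rate`.
#' @export
detection_stats <- function(conc, design = study_design(),
                            beads_analyzed = design$beads_per_replicate) {
  if (conc <= 0 || beads_analyzed <= 0) stop_domain("inputs must be positive")
  if (beads_analyzed > design$N_B)
    stop_domain("beads_analyzed cannot exceed N_B")
  expected <- conc * design$V_S * beads_analyzed / design$N_B
  list(expected_targets = expected, detection_rate = 1 - exp(-expected))
}

#' Quantify one well from per-bead intensities
#'
#' Full per-well digital PCR analysis: modality selection, threshold,
#' positive/negative classification, Poisson lambda and bead-count-based
#' concentration. Unimodal wells are resolved against a positive-control
#' intensity: a single component below it means all beads are negative
#' (lambda 0), above it all positive (above range); without a control the
#' well is flagged indeterminate.
#'
#' @param intensities valid-bead detection-channel intensities.
#' @param design a [study_design()].
#' @param positive_control intensity of a known-positive control; used only
#'   to interpret unimodal wells.
#' @param min_n minimum bead count for quantification.
#' @param threshold fixed classification threshold; when supplied the
#'   mixture/modality step is skipped and beads are classified directly.
#'   Useful for run-level thresholds shared across replicate wells, which
#'   keep wells with only a handful of positive beads quantifiable.
#' @param ci also report a 95% Wilson interval on lambda and concentration.
#' @param seed RNG seed for the mixture fit.
#' @return an object of class `quant_result` with `N`, `N_neg`,
#'   `threshold`, `lambda`, `concentration`, `flags`, and the
#'   `threshold_result`.
#' @export
quantify_well <- function(intensities, design = study_design(),
                          positive_control = NULL, min_n = 10,
                          threshold = NULL, ci = FALSE, seed = 1) {
  N <- length(intensities)
  fixed_thr <- !is.null(threshold) && is.finite(threshold)
  tr <- if (fixed_thr)
    structure(list(modality = 2L, threshold = threshold, means = NA_real_,
                   sds = NA_real_, weights = NA_real_, BIC_1 = NA_real_,
                   BIC_2 = NA_real_, indeterminate = FALSE, demoted = FALSE,
                   n = N), class = "threshold_result")
  else select_modality(intensities, min_n = min_n, seed = seed)
  flags <- character(0)
  N_neg <- NA_integer_; lam <- NA_real_; conc <- NA_real_; thr <- NA_real_
  lam_ci <- conc_ci <- c(NA_real_, NA_real_)
  if (tr$indeterminate) {
    flags <- "indeterminate"
  } else if (tr$modality == 2L) {
    thr <- tr$threshold
    N_neg <- sum(intensities <= thr)
    lam0 <- poisson_lambda(N_neg, N)
    flags <- attr(lam0, "flags")
    lam <- as.numeric(lam0)
    if (!is.na(lam)) conc <- concentration_beads(lam, design)
    else flags <- union(flags, "above_range")
    if (ci && !is.na(lam)) {
      lam_ci <- lambda_ci(N_neg, N)
      conc_ci <- concentration_beads(lam_ci, design)
    }
  } else {
    if (is.null(positive_control)) {
      flags <- "indeterminate"
    } else if (tr$means[1] < positive_control) {
      N_neg <- N; lam <- 0; conc <- 0; flags <- "all_negative"
    } else {
      N_neg <- 0L; flags <- c("all_positive", "above_range")
    }
  }
  structure(list(N = N, N_neg = N_neg, threshold = thr, lambda = lam,
                 concentration = conc, flags = flags, design = design,
                 lambda_ci = lam_ci, concentration_ci = conc_ci,
                 threshold_result = tr),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant result: N = %d, N_neg = %s, lambda = %s, conc = %s cp/uL\n",
              x$N, format(x$N_neg), format(signif(x$lambda, 4)),
              format(signif(x$concentration, 4))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify a set of replicate wells
#'
#' Applies [quantify_well()] per replicate (default) or pools all beads of
#' a level into a single estimate.
#'
#' @param intensity_sets list of per-well intensity vectors.
#' @param design a [study_design()].
#' @param mode `"per_replicate"` or `"pooled"`.
#' @param ... passed to [quantify_well()].
#' @return for per-replicate mode, a data frame with one row per well
#'   (`well`, `N`, `N_neg`, `threshold`, `lambda`, `concentration`,
#'   `flags`); for pooled mode a single `quant_result`.
#' @export
quantify_run <- function(intensity_sets, design = study_design(),
                         mode = c("per_replicate", "pooled"), ...) {
  mode <- match.arg(mode)
  if (mode == "pooled")
    return(quantify_well(unlist(intensity_sets), design = design, ...))
  rows <- lapply(seq_along(intensity_sets), function(i) {
    q <- quantify_well(intensity_sets[[i]], design = design, ...)
    data.frame(well = i, N = q$N, N_neg = q$N_neg, threshold = q$threshold,
               lambda = q$lambda, concentration = q$concentration,
               flags = paste(q$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
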