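#' Langmuir adsorption isotherm
#'
#' Saturable equilibrium binding: `bound = q_max * free / (K_D + free)`.
#' At `free = K_D` the beads are half-saturated; as `free` grows the bound
#' amount approaches the capacity `q_max`. The degenerate point
#' `K_D = free = 0` is defined as the saturation limit `q_max`.
#'
#' @param free equilibrium free concentration, ng/uL (>= 0).
#' @param q_max per-bead capacity, ng/bead (>= 0).
#' @param K_D dissociation constant, ng/uL (>= 0).
#' @return bound amount per bead, ng.
#' @export
langmuir_isotherm <- function(free, q_max, K_D) {
  if (any(c(free, q_max, K_D) < 0)) stop_domain("arguments must be >= 0")
  ifelse(K_D + free == 0, q_max, q_max * free / (K_D + free))
}

#' Langmuir adsorption kinetics (finite bath)
#'
#' Time course of DNA binding to a finite bead capacity from a finite,
#' depleting solution: the bound concentration follows
#' `db/dt = (k_a / b_max) * (C0 - b) * (b_max - b)`, whose integral is
#' \deqn{b_t = \frac{C_0 b_{max} (1 - e^{-k_a t (C_0 - b_{max})/b_{max}})}
#'                  {C_0 - b_{max} e^{-k_a t (C_0 - b_{max})/b_{max}}}.}
#' It starts at `b_0 = 0`, increases monotonically, and saturates at
#' `min(C0, b_max)`: either the DNA supply or the bead capacity runs out.
#' When `C0 = b_max` the expression degenerates to the logistic limit
#' `b_t = C0 * k_a * t / (1 + k_a * t)`.
#'
#' @param t time, s (>= 0); vectorised.
#' @param k_a adsorption rate constant, 1/s.
#' @param b_max maximum bound concentration (bead capacity expressed per
#'   solution volume), ng/uL.
#' @param C0 initial free DNA concentration, ng/uL.
#' @return bound concentration at each time, ng/uL.
#' @export
langmuir_kinetics <- function(t, k_a, b_max, C0) {
  if (any(t < 0)) stop_domain("t must be >= 0")
  if (any(c(k_a, b_max, C0) < 0)) stop_domain("parameters must be >= 0")
  if (b_max == 0 || C0 == 0 || k_a == 0) return(rep(0, length(t)))
  if (abs(C0 - b_max) < 1e-9 * max(C0, b_max)) {
    return(C0 * k_a * t / (1 + k_a * t))
  }
  g <- k_a * (C0 - b_max) / b_max
  if (g > 0) {
    E <- exp(-g * t)
    C0 * b_max * (1 - E) / (C0 - b_max * E)
  } else {
    # C0 < b_max: rewrite with the decaying exponential for stability
    E2 <- exp(g * t)
    C0 * b_max * (E2 - 1) / (C0 * E2 - b_max)
  }
}

# Common scaffolding for the two nonlinear fits: multi-start nlsLM, then
# bootstrap / asymptotic 95% CIs.
langmuir_fit_result <- function(fit, data, model, ci, nboot, seed, refit) {
  est <- stats::coef(fit)
  conf <- 0.95
  lower <- upper <- rep(NA_real_, length(est))
  names(lower) <- names(upper) <- names(est)
  if (ci == "asymptotic") {
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
    if (!is.null(se)) {
      tq <- stats::qt(1 - (1 - conf) / 2, df = nrow(data) - length(est))
      lower <- est - tq * se
      upper <- est + tq * se
    }
  } else if (ci == "bootstrap") {
    boots <- with_seed(seed, {
      reps <- matrix(NA_real_, nboot, length(est))
      for (b in seq_len(nboot)) {
        for (try_ in 1:20) {
          idx <- sample.int(nrow(data), replace = TRUE)
          if (length(unique(data[idx, 1])) >= 3) break
        }
        cf <- tryCatch(stats::coef(refit(data[idx, , drop = FALSE], est)),
                       error = function(e) NULL)
        if (!is.null(cf)) reps[b, ] <- cf
      }
      reps
    })
    qs <- apply(boots, 2, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  lower <- pmax(pmin(lower, est), 0)
  upper <- pmax(upper, est)
  structure(list(
    model = model,
    estimates = data.frame(parameter = names(est), estimate = unname(est),
                           lower = unname(lower), upper = unname(upper)),
    ci_method = ci,
    residuals = stats::residuals(fit),
    rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv %||% TRUE,
    fit = fit
  ), class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Langmuir", x$model, "fit\n")
  e <- x$estimates
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-6s %.4g  (95%% CI %.4g - %.4g, %s)\n", e$parameter[i],
                e$estimate[i], e$lower[i], e$upper[i], x$ci_method))
  cat(sprintf("  RSS %.4g over %d residuals\n", x$rss, length(x$residuals)))
  invisible(x)
}

#' Fit the Langmuir isotherm
#'
#' Nonlinear least squares fit of `bound = q_max * free / (K_D + free)` to
#' equilibrium (free, bound) data, with multi-start initial guesses
#' (`q_max` near the largest observed bound amount, `K_D` near the free
#' concentration at half of it) and 95% confidence intervals by
#' nonparametric bootstrap over rows (default) or from the asymptotic
#' covariance.
#'
#' @param data data frame with columns `free` and `bound` (ng/uL,
#'   ng/bead); at least three distinct free concentrations.
#' @param ci `"bootstrap"`, `"asymptotic"` or `"none"`.
#' @param weights `"none"` for ordinary least squares or `"relative"` for
#'   `1/bound^2` weights — the efficient choice when the readout carries
#'   constant relative (CV) noise, as photometric assays do.
#' @param nboot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `langmuir_fit` with estimates `q_max`, `K_D`.
#' @export
fit_isotherm <- function(data, ci = c("bootstrap", "asymptotic", "none"),
                         weights = c("none", "relative"),
                         nboot = 2000, seed = 1) {
  ci <- match.arg(ci)
  weights <- match.arg(weights)
  data <- data.frame(free = data$free, bound = data$bound)
  if (length(unique(data$free)) < 3)
    stop_domain("need >= 3 distinct free concentrations")
  fit1 <- function(d, start) {
    w <- if (weights == "relative") 1 / pmax(d$bound, 1e-9)^2
         else rep(1, nrow(d))
    minpack.lm::nlsLM(bound ~ q_max * free / (K_D + free), data = d,
                      start = as.list(start), weights = w,
                      lower = c(q_max = 0, K_D = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  qm0 <- max(data$bound)
  half <- qm0 / 2
  kd0 <- tryCatch(stats::approx(data$bound, data$free, xout = half,
                                ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(data$free) / 2
  starts <- expand.grid(q_max = qm0 * c(1, 1.5, 3), K_D = kd0 * c(0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(fit1(data, unlist(starts[i, ])), error = function(e) NULL)
    if (!is.null(f)) {
      rss <- stats::deviance(f)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best))
    stop_domain("isotherm fit failed to converge from all starts")
  langmuir_fit_result(best$fit, data, "isotherm", ci, nboot, seed,
                      refit = function(d, est) fit1(d, est))
}

#' Fit the Langmuir adsorption kinetics
#'
#' Nonlinear least squares fit of the finite-bath kinetic model (see
#' [langmuir_kinetics()]) to (t, bound) data for the adsorption rate
#' constant `k_a`, with `b_max` either fixed (e.g. to the isotherm's
#' capacity) or co-estimated. Rows are sorted by time internally, so the
#' fit is invariant to input order. A flat all-zero trajectory yields
#' `k_a = 0` flagged as degenerate rather than a spurious rate.
#'
#' @param data data frame with columns `t` (s) and `bound` (ng/uL).
#' @param C0 initial free concentration, ng/uL.
#' @param b_max capacity in ng/uL, or `NULL` to estimate it.
#' @param ci,nboot,seed as in [fit_isotherm()].
#' @return an object of class `langmuir_fit` with estimate `k_a` (and
#'   `b_max` when co-estimated).
#' @export
fit_kinetics <- function(data, C0, b_max = NULL,
                         ci = c("bootstrap", "asymptotic", "none"),
                         nboot = 2000, seed = 1) {
  ci <- match.arg(ci)
  data <- data.frame(t = data$t, bound = data$bound)
  data <- data[order(data$t), ]
  if (nrow(data) < 4) stop_domain("need >= 4 time points")
  if (all(data$bound == 0)) {
    out <- structure(list(
      model = "kinetics",
      estimates = data.frame(parameter = "k_a", estimate = 0,
                             lower = NA_real_, upper = NA_real_),
      ci_method = "none", residuals = rep(0, nrow(data)), rss = 0,
      converged = FALSE, degenerate = TRUE, fit = NULL),
      class = "langmuir_fit")
    return(out)
  }
  fixed_bmax <- !is.null(b_max)
  fit1 <- if (fixed_bmax) {
    force(b_max)
    function(d, start) {
      minpack.lm::nlsLM(bound ~ langmuir_kinetics(t, k_a, b_max, C0),
                        data = d, start = as.list(start["k_a"]),
                        lower = c(k_a = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  } else {
    function(d, start) {
      minpack.lm::nlsLM(bound ~ langmuir_kinetics(t, k_a, bm, C0),
                        data = d, start = as.list(start[c("k_a", "bm")]),
                        lower = c(k_a = 0, bm = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  # initial slope db/dt ~ k_a * C0 at t = 0
  pos <- data[data$t > 0, ]
  ka0 <- if (nrow(pos) > 0) max(pos$bound[1] / pos$t[1] / C0, 1e-4) else 0.1
  bm0 <- max(data$bound) * 1.1
  starts <- if (fixed_bmax)
    data.frame(k_a = ka0 * c(0.2, 1, 5, 25))
  else expand.grid(k_a = ka0 * c(0.2, 1, 5, 25), bm = bm0 * c(1, 1.5, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(fit1(data, unlist(starts[i, , drop = FALSE])),
                  error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best))
    stop_domain("kinetics fit failed to converge from all starts")
  out <- langmuir_fit_result(best$fit, data, "kinetics", ci, nboot, seed,
                             refit = function(d, est) fit1(d, est))
  if (!fixed_bmax)
    out$estimates$parameter[out$estimates$parameter == "bm"] <- "b_max"
  out
}

#' Predicted equilibrium capture fraction
#'
#' Fraction of the input DNA bound to the beads at equilibrium, from the
#' Langmuir mass balance
#' `free * volume + n_beads * q_max * free / (K_D + free) = input_mass`,
#' solved for the free concentration by a bracketed root find on
#' `[0, input_mass / volume]` to a relative tolerance of 1e-10.
#'
#' @param q_max per-bead capacity, ng.
#' @param K_D dissociation constant, ng/uL.
#' @param n_beads number of beads (0 gives capture 0).
#' @param input_mass total input DNA, ng.
#' @param volume binding volume, uL.
#' @return capture fraction in \[0, 1\], with attribute `free` (the
#'   equilibrium free concentration, ng/uL).
#' @export
capture_fraction <- function(q_max, K_D, n_beads, input_mass, volume) {
  if (q_max < 0 || K_D < 0 || n_beads < 0 || input_mass <= 0 || volume <= 0)
    stop_domain("q_max, K_D, n_beads >= 0; input_mass, volume > 0")
  if (n_beads == 0 || q_max == 0) {
    out <- 0
    attr(out, "free") <- input_mass / volume
    return(out)
  }
  if (K_D == 0) {
    # irreversible limit: beads saturate or take everything
    capacity <- n_beads * q_max
    free <- max(input_mass - capacity, 0) / volume
    out <- 1 - free * volume / input_mass
    attr(out, "free") <- free
    return(out)
  }
  f <- function(free) free * volume +
    n_beads * langmuir_isotherm(free, q_max, K_D) - input_mass
  hi <- input_mass / volume
  root <- tryCatch(
    stats::uniroot(f, c(0, hi), tol = hi * 1e-12, maxiter = 200),
    error = function(e)
      stop_domain(sprintf(
        "capture_fraction bracketing failed (q_max=%g, K_D=%g, n=%g, input=%g, V=%g): %s",
        q_max, K_D, n_beads, input_mass, volume, conditionMessage(e))))
  free <- root$root
  out <- 1 - free * volume / input_mass
  attr(out, "free") <- free
  out
}

#' Binding capacity as matrix density
#'
#' Converts a per-bead capacity into a binding-matrix density for
#' comparison with packed-resin literature values: `q_max / bead_volume`,
#' with ng/nL equal to mg/mL.
#'
#' @param q_max per-bead capacity, ng.
#' @param bead_volume single-bead volume, nL.
#' @return density in mg/mL.
#' @export
capacity_density <- function(q_max, bead_volume) {
  if (q_max <= 0 || bead_volume <= 0) stop_domain("inputs must be positive")
  q_max / bead_volume
}

#' Absorbance-to-concentration conversion for dsDNA
#'
#' One unit of absorbance at 260 nm corresponds to 50 ng/uL double-stranded
#' DNA; used to ingest photometric supernatant readings.
#'
#' @param a260 absorbance values.
#' @return concentrations in ng/uL.
#' @export
absorbance_to_conc <- function(a260) {
  if (any(a260 < 0)) stop_domain("absorbance must be >= 0")
  50 * a260
}
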