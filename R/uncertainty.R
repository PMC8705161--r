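# Sensitivity analysis: method-of-moments distribution fits, probabilistic
# sensitivity analysis with CE-plane draws and acceptability curves, one-way
# (tornado) analysis, and non-parametric bootstrap confidence intervals.

#' Fit a Beta distribution by the method of moments
#'
#' Solves `alpha = mean * k`, `beta = (1 - mean) * k` with
#' `k = mean(1 - mean)/sd^2 - 1`. A standard deviation at or beyond the
#' feasibility bound `sqrt(mean(1 - mean))` admits no Beta (k <= 0), and a
#' standard deviation just inside the bound yields a degenerate two-point
#' mass; both cases are repaired by shrinking the sd to 0.95 times the bound
#' and flagged. `sd = 0` yields a flagged degenerate (point-mass) fit.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation (>= 0).
#' @return A list of class `"dist_fit"`: `family = "beta"`, `shape1`,
#'   `shape2`, `mean`, `sd` (possibly repaired), `target_mean`, `target_sd`,
#'   `repaired`.
#' @export
beta_from_moments <- function(mean, sd) {
  if (!(mean > 0 && mean < 1)) stop("beta mean must be in (0,1)")
  if (sd < 0) stop("sd must be >= 0")
  bound <- sqrt(mean * (1 - mean))
  repaired <- FALSE
  if (sd == 0) {
    return(structure(list(family = "degenerate", value = mean, mean = mean,
                          sd = 0, target_mean = mean, target_sd = 0,
                          repaired = FALSE), class = "dist_fit"))
  }
  if (sd > 0.95 * bound) {
    sd <- 0.95 * bound
    repaired <- TRUE
  }
  k <- mean * (1 - mean) / sd^2 - 1
  structure(list(family = "beta", shape1 = mean * k, shape2 = (1 - mean) * k,
                 mean = mean, sd = sd, target_mean = mean,
                 target_sd = if (repaired) NA_real_ else sd,
                 repaired = repaired),
            class = "dist_fit")
}

#' Fit a Gamma distribution by the method of moments
#'
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`; the implied moments match the
#' inputs exactly. `sd = 0` is an error for the Gamma family proper; use a
#' degenerate fit instead.
#'
#' @param mean Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return A `dist_fit` with `family = "gamma"`, `shape`, `scale`.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0) stop("gamma mean must be > 0")
  if (sd <= 0) stop("gamma sd must be > 0")
  structure(list(family = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean,
                 mean = mean, sd = sd, target_mean = mean, target_sd = sd,
                 repaired = FALSE),
            class = "dist_fit")
}

#' Fit a log-normal distribution from an arithmetic mean and log-scale sd
#'
#' `mu = log(mean) - log_sd^2/2` so the arithmetic mean of the distribution
#' equals the requested mean; `sigma = log_sd`.
#'
#' @param mean Arithmetic mean (> 0).
#' @param log_sd Standard deviation on the log scale (> 0).
#' @return A `dist_fit` with `family = "lognormal"`, `meanlog`, `sdlog`.
#' @export
lognormal_from_moments <- function(mean, log_sd) {
  if (mean <= 0) stop("lognormal mean must be > 0")
  if (log_sd <= 0) stop("lognormal log_sd must be > 0")
  structure(list(family = "lognormal", meanlog = log(mean) - log_sd^2 / 2,
                 sdlog = log_sd, mean = mean,
                 sd = mean * sqrt(exp(log_sd^2) - 1),
                 target_mean = mean, target_sd = NA_real_, repaired = FALSE),
            class = "dist_fit")
}

#' Sample from a fitted distribution
#'
#' @param fit A `dist_fit`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_fit <- function(fit, n) {
  switch(fit$family,
    beta = stats::rbeta(n, fit$shape1, fit$shape2),
    gamma = stats::rgamma(n, shape = fit$shape, scale = fit$scale),
    lognormal = stats::rlnorm(n, fit$meanlog, fit$sdlog),
    degenerate = rep.int(fit$value, n),
    stop("unknown family: ", fit$family)
  )
}

#' Distribution fits for every uncertain parameter of a bundle
#'
#' Beta (method of moments, with feasibility repair) for transition
#' probabilities and utilities, Gamma for costs, log-normal for the
#' hospitalisation relative risk (the tabulated dispersion for the relative
#' risk is unusable as a standard deviation, so the configurable log-scale
#' sd `effect$rr_log_sd` is used and flagged in manifests).
#'
#' @param bundle A `param_bundle`.
#' @return Named list of `dist_fit` objects, one per [param_table()] row.
#' @export
psa_fits <- function(bundle) {
  tab <- param_table(bundle)
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    if (tab$sd[i] == 0) {
      # zero dispersion: point mass at the mean, whatever the family
      return(structure(list(family = "degenerate", value = tab$value[i],
                            mean = tab$value[i], sd = 0,
                            target_mean = tab$value[i], target_sd = 0,
                            repaired = FALSE), class = "dist_fit"))
    }
    switch(tab$distribution[i],
      beta = beta_from_moments(tab$value[i], tab$sd[i]),
      gamma = gamma_from_moments(tab$value[i], tab$sd[i]),
      lognormal = lognormal_from_moments(tab$value[i], tab$sd[i])
    )
  })
  names(fits) <- tab$name
  fits
}

# Apply one row of sampled parameter values to a bundle, repairing row
# feasibility by renormalising hospitalisation + death when their sum
# leaves no room for the residual stay probability. The cap reserves
# headroom for the largest monthly background mortality the run can see,
# because the engine later combines heart-failure and background death as
# competing risks within the same row.
realize_bundle <- function(bundle, values) {
  for (nm in names(values)) bundle <- set_param(bundle, nm, values[[nm]])
  p_bg_max <- annual_prob_to_monthly(max(bundle$mortality$annual_prob))
  cap <- 1 - p_bg_max
  pairs <- list(c("p_hosp_nrh", "p_death_nrh"),
                c("p_hosp_rh1", "p_death_rh1"),
                c("p_hosp_rh2", "p_death_rh2"))
  for (pr in pairs) {
    s <- sum(bundle$transitions[pr])
    if (s > cap) {
      bundle$transitions[pr] <- bundle$transitions[pr] * (cap / s)
    }
  }
  if (bundle$transitions[["p_death_rh3"]] > cap) {
    bundle$transitions[["p_death_rh3"]] <- cap
  }
  bundle$utilities <- pmin(bundle$utilities, 1)
  bundle
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its fitted distribution (the
#' relative risk once per draw, applied to the BNP arm only), repairs row
#' feasibility where independent sampling breaks it, runs the two-arm model
#' per draw, and records the incremental cost and effect.
#'
#' @param bundle A valid `param_bundle`.
#' @param n_draws Number of Monte-Carlo draws (default from config).
#' @param seed Integer seed (default from config); the (seed, bundle, n)
#'   triple fully determines the output.
#' @return A list of class `"psa_draws"`: `draws` (data frame with `draw`,
#'   `delta_cost`, `delta_qaly`, per-arm totals), `params` (matrix of
#'   sampled values, one column per parameter), `repaired_fits` (names of
#'   moment fits that needed feasibility repair), `seed`, `n_draws`.
#' @export
run_psa <- function(bundle, n_draws = bundle$config$psa_draws,
                    seed = bundle$config$seed) {
  stopifnot(n_draws >= 1)
  stop_if_invalid(bundle)
  fits <- psa_fits(bundle)
  set.seed(seed)
  values <- vapply(fits, sample_fit, numeric(n_draws), n = n_draws)
  values <- matrix(values, nrow = n_draws,
                   dimnames = list(NULL, names(fits)))
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    b <- realize_bundle(bundle, values[i, ])
    res <- run_cea(b)
    out[[i]] <- data.frame(
      draw = i,
      cost_bnp = res$arms$BNP$cost, qaly_bnp = res$arms$BNP$qaly,
      cost_standard = res$arms$STANDARD$cost,
      qaly_standard = res$arms$STANDARD$qaly,
      delta_cost = res$delta_cost, delta_qaly = res$delta_qaly
    )
  }
  structure(list(
    draws = do.call(rbind, out),
    params = values,
    repaired_fits = names(fits)[vapply(fits, `[[`, logical(1), "repaired")],
    seed = seed, n_draws = n_draws
  ), class = "psa_draws")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of PSA draws with positive net monetary
#' benefit.
#'
#' @param draws A `psa_draws` object.
#' @param wtp_grid Strictly increasing vector of WTP values (USD/QALY).
#' @return A data frame of class `"ceac_curve"`: `wtp`, `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (!length(wtp_grid)) stop("wtp grid must be non-empty")
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp grid must be strictly increasing")
  }
  d <- draws$draws
  prob <- vapply(wtp_grid, function(w) {
    mean(nmb(d$delta_cost, d$delta_qaly, w) > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_ce = prob),
            class = c("ceac_curve", "data.frame"))
}

#' One-way (tornado) sensitivity analysis
#'
#' Perturbs each uncertain parameter down and up by a fixed fraction
#' (default 20%), clips probabilities and utilities into their valid range
#' (recording the clip), reruns the full deterministic two-arm model at each
#' extreme, and reports the outcome range per parameter sorted by bar width.
#' The default outcome is the net monetary benefit at the configured
#' threshold, which stays sign-stable around dominance; `outcome = "icer"`
#' reports the raw ratio instead.
#'
#' @param bundle A valid `param_bundle`.
#' @param perturbation Fraction in (0, 1); default 0.20.
#' @param outcome `"nmb"` or `"icer"`.
#' @return A data frame of class `"tornado"`: `parameter`, `low_value`,
#'   `high_value`, `outcome_low`, `outcome_high`, `width`, `clipped`,
#'   sorted by decreasing width; attribute `base_outcome`.
#' @export
tornado <- function(bundle, perturbation = 0.20, outcome = c("nmb", "icer")) {
  if (!(perturbation > 0 && perturbation < 1)) {
    stop("perturbation must be in (0,1)")
  }
  outcome <- match.arg(outcome)
  stop_if_invalid(bundle)
  tab <- param_table(bundle)
  eval_outcome <- function(b) {
    res <- run_cea(b)
    if (outcome == "nmb") res$nmb else res$delta_cost / res$delta_qaly
  }
  base_outcome <- eval_outcome(bundle)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    val <- tab$value[i]
    lo <- val * (1 - perturbation)
    hi <- val * (1 + perturbation)
    clipped <- FALSE
    if (tab$distribution[i] == "beta") {        # probabilities and utilities
      if (hi > 1) { hi <- 1; clipped <- TRUE }
      if (lo < 0) { lo <- 0; clipped <- TRUE }
    }
    out_lo <- eval_outcome(stop_if_invalid(set_param(bundle, nm, lo)))
    out_hi <- eval_outcome(stop_if_invalid(set_param(bundle, nm, hi)))
    data.frame(parameter = nm, low_value = lo, high_value = hi,
               outcome_low = out_lo, outcome_high = out_hi,
               width = abs(out_hi - out_lo), clipped = clipped)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$width), ]
  rownames(res) <- NULL
  attr(res, "base_outcome") <- base_outcome
  attr(res, "outcome") <- outcome
  class(res) <- c("tornado", "data.frame")
  res
}

#' Non-parametric percentile bootstrap confidence interval for a mean
#'
#' Resamples the data with replacement `n_reps` times (each resample of the
#' original size), takes the mean of each resample, and reports the
#' percentile interval at the requested level alongside the sample mean.
#'
#' @param values Numeric vector (at least 2 values).
#' @param n_reps Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `low`, `high`, `point`, `level`, `n_reps`.
#' @export
bootstrap_ci <- function(values, n_reps = 1000, seed = 1L, level = 0.95) {
  if (length(values) < 2) stop("need at least 2 values")
  stopifnot(n_reps >= 1)
  set.seed(seed)
  n <- length(values)
  idx <- sample.int(n, n * n_reps, replace = TRUE)
  means <- rowMeans(matrix(values[idx], nrow = n_reps))
  qs <- stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  list(low = qs[1], high = qs[2], point = mean(values),
       level = level, n_reps = n_reps)
}
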