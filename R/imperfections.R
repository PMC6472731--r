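# Injecting specific computational imperfections into the optimal
# observer and characterising the induced decision-variable error.

.IMPERFECTION_KINDS <- c("local_dv_noise", "overestimated_sigma_external",
                         "overestimated_sensory_sigmas",
                         "trialwise_sigma_noise")

#' Simulate decision-variable errors caused by computational imperfections
#'
#' Draws trials (stimuli and observations) from the generative model,
#' computes the flawless Bayesian decision variable `d(x)` and the
#' decision variable of a variant with one or more computational
#' imperfections, and summarises the error `delta_d = d_imperfect -
#' d_flawless`: Gaussian moment fit (mean = bias, SD), and the accuracy
#' loss of the imperfect variant on the same trials.
#'
#' Available kinds (`magnitude` semantics in parentheses):
#' * `"local_dv_noise"` - zero-mean Gaussian noise with SD `magnitude`
#'   added to each log local evidence before pooling (multiplicative
#'   log-normal on the evidence scale, preserving positivity);
#' * `"overestimated_sigma_external"` - the decision rule believes
#'   `magnitude * sigma_external` (factor > 1);
#' * `"overestimated_sensory_sigmas"` - believes `magnitude * sigma_low`
#'   and `magnitude * sigma_high`;
#' * `"trialwise_sigma_noise"` - item- and trial-wise log-normal jitter
#'   with SD `magnitude` log-units on the believed sensory SDs.
#'
#' @param kinds Character vector of one or more kinds above.
#' @param condition A [search_condition()] with `sigma_external > 0`.
#' @param sigma_low,sigma_high True sensory noise SDs (degrees).
#' @param magnitudes Named numeric vector (or single default per kind):
#'   noise SDs for the noise kinds, overestimation factors (> 1) for the
#'   overestimation kinds. Defaults: 0.5 (local noise), 1.5 (both
#'   overestimations), 0.3 log-units (trial-wise jitter).
#' @param n_trials Number of simulated trials.
#' @param seed Integer seed.
#' @return A list of class `"delta_d_sim"`: `delta_d` (numeric vector),
#'   `summary` (one-row tibble: `mean`, `sd`, `accuracy_loss` in
#'   percentage points, `n_trials`, `goodness` = total-variation
#'   distance to the fitted Gaussian) and `kinds`.
#' @export
simulate_delta_d <- function(kinds, condition, sigma_low, sigma_high,
                             magnitudes = NULL, n_trials = 1e5, seed = 1L) {
  .check_condition(condition)
  if (condition$sigma_external <= 0) {
    abort("Imperfection simulations need a condition with external uncertainty.")
  }
  bad <- setdiff(kinds, .IMPERFECTION_KINDS)
  if (length(bad)) {
    abort(sprintf("Unknown imperfection kind(s): %s", paste(bad, collapse = ", ")))
  }
  defaults <- c(local_dv_noise = 0.5, overestimated_sigma_external = 1.5,
                overestimated_sensory_sigmas = 1.5,
                trialwise_sigma_noise = 0.3)
  mag <- defaults
  if (!is.null(magnitudes)) mag[names(magnitudes)] <- magnitudes
  for (k in intersect(kinds, c("overestimated_sigma_external",
                               "overestimated_sensory_sigmas"))) {
    if (mag[k] <= 1) abort(sprintf("Overestimation factor for %s must exceed 1.", k))
  }
  for (k in intersect(kinds, c("local_dv_noise", "trialwise_sigma_noise"))) {
    if (mag[k] <= 0) abort(sprintf("Noise magnitude for %s must be positive.", k))
  }

  seeds <- .child_seeds(seed, 3L)
  trials <- simulate_search_trials(condition, n_trials, seed = seeds[1])
  trials <- add_observations(trials, sigma_low, sigma_high, seed = seeds[2])
  x <- .trial_matrix(trials, "x")
  rel_high <- .trial_matrix(trials, "rel") == "high"
  mu <- condition$mu_target

  sig_true <- ifelse(rel_high, sigma_high, sigma_low)
  a_flawless <- 2 * mu * x / (sig_true^2 + condition$sigma_external^2)
  d_flawless <- .log_mean_exp_rows(a_flawless)

  sig_bel <- sig_true
  sext_bel <- condition$sigma_external
  if ("overestimated_sensory_sigmas" %in% kinds) {
    sig_bel <- sig_bel * mag["overestimated_sensory_sigmas"]
  }
  if ("overestimated_sigma_external" %in% kinds) {
    sext_bel <- sext_bel * mag["overestimated_sigma_external"]
  }
  extra <- withr::with_seed(seeds[3], {
    jit <- if ("trialwise_sigma_noise" %in% kinds) {
      matrix(rnorm(length(x), 0, mag["trialwise_sigma_noise"]),
             nrow(x), ncol(x))
    } else NULL
    loc <- if ("local_dv_noise" %in% kinds) {
      matrix(rnorm(length(x), 0, mag["local_dv_noise"]), nrow(x), ncol(x))
    } else NULL
    list(jit = jit, loc = loc)
  })
  if (!is.null(extra$jit)) sig_bel <- sig_bel * exp(extra$jit)
  a_imp <- 2 * mu * x / (sig_bel^2 + sext_bel^2)
  if (!is.null(extra$loc)) a_imp <- a_imp + extra$loc
  d_imp <- .log_mean_exp_rows(a_imp)

  delta <- d_imp - d_flawless
  acc_flaw <- mean((d_flawless > 0) == trials$target_present)
  acc_imp <- mean((d_imp > 0) == trials$target_present)
  summary <- tibble(mean = mean(delta), sd = sd(delta),
                    accuracy_loss = 100 * (acc_flaw - acc_imp),
                    n_trials = as.integer(n_trials),
                    goodness = .tv_to_gaussian(delta))
  structure(list(delta_d = delta, summary = summary, kinds = kinds,
                 magnitudes = mag[kinds]),
            class = "delta_d_sim")
}

#' @export
print.delta_d_sim <- function(x, ...) {
  cat("<delta_d_sim>", paste(x$kinds, collapse = " + "), "\n")
  print(x$summary)
  invisible(x)
}

# Total-variation distance between the sample histogram and the
# moment-fitted Gaussian (descriptive goodness of the Gaussian account).
.tv_to_gaussian <- function(z, n_bins = 101) {
  m <- mean(z); s <- sd(z)
  br <- seq(min(z) - 1e-9, max(z) + 1e-9, length.out = n_bins + 1)
  obs <- tabulate(findInterval(z, br, rightmost.closed = TRUE), n_bins) /
    length(z)
  expd <- diff(pnorm(br, m, s))
  0.5 * sum(abs(obs - expd / sum(expd)))
}

#' Distributional summary of a decision-error sample
#'
#' Reports standardised skewness, excess kurtosis (with their asymptotic
#' standard errors under normality) and the total-variation distance of
#' the sample histogram from the moment-fitted Gaussian. Descriptive:
#' the Gaussian account of computational errors is an approximation, not
#' a testable null here.
#'
#' @param delta_d Numeric vector (or a `"delta_d_sim"` object), length
#'   `>= 1e4`.
#' @return A one-row tibble: `skewness`, `se_skewness`,
#'   `excess_kurtosis`, `se_kurtosis`, `tv_distance`, `n`.
#' @export
gaussianity_report <- function(delta_d) {
  if (inherits(delta_d, "delta_d_sim")) delta_d <- delta_d$delta_d
  n <- length(delta_d)
  if (n < 1e4) abort("Need at least 1e4 samples for a stable report.")
  z <- (delta_d - mean(delta_d)) / sd(delta_d)
  tibble(skewness = mean(z^3),
         se_skewness = sqrt(6 / n),
         excess_kurtosis = mean(z^4) - 3,
         se_kurtosis = sqrt(24 / n),
         tv_distance = .tv_to_gaussian(delta_d),
         n = n)
}
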