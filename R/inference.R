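# Marginal trial likelihoods, prior-constrained fitting, cross-validation.

#' Monte-Carlo settings for the marginal trial likelihood
#'
#' The probability of a response given the presented stimuli is the
#' average of the response probability over draws of the sensory
#' observations. With `common_random_numbers = TRUE` the noise draws are
#' regenerated from a fixed per-trial seed on every evaluation, so the
#' likelihood surface is deterministic in the parameters (a requirement
#' for stable optimisation) and per-trial contributions do not depend on
#' which other trials are in the set.
#'
#' @param n_mc Observation draws per trial (`>= 100`). 2000 is a good
#'   fitting default; use 1e5 for final reporting.
#' @param seed Integer seed for the noise streams.
#' @param common_random_numbers Logical; see above.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_mc = 2000, seed = 1L, common_random_numbers = TRUE) {
  .assert_scalar_number(n_mc, "n_mc", lower = 100)
  .assert_scalar_number(seed, "seed")
  structure(list(n_mc = as.integer(n_mc), seed = as.integer(seed),
                 common_random_numbers = isTRUE(common_random_numbers),
                 cache = new.env(parent = emptyenv())),
            class = "mc_config")
}

# Per-trial standard-normal observation noise, trial-major stacking
# (row i = trial + n * (draw - 1)). Each trial has its own substream
# derived from (seed, trial id), so a trial's draws are invariant to the
# composition of the set. Cached per (ids, n_mc) when small enough.
.obs_noise <- function(mc, trial_ids, n_mc) {
  n <- length(trial_ids)
  if (!mc$common_random_numbers) {
    return(matrix(rnorm(n * n_mc * 4), n * n_mc, 4))
  }
  key <- paste(mc$seed, n_mc, paste(trial_ids, collapse = ","), sep = "|")
  hit <- mc$cache$key
  if (identical(hit, key)) return(mc$cache$z)
  z <- matrix(0, n * n_mc, 4)
  stride <- n * (0:(n_mc - 1))
  for (t in seq_len(n)) {
    seed_t <- (mc$seed + 1664525 * as.numeric(trial_ids[t])) %% 2147483629
    z[t + stride, ] <- withr::with_seed(as.integer(seed_t),
                                        matrix(rnorm(4 * n_mc), n_mc, 4))
  }
  if (n * n_mc * 4 <= 4e7) {
    mc$cache$key <- key
    mc$cache$z <- z
  }
  z
}

#' Predicted "target present" probability per trial
#'
#' Computes `p(present | s)` for every trial by Monte-Carlo
#' marginalisation over the sensory observations (closed form, with no
#' Monte Carlo, in the noise-free unlimited regime). Lapse mixing is
#' applied once, and probabilities are clamped to `[1e-6, 1 - 1e-6]` for
#' numerical stability.
#'
#' @inheritParams compute_decision_variable
#' @param mc An [mc_config()].
#' @return A numeric vector of per-trial probabilities.
#' @export
predict_response_prob <- function(trials, model, params, condition = NULL,
                                  mc = mc_config()) {
  condition <- .trials_condition(trials, condition)
  info <- .model_info(model)
  lapse <- params$lapse %||% 0
  if (.is_noise_free(condition)) {
    rel_high <- .trial_matrix(trials, "rel") == "high"
    d0 <- .dv_matrix(info, .trial_matrix(trials, "s"), rel_high, params,
                     condition)
    return(.clamp_prob(.apply_lapse(.p_core(info, d0, params), lapse)))
  }
  s <- .trial_matrix(trials, "s")
  rel_high <- .trial_matrix(trials, "rel") == "high"
  n <- nrow(s)
  if (condition$display_regime == "unlimited") {
    sig_true <- matrix(condition$fixed_sensory_sd, n, 4)
  } else {
    sig_true <- ifelse(rel_high, params$sigma_high, params$sigma_low)
  }
  ids <- trials$trial %||% seq_len(n)
  # evidence coefficients of the Bayesian-family rules, with the same
  # degeneracy guards as the direct path
  if (info$family %in% c("bayesian", "sampling")) {
    sig_assumed <- .assumed_sigma(info, rel_high, params, condition)
    denom <- sig_assumed^2 + condition$sigma_external^2
    if (any(denom <= 0)) {
      abort("Degenerate evidence: assumed sigma_i and sigma_external are both 0.")
    }
    coef <- 2 * condition$mu_target / denom
  } else {
    coef <- matrix(0, n, 4)
  }
  rule <- switch(info$name,
    max = , imperfect_max = 1L,
    min_dev = , imperfect_min_dev = 2L,
    minkowski = , imperfect_minkowski = 3L,
    mean = , imperfect_mean = 4L,
    variance = , imperfect_variance = 5L,
    0L)
  if (info$family == "sampling") {
    pcore <- 2L
  } else if (.has_late_noise(info$name)) {
    pcore <- if (params$sigma_late == 0) {
      warn("sigma_late = 0: falling back to the deterministic decision rule.")
      0L
    } else 1L
  } else {
    pcore <- 0L
  }
  threshold <- if (info$family == "bayesian") 0 else params$criterion %||% 0
  # block over trials so that block_n * n_mc stays in memory budget
  block_n <- max(1L, min(n, floor(4e7 / (4 * mc$n_mc))))
  p <- numeric(n)
  for (start in seq(1L, n, by = block_n)) {
    rows <- start:min(n, start + block_n - 1L)
    z <- .obs_noise(mc, ids[rows], mc$n_mc)
    p[rows] <- .mc_present_prob_cpp(
      s[rows, , drop = FALSE], z, sig_true[rows, , drop = FALSE],
      coef[rows, , drop = FALSE], rule, condition$mu_target,
      params$beta %||% 2, pcore, info$direction, threshold,
      params$mu_late %||% 0, params$sigma_late %||% 1,
      params$n_samples %||% 1L)
  }
  .clamp_prob(.apply_lapse(p, lapse))
}

#' Log-likelihood of recorded responses under an observer model
#'
#' Sum over trials of the log marginal probability of the recorded
#' response (see [predict_response_prob()]).
#'
#' @inheritParams predict_response_prob
#' @return A single number.
#' @export
log_likelihood <- function(trials, model, params, condition = NULL,
                           mc = mc_config()) {
  if (!nrow(trials)) abort("Cannot compute a likelihood on an empty trial set.")
  if (!("response" %in% names(trials)) || anyNA(trials$response)) {
    abort("All trials must have a recorded `response`.")
  }
  p <- predict_response_prob(trials, model, params, condition, mc)
  sum(log(ifelse(trials$response, p, 1 - p)))
}

#' Prior constraints for Bayesian-observer parameters
#'
#' In the constrained fitting regime the sensory noise SDs are anchored
#' to the subject's discrimination-task estimates by Normal priors on the
#' log scale, and the lapse rate is shrunk toward small values by a Beta
#' prior. All other parameters remain unconstrained.
#'
#' @param sigma_low,sigma_high Prior anchors: the discrimination-task
#'   noise estimates, degrees.
#' @param log_sd SD of the Normal priors on `log(sigma)` (log-units).
#' @param lapse_shape1,lapse_shape2 Beta prior shape parameters for the
#'   lapse rate (default Beta(1, 24): mode 0, mean 0.04).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(sigma_low, sigma_high, log_sd = 0.25,
                       lapse_shape1 = 1, lapse_shape2 = 24) {
  .assert_scalar_number(sigma_low, "sigma_low", lower = 1e-8)
  .assert_scalar_number(sigma_high, "sigma_high", lower = 1e-8)
  .assert_scalar_number(log_sd, "log_sd", lower = 1e-8)
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high,
                 log_sd = log_sd, lapse_shape1 = lapse_shape1,
                 lapse_shape2 = lapse_shape2),
            class = "prior_spec")
}

.log_prior <- function(params, priors) {
  if (is.null(priors)) return(0)
  lp <- 0
  if (!is.null(params$sigma_low)) {
    lp <- lp + dnorm(log(params$sigma_low), log(priors$sigma_low),
                     priors$log_sd, log = TRUE)
  }
  if (!is.null(params$sigma_high)) {
    lp <- lp + dnorm(log(params$sigma_high), log(priors$sigma_high),
                     priors$log_sd, log = TRUE)
  }
  if (!is.null(params$lapse)) {
    lp <- lp + dbeta(params$lapse, priors$lapse_shape1,
                     priors$lapse_shape2, log = TRUE)
  }
  lp
}
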