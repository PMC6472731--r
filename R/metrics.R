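# Sensitivity, optimality indices, and the loss decomposition.

#' Sensitivity index d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)`. Rates of exactly 0 or 1 are
#' adjusted by the standard 1/(2n) correction (n = trials of that class)
#' before the z-transform.
#'
#' @param responses Logical vector of "target present" responses.
#' @param truth Logical vector of true target presence.
#' @return A single number.
#' @examples
#' dprime(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
dprime <- function(responses, truth) {
  if (length(responses) != length(truth)) {
    abort("`responses` and `truth` must have equal length.")
  }
  n_sig <- sum(truth)
  n_noise <- sum(!truth)
  if (n_sig == 0 || n_noise == 0) {
    abort("Need at least one target-present and one target-absent trial.")
  }
  hr <- sum(responses & truth) / n_sig
  far <- sum(responses & !truth) / n_noise
  hr <- min(max(hr, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
  far <- min(max(far, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  qnorm(hr) - qnorm(far)
}

#' Sensitivity of the optimal observer in a condition
#'
#' Simulates the flawless Bayesian observer (with the given sensory noise
#' SDs and lapse rate) on freshly drawn trials from the condition and
#' returns its d'. Used as the denominator of the optimality index: with
#' the subject's fitted noise levels it gives the *relative* benchmark;
#' with `sigma_low = sigma_high = 0` the *absolute* (noise-free)
#' benchmark.
#'
#' @param condition A [search_condition()].
#' @param sigma_low,sigma_high Sensory noise SDs (degrees).
#' @param lapse Lapse rate applied to the simulated optimal observer.
#' @param n_sim Number of simulated trials (`>= 1e4`).
#' @param seed Integer seed.
#' @return The simulated d'.
#' @export
optimal_dprime <- function(condition, sigma_low, sigma_high, lapse = 0,
                           n_sim = 1e5, seed = 1L) {
  .check_condition(condition)
  .assert_scalar_number(n_sim, "n_sim", lower = 1e4)
  seeds <- .child_seeds(seed, 3L)
  trials <- simulate_search_trials(condition, n_sim, seed = seeds[1])
  # the benchmark observer runs in the short regime with the given SDs,
  # whatever the condition's regime, so that sigma can be "turned off"
  bench <- condition
  bench$display_regime <- "short"
  bench$fixed_sensory_sd <- NULL
  sl <- max(sigma_low, 0)
  sh <- max(sigma_high, 0)
  if (sl > 0 || sh > 0) {
    trials <- add_observations(trials, sl, sh, seed = seeds[2])
  }
  params <- observer_params("flawless_bayes", bench, sigma_low = sl,
                            sigma_high = sh, lapse = lapse)
  trials <- response_probability(trials, "flawless_bayes", params, bench)
  resp <- withr::with_seed(seeds[3], runif(n_sim) < trials$p_present)
  dprime(resp, trials$target_present)
}

#' Optimality index
#'
#' Ratio of empirical to optimal sensitivity, `I = d'_emp / d'_opt`.
#'
#' @param d_emp Empirical d'.
#' @param d_opt Optimal-observer d' (must be positive).
#' @return A single number.
#' @export
optimality_index <- function(d_emp, d_opt) {
  if (!is.numeric(d_opt) || d_opt <= 0) abort("`d_opt` must be positive.")
  d_emp / d_opt
}

#' Decompose optimality loss into sensory and computational shares
#'
#' With a relative index `I_rel` (optimal observer keeps the subject's
#' sensory noise) and an absolute index `I_abs` (sensory noise turned
#' off), the total loss `1 - I_abs` splits into a sensory part
#' `I_rel - I_abs` and a computational part `1 - I_rel`:
#' `share_sensory = 100 (I_rel - I_abs) / (1 - I_abs)` and
#' `share_computational = 100 (1 - I_rel) / (1 - I_abs)`. The shares
#' always sum to 100.
#'
#' @param index_relative,index_absolute Indices with
#'   `0 < index_absolute <= index_relative <= 1`.
#' @return A tibble with `share_sensory` and `share_computational`
#'   (percent).
#' @examples
#' loss_decomposition(0.80, 0.70)  # 33.3% sensory, 66.7% computational
#' @export
loss_decomposition <- function(index_relative, index_absolute) {
  .assert_scalar_number(index_relative, "index_relative")
  .assert_scalar_number(index_absolute, "index_absolute")
  if (!(index_absolute > 0 && index_absolute <= index_relative &&
          index_relative <= 1)) {
    abort("Need 0 < index_absolute <= index_relative <= 1.")
  }
  if (index_absolute == 1) {
    abort("No loss to decompose when the absolute index is 1.")
  }
  total <- 1 - index_absolute
  tibble(share_sensory = 100 * (index_relative - index_absolute) / total,
         share_computational = 100 * (1 - index_relative) / total)
}

#' Full optimality report for one dataset
#'
#' Computes the empirical d', the relative and absolute optimal
#' benchmarks, both optimality indices, and the sensory/computational
#' loss shares.
#'
#' @param trials Trial tibble with `response` and `target_present`.
#' @param sigma_low,sigma_high Sensory noise SDs used for the relative
#'   benchmark (typically maximum-likelihood estimates of the
#'   best-fitting model).
#' @param lapse Lapse rate for the benchmark observer.
#' @param condition Condition; defaults to the attribute on `trials`.
#' @param n_sim,seed Simulation controls for [optimal_dprime()].
#' @return A one-row tibble with `d_emp`, `d_opt_relative`,
#'   `d_opt_absolute`, `index_relative`, `index_absolute`,
#'   `share_sensory`, `share_computational` (shares are `NA` when an
#'   index falls outside the decomposable range).
#' @export
optimality_report <- function(trials, sigma_low, sigma_high, lapse = 0,
                              condition = NULL, n_sim = 1e5, seed = 1L) {
  condition <- .trials_condition(trials, condition)
  d_emp <- dprime(trials$response, trials$target_present)
  d_rel <- optimal_dprime(condition, sigma_low, sigma_high, lapse,
                          n_sim = n_sim, seed = seed)
  d_abs <- optimal_dprime(condition, 0, 0, lapse, n_sim = n_sim,
                          seed = seed + 1L)
  i_rel <- optimality_index(d_emp, d_rel)
  i_abs <- optimality_index(d_emp, d_abs)
  shares <- if (i_abs > 0 && i_abs <= i_rel && i_rel <= 1 && i_abs < 1) {
    loss_decomposition(i_rel, i_abs)
  } else {
    tibble(share_sensory = NA_real_, share_computational = NA_real_)
  }
  tibble(d_emp = d_emp, d_opt_relative = d_rel, d_opt_absolute = d_abs,
         index_relative = i_rel, index_absolute = i_abs,
         share_sensory = shares$share_sensory,
         share_computational = shares$share_computational)
}
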