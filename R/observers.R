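# Observer models for the four-item detection task.
#
# The Bayesian family pools per-item posterior evidence,
#   d(x) = log( (1/N) sum_i exp( 2 mu_target x_i / (sigma_i^2 + sigma_ext^2) ) ),
# and responds "present" when d > 0. Imperfect variants add late decision
# noise eta ~ N(mu_late, sigma_late) to d; the ignorant variant replaces
# the item-specific sigma_i by a single sigma_single (no reliability
# weighting). Heuristic rules compare a summary statistic of the
# observations with a fitted criterion c. The sampling observer converts
# d into a posterior probability and takes a majority vote over n
# Bernoulli samples.

.MODEL_TABLE <- tibble::tribble(
  ~id, ~name,                     ~label,                                 ~family,     ~direction, ~base,
  1L,  "flawless_bayes",          "Flawless Bayesian",                    "bayesian",   1, NA_character_,
  2L,  "imperfect_bayes",         "Imperfect Bayesian",                   "bayesian",   1, "flawless_bayes",
  3L,  "ignorant_bayes",          "Ignorant Bayesian",                    "bayesian",   1, NA_character_,
  4L,  "imperfect_ignorant_bayes","Imperfect ignorant Bayesian",          "bayesian",   1, "ignorant_bayes",
  5L,  "max",                     "Maximum of observations",              "heuristic",  1, NA_character_,
  6L,  "min_dev",                 "Minimum deviation from target",        "heuristic", -1, NA_character_,
  7L,  "minkowski",               "Minkowski distance from target",       "heuristic", -1, NA_character_,
  8L,  "mean",                    "Mean of observations",                 "heuristic",  1, NA_character_,
  9L,  "variance",                "Variance of observations",             "heuristic",  1, NA_character_,
  10L, "imperfect_max",           "Imperfect maximum-of-observations",    "heuristic",  1, "max",
  11L, "imperfect_min_dev",       "Imperfect minimum-deviation",          "heuristic", -1, "min_dev",
  12L, "imperfect_minkowski",     "Imperfect Minkowski-distance",         "heuristic", -1, "minkowski",
  13L, "imperfect_mean",          "Imperfect mean-of-observations",       "heuristic",  1, "mean",
  14L, "imperfect_variance",      "Imperfect variance-of-observations",   "heuristic",  1, "variance",
  15L, "sampling_bayes",          "Bayesian sampling",                    "sampling",   1, "flawless_bayes"
)

.MODEL_PARAMS <- list(
  flawless_bayes           = c("sigma_low", "sigma_high", "lapse"),
  imperfect_bayes          = c("sigma_low", "sigma_high", "lapse", "mu_late", "sigma_late"),
  ignorant_bayes           = c("sigma_low", "sigma_high", "lapse", "sigma_single"),
  imperfect_ignorant_bayes = c("sigma_low", "sigma_high", "lapse", "sigma_single", "mu_late", "sigma_late"),
  max                      = c("sigma_low", "sigma_high", "lapse", "criterion"),
  min_dev                  = c("sigma_low", "sigma_high", "lapse", "criterion"),
  minkowski                = c("sigma_low", "sigma_high", "lapse", "criterion", "beta"),
  mean                     = c("sigma_low", "sigma_high", "lapse", "criterion"),
  variance                 = c("sigma_low", "sigma_high", "lapse", "criterion"),
  imperfect_max            = c("sigma_low", "sigma_high", "lapse", "criterion", "sigma_late"),
  imperfect_min_dev        = c("sigma_low", "sigma_high", "lapse", "criterion", "sigma_late"),
  imperfect_minkowski      = c("sigma_low", "sigma_high", "lapse", "criterion", "beta", "sigma_late"),
  imperfect_mean           = c("sigma_low", "sigma_high", "lapse", "criterion", "sigma_late"),
  imperfect_variance       = c("sigma_low", "sigma_high", "lapse", "criterion", "sigma_late"),
  sampling_bayes           = c("sigma_low", "sigma_high", "lapse", "n_samples")
)

#' Registry of observer models
#'
#' Lists the 14 numbered observer models (4 Bayesian, 10 heuristic) plus
#' the posterior-sampling observer, with their families, decision
#' directions and free parameters. `direction` is +1 for rules that
#' respond "present" when the decision variable exceeds the threshold and
#' -1 for the deviation-based rules (models 6, 7, 11, 12), where a
#' *small* statistic is evidence for a target. Imperfect heuristics fix
#' `mu_late = 0` (bias is absorbed by the criterion) and only add
#' `sigma_late`.
#'
#' @return A tibble with columns `id`, `name`, `label`, `family`,
#'   `direction`, `base` and a list-column `params` of free-parameter
#'   names (short display regime; in the unlimited regime `sigma_low` and
#'   `sigma_high` are fixed by the condition and not free).
#' @examples
#' observer_models()
#' @export
observer_models <- function() {
  out <- .MODEL_TABLE
  out$params <- unname(.MODEL_PARAMS[out$name])
  out
}

# Resolve a model given by name or Table-row id to its registry row.
.model_info <- function(model) {
  if (is.numeric(model)) {
    row <- .MODEL_TABLE[match(as.integer(model), .MODEL_TABLE$id), ]
  } else {
    row <- .MODEL_TABLE[match(model, .MODEL_TABLE$name), ]
  }
  if (nrow(row) != 1L || is.na(row$name)) {
    abort(sprintf("Unknown observer model: %s", format(model)))
  }
  as.list(row)
}

# Free parameters of a model in a given condition. In the unlimited
# regime the sensory noise SD is fixed by the condition, so sigma_low and
# sigma_high are not free.
.active_params <- function(model, condition, lapse_fixed_zero = FALSE) {
  info <- .model_info(model)
  p <- .MODEL_PARAMS[[info$name]]
  if (condition$display_regime == "unlimited") {
    p <- setdiff(p, c("sigma_low", "sigma_high"))
  }
  if (lapse_fixed_zero) p <- setdiff(p, "lapse")
  p
}

#' Construct and validate an observer parameter set
#'
#' @param model Model name or id (see [observer_models()]).
#' @param condition A [search_condition()]; governs which parameters are
#'   free (sensory noise SDs are fixed in the unlimited regime).
#' @param ... Named parameter values among `sigma_low`, `sigma_high`
#'   (degrees), `lapse` (probability in `[0, 1]`), `mu_late`,
#'   `sigma_late` (decision-variable units), `sigma_single` (degrees),
#'   `criterion` (units of the heuristic statistic), `beta` (> 0) and
#'   `n_samples` (positive integer).
#' @return A named list of class `"observer_params"`.
#' @examples
#' cond <- search_condition("short", mu_target = 5, sigma_external = 3.4)
#' observer_params("flawless_bayes", cond,
#'                 sigma_low = 6, sigma_high = 3, lapse = 0.02)
#' @export
observer_params <- function(model, condition, ...) {
  .check_condition(condition)
  info <- .model_info(model)
  vals <- list(...)
  needed <- .active_params(info$name, condition)
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    abort(sprintf("Model '%s' requires parameter(s): %s",
                  info$name, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(vals), needed)
  if (length(extra)) {
    abort(sprintf("Parameter(s) not used by model '%s' in this regime: %s",
                  info$name, paste(extra, collapse = ", ")))
  }
  for (nm in intersect(names(vals), c("sigma_low", "sigma_high",
                                      "sigma_single", "sigma_late"))) {
    .assert_scalar_number(vals[[nm]], nm, lower = 0)
  }
  if ("lapse" %in% names(vals)) {
    .assert_scalar_number(vals$lapse, "lapse", lower = 0, upper = 1)
  }
  if ("beta" %in% names(vals)) {
    .assert_scalar_number(vals$beta, "beta", lower = 1e-8)
  }
  if ("n_samples" %in% names(vals)) {
    .assert_scalar_number(vals$n_samples, "n_samples", lower = 1)
    vals$n_samples <- as.integer(vals$n_samples)
  }
  structure(vals[needed], class = "observer_params", model = info$name)
}

#' Local posterior evidence for one observation
#'
#' The per-item (local) decision variable of the Bayesian observer:
#' `exp(((x + mu)^2 - (x - mu)^2) / (2 (sigma_i^2 + sigma_ext^2)))`,
#' which simplifies to `exp(2 mu x / (sigma_i^2 + sigma_ext^2))`. Values
#' above 1 are evidence for a target at that location, values below 1
#' evidence for a distractor.
#'
#' @param x Observation(s), degrees.
#' @param sigma_i Sensory noise SD of the item, degrees.
#' @param condition A [search_condition()] supplying `mu_target` and
#'   `sigma_external`.
#' @return Positive evidence value(s), same length as `x`.
#' @export
local_evidence <- function(x, sigma_i, condition) {
  .check_condition(condition)
  denom <- sigma_i^2 + condition$sigma_external^2
  if (any(denom <= 0)) {
    abort(paste("Local evidence is degenerate when sigma_i and",
                "sigma_external are both 0; the noise-free rule applies",
                "only inside the pooled log-mean."))
  }
  exp(((x + condition$mu_target)^2 - (x - condition$mu_target)^2) /
        (2 * denom))
}

# --- internal vectorised decision-variable engines -----------------------

# Assumed per-item noise SD matrix used *inside* the decision rule.
.assumed_sigma <- function(info, rel_high, params, condition) {
  if (condition$display_regime == "unlimited") {
    base <- condition$fixed_sensory_sd
  } else {
    base <- NULL
  }
  if (info$name %in% c("ignorant_bayes", "imperfect_ignorant_bayes")) {
    matrix(params$sigma_single, nrow(rel_high), ncol(rel_high))
  } else if (!is.null(base)) {
    matrix(base, nrow(rel_high), ncol(rel_high))
  } else {
    ifelse(rel_high, params$sigma_high, params$sigma_low)
  }
}

# Noise-free decision variable for an n x 4 observation matrix.
.dv_matrix <- function(info, x, rel_high, params, condition) {
  mu <- condition$mu_target
  switch(info$family,
    bayesian = ,
    sampling = {
      sig <- .assumed_sigma(info, rel_high, params, condition)
      denom <- sig^2 + condition$sigma_external^2
      if (all(denom == 0)) {
        # zero-noise, zero-uncertainty limit: the largest local evidence
        # dominates the pooled log-mean, so only the sign of max(x) matters
        mx <- do.call(pmax, as.data.frame(x))
        return(ifelse(mx > 0, Inf, -Inf))
      }
      if (any(denom <= 0)) {
        abort("Degenerate evidence: assumed sigma_i and sigma_external are both 0.")
      }
      .log_mean_exp_rows(2 * mu * x / denom)
    },
    heuristic = switch(info$name,
      max = , imperfect_max = do.call(pmax, as.data.frame(x)),
      min_dev = , imperfect_min_dev = do.call(pmin, as.data.frame(abs(x - mu))),
      minkowski = , imperfect_minkowski =
        rowSums(abs(x - mu)^params$beta)^(1 / params$beta),
      mean = , imperfect_mean = rowMeans(x),
      # population (1/N) variance, as defined for this rule
      variance = , imperfect_variance = rowMeans((x - rowMeans(x))^2)
    )
  )
}

#' Compute observer decision variables for a set of trials
#'
#' Evaluates the model's (noise-free) global decision variable for every
#' trial and returns it as a new column `d`. For imperfect models a
#' late-noise draw `eta ~ N(mu_late, sigma_late)` is added when
#' `noise_seed` is given; otherwise the noise-free value is returned.
#'
#' @param trials Trial tibble. Observation columns `x1`..`x4` are used
#'   when present, otherwise the stimulus columns `s1`..`s4` (the
#'   noise-free path appropriate for unlimited display with
#'   `fixed_sensory_sd = 0`).
#' @param model Model name or id.
#' @param params An [observer_params()] set (or named list).
#' @param condition Condition; defaults to the attribute on `trials`.
#' @param noise_seed Optional integer seed; when supplied (and the model
#'   has late noise) one `eta` draw per trial is added to `d`.
#' @return `trials` with a numeric column `d` appended.
#' @export
compute_decision_variable <- function(trials, model, params,
                                      condition = NULL, noise_seed = NULL) {
  condition <- .trials_condition(trials, condition)
  info <- .model_info(model)
  x <- if ("x1" %in% names(trials)) .trial_matrix(trials, "x")
       else .trial_matrix(trials, "s")
  rel_high <- .trial_matrix(trials, "rel") == "high"
  d <- .dv_matrix(info, x, rel_high, params, condition)
  if (!is.null(noise_seed) && .has_late_noise(info$name)) {
    mu_late <- params$mu_late %||% 0
    d <- d + withr::with_seed(noise_seed,
                              rnorm(length(d), mu_late, params$sigma_late))
  }
  out <- trials
  out$d <- d
  .copy_trial_attrs(out, trials)
}

.has_late_noise <- function(name) {
  name %in% c("imperfect_bayes", "imperfect_ignorant_bayes",
              "imperfect_max", "imperfect_min_dev", "imperfect_minkowski",
              "imperfect_mean", "imperfect_variance")
}

# Core "target present" probability given noise-free decision variables
# d0, *before* lapse mixing. Ties at the threshold count as "absent".
.p_core <- function(info, d0, params) {
  dir <- info$direction
  if (info$family == "sampling") {
    n <- params$n_samples
    p1 <- plogis(d0)
    p <- 1 - pbinom(floor(n / 2), n, p1)
    if (n %% 2 == 0) p <- p + 0.5 * dbinom(n %/% 2, n, p1)
    return(p)
  }
  threshold <- if (info$family == "bayesian") 0 else params$criterion
  if (.has_late_noise(info$name)) {
    sigma_late <- params$sigma_late
    if (sigma_late == 0) {
      warn("sigma_late = 0: falling back to the deterministic decision rule.")
      return(as.numeric(dir * (d0 - threshold) > 0))
    }
    mu_late <- params$mu_late %||% 0
    pnorm(dir * (d0 + mu_late - threshold) / sigma_late)
  } else {
    as.numeric(dir * (d0 - threshold) > 0)
  }
}

.apply_lapse <- function(p, lapse) lapse / 2 + (1 - lapse) * p

#' Probability of a "target present" response given observations
#'
#' Marginalises the model's response rule over its internal noise (late
#' decision noise, posterior sampling) conditional on the observation
#' vector, and applies lapse mixing last:
#' `p = lapse/2 + (1 - lapse) * p_core`. Flawless rules yield 0/1
#' indicator probabilities; imperfect rules a probit of the distance to
#' threshold; the sampling rule a binomial majority vote (even-`n` ties
#' split as a fair coin).
#'
#' @inheritParams compute_decision_variable
#' @return `trials` with a column `p_present` appended.
#' @export
response_probability <- function(trials, model, params, condition = NULL) {
  condition <- .trials_condition(trials, condition)
  info <- .model_info(model)
  x <- if ("x1" %in% names(trials)) .trial_matrix(trials, "x")
       else .trial_matrix(trials, "s")
  rel_high <- .trial_matrix(trials, "rel") == "high"
  d0 <- .dv_matrix(info, x, rel_high, params, condition)
  p <- .apply_lapse(.p_core(info, d0, params), params$lapse %||% 0)
  out <- trials
  out$p_present <- p
  .copy_trial_attrs(out, trials)
}

#' Simulate observer responses for a set of trials
#'
#' Draws the full response-generation chain per trial: sensory
#' observations (skipped in the noise-free unlimited regime), internal
#' decision noise or posterior sampling, and lapses. The marginal
#' response distribution equals the lapse-mixed probability computed by
#' [response_probability()].
#'
#' @inheritParams compute_decision_variable
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return `trials` with logical `response` (and, in noisy regimes,
#'   observation columns `x1`..`x4`) appended.
#' @export
simulate_responses <- function(trials, model, params, condition = NULL,
                               seed = NULL) {
  condition <- .trials_condition(trials, condition)
  info <- .model_info(model)
  run <- function() {
    work <- trials
    if (!.is_noise_free(condition) && !("x1" %in% names(work))) {
      if (condition$display_regime == "unlimited") {
        sl <- sh <- condition$fixed_sensory_sd
      } else {
        sl <- params$sigma_low
        sh <- params$sigma_high
      }
      work <- add_observations(work, sigma_low = sl, sigma_high = sh)
    }
    work <- response_probability(work, info$name, params, condition)
    work$response <- runif(nrow(work)) < work$p_present
    work$p_present <- NULL
    work
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .copy_trial_attrs(out, trials)
}
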