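# AIC model-comparison tables and model-recovery analysis.

#' Relative-AIC comparison table across datasets
#'
#' Given one fit per (dataset, model) cell, computes each model's AIC
#' difference to the best (lowest-AIC) model of the same dataset, flags
#' cells with `delta_aic >= 10` ("no support" by the usual
#' rules of thumb), and summarises each model's mean ± SE across
#' datasets. Works equally for cross-validated log-likelihoods by
#' passing `-2 * cvll` in the `aic` column.
#'
#' @param fits A data frame with columns `dataset`, `model` and `aic`
#'   (one row per cell), or a list of [fit_observer()] results carrying a
#'   `dataset` attribute... most simply, build the tibble with
#'   [glance()] and add a `dataset` column.
#' @param no_support_at ΔAIC threshold annotated as "no support".
#' @return A tibble of class `"observer_comparison"` with columns
#'   `dataset`, `model`, `aic`, `delta_aic`, `best`, `no_support`;
#'   per-model summary in `attr(, "summary")`.
#' @export
delta_aic_table <- function(fits, no_support_at = 10) {
  fits <- as_tibble(fits)
  req <- c("dataset", "model", "aic")
  if (!all(req %in% names(fits))) {
    abort("`fits` needs columns dataset, model and aic.")
  }
  grid <- tidyr::complete(fits[req], .data$dataset, .data$model)
  if (anyNA(grid$aic)) {
    abort("Incomplete grid: every dataset needs a fit for every model.")
  }
  out <- grid |>
    group_by(.data$dataset) |>
    mutate(delta_aic = .data$aic - min(.data$aic),
           best = .data$delta_aic == 0,
           no_support = .data$delta_aic >= no_support_at) |>
    ungroup()
  summary <- out |>
    group_by(.data$model) |>
    summarise(mean_delta_aic = mean(.data$delta_aic),
              se_delta_aic = sd(.data$delta_aic) / sqrt(dplyr::n()),
              n_best = sum(.data$best), .groups = "drop") |>
    arrange(.data$mean_delta_aic)
  attr(out, "summary") <- summary
  attr(out, "no_support_at") <- no_support_at
  class(out) <- c("observer_comparison", class(out))
  out
}

#' @export
print.observer_comparison <- function(x, ...) {
  cat("<observer_comparison>", length(unique(x$dataset)), "dataset(s),",
      length(unique(x$model)), "model(s)\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Model-recovery analysis
#'
#' For each generator model, draws parameter vectors from a multivariate
#' Gaussian with the supplied mean and covariance (rejection-resampled
#' into the plausible parameter ranges), simulates datasets of the given
#' size, fits every candidate model to every dataset, and tabulates the
#' mean AIC of each candidate relative to the per-row best. A
#' well-behaved model set recovers its generator on the diagonal.
#'
#' @param models Character vector of candidate (fitted) model names; also
#'   the generators unless `generators` is given.
#' @param param_stats Named list (by generator model) of lists with
#'   elements `mean` (named numeric vector over the model's free
#'   parameters) and `cov` (covariance matrix; a diagonal matrix of
#'   squared spreads is fine).
#' @param condition A [search_condition()].
#' @param n_per_model Synthetic datasets per generator.
#' @param n_trials Trials per synthetic dataset.
#' @param generators Generator model names (default `models`).
#' @param priors,mc,n_starts,seed Passed to the fitting stage; `seed`
#'   also controls parameter draws and simulation.
#' @param ... Further arguments passed to [fit_observer()].
#' @return A tibble of class `"recovery_matrix"`: one row per
#'   (generator, fitted) pair with `mean_aic`, `delta_aic` (relative to
#'   the row's best) and `winner` (ties broken toward the lower model
#'   id).
#' @export
model_recovery <- function(models, param_stats, condition,
                           n_per_model = 10, n_trials = 1500,
                           generators = models, priors = NULL,
                           mc = mc_config(), n_starts = 3, seed = 1L, ...) {
  .check_condition(condition)
  seeds <- .child_seeds(seed, length(generators) * n_per_model * 3 + 1L)
  si <- 0L
  rows <- list()
  for (g in generators) {
    stats_g <- param_stats[[g]]
    if (is.null(stats_g)) abort(sprintf("No param_stats for generator '%s'.", g))
    for (r in seq_len(n_per_model)) {
      theta <- .draw_recovery_params(g, stats_g, condition, seeds[si + 1L])
      trials <- simulate_search_trials(condition, n_trials,
                                       seed = seeds[si + 2L])
      trials <- simulate_responses(trials, g, theta, condition,
                                   seed = seeds[si + 3L])
      si <- si + 3L
      for (m in models) {
        # constrained fitting applies to the Bayesian families only;
        # heuristic parameters stay unconstrained
        use_priors <- if (.model_info(m)$family == "heuristic") NULL else priors
        fit <- fit_observer(trials, m, condition, priors = use_priors, mc = mc,
                            n_starts = n_starts, seed = seeds[si], ...)
        rows[[length(rows) + 1L]] <-
          tibble(generator = g, fitted = m, replicate = r, aic = fit$aic)
      }
    }
  }
  cells <- bind_rows(rows) |>
    group_by(.data$generator, .data$fitted) |>
    summarise(mean_aic = mean(.data$aic), .groups = "drop")
  ids <- vapply(cells$fitted, function(m) .model_info(m)$id, integer(1))
  cells$fitted_id <- ids
  cells <- cells |>
    group_by(.data$generator) |>
    mutate(delta_aic = .data$mean_aic - min(.data$mean_aic)) |>
    mutate(winner = seq_along(.data$fitted) ==
             order(.data$delta_aic, .data$fitted_id)[1]) |>
    ungroup()
  attr(cells, "n_per_model") <- n_per_model
  attr(cells, "n_trials") <- n_trials
  attr(cells, "seed") <- seed
  class(cells) <- c("recovery_matrix", class(cells))
  cells
}

# Draw one generator parameter vector, truncated to the plausible boxes.
.draw_recovery_params <- function(model, stats_g, condition, seed) {
  info <- .model_info(model)
  nm <- names(stats_g$mean)
  lo <- vapply(nm, function(p) switch(p,
    sigma_low = , sigma_high = , sigma_single = 0.1, lapse = 0,
    mu_late = -5, sigma_late = 0.01, beta = 0.25, criterion = -Inf,
    n_samples = 1), numeric(1))
  hi <- vapply(nm, function(p) switch(p,
    sigma_low = , sigma_high = , sigma_single = 30, lapse = 0.5,
    mu_late = 5, sigma_late = 10, beta = 10, criterion = Inf,
    n_samples = 501), numeric(1))
  draw <- withr::with_seed(seed, {
    for (i in 1:200) {
      v <- drop(MASS::mvrnorm(1, stats_g$mean, stats_g$cov))
      if (all(v >= lo & v <= hi)) break
    }
    pmin(pmax(v, lo), hi)
  })
  args <- as.list(draw)
  if ("n_samples" %in% nm) args$n_samples <- round(args$n_samples)
  do.call(observer_params, c(list(model = info$name, condition = condition),
                             args[.active_params(info$name, condition)]))
}

#' @export
print.recovery_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(x[c("generator", "fitted", "delta_aic")],
                             names_from = "fitted",
                             values_from = "delta_aic")
  cat("<recovery_matrix> mean ΔAIC (rows = generator)\n")
  print(wide)
  invisible(x)
}
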