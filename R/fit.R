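# Prior-constrained maximum-likelihood fitting and cross-validation.

# Plausible boxes; optimisation runs on an unconstrained scale via a
# logistic map into the box.
.param_box <- function(name, info, trials, condition, priors, constrained_lapse) {
  switch(name,
    sigma_low = , sigma_high = , sigma_single = c(0.1, 30),
    lapse = if (constrained_lapse) c(0, 0.5) else c(0, 1),
    mu_late = c(-5, 5),
    sigma_late = c(0.01, 10),
    beta = c(0.25, 10),
    criterion = {
      # span of the heuristic statistic on the presented stimuli,
      # widened to absorb sensory-noise broadening
      stat <- .dv_matrix(info, .trial_matrix(trials, "s"),
                         .trial_matrix(trials, "rel") == "high",
                         list(beta = 2), condition)
      r <- range(stat)
      span <- max(diff(r), 1)
      c(r[1] - 0.75 * span, r[2] + 0.75 * span)
    }
  )
}

.to_unconstrained <- function(v, box) {
  qlogis(pmin(pmax((v - box[1]) / (box[2] - box[1]), 1e-8), 1 - 1e-8))
}
.from_unconstrained <- function(t, box) box[1] + (box[2] - box[1]) * plogis(t)

.default_start <- function(name, priors, boxes) {
  switch(name,
    sigma_low = priors$sigma_low %||% 5,
    sigma_high = priors$sigma_high %||% 2.5,
    sigma_single = mean(c(priors$sigma_low %||% 5, priors$sigma_high %||% 2.5)),
    lapse = 0.03,
    mu_late = 0,
    sigma_late = 1,
    beta = 2,
    criterion = mean(boxes$criterion)
  )
}

#' Fit an observer model to trial data by penalised maximum likelihood
#'
#' Maximises the Monte-Carlo marginal log-likelihood (plus log prior when
#' a [prior_spec()] is given) with derivative-free local optimisation
#' from multiple start points. Common random numbers make the objective
#' deterministic. The sampling observer's integer `n_samples` is fitted
#' by profiling over a grid.
#'
#' @inheritParams predict_response_prob
#' @param priors A [prior_spec()] or `NULL` for fully unconstrained
#'   fitting. Priors act on `sigma_low`, `sigma_high` and `lapse` only,
#'   so passing them for a heuristic model reproduces the
#'   "constrained heuristic" variant.
#' @param n_starts Number of optimisation restarts (best kept `>= 2`).
#' @param seed Integer seed controlling the restart draws.
#' @param lapse_fixed_zero Fit with the lapse rate fixed at 0.
#' @param n_grid Candidate `n_samples` values for the sampling observer.
#' @param optim_control Control list passed to [stats::optim()].
#' @return An object of class `"observer_fit"` with elements `model`,
#'   `params` (fitted [observer_params()]), `loglik` (prior excluded),
#'   `logpost`, `k_params`, `aic = 2 * k_params - 2 * loglik`,
#'   `converged`, `n_starts` and `seed`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_observer <- function(trials, model, condition = NULL, priors = NULL,
                         mc = mc_config(), n_starts = 10, seed = 1L,
                         lapse_fixed_zero = FALSE,
                         n_grid = c(1L, 3L, 5L, 9L, 17L, 33L, 65L, 129L,
                                    257L, 501L),
                         optim_control = list(maxit = 400, reltol = 1e-7)) {
  condition <- .trials_condition(trials, condition)
  info <- .model_info(model)
  free <- .active_params(info$name, condition, lapse_fixed_zero)
  cont <- setdiff(free, "n_samples")
  boxes <- lapply(stats::setNames(cont, cont), .param_box, info = info,
                  trials = trials, condition = condition, priors = priors,
                  constrained_lapse = !is.null(priors))

  assemble <- function(v_cont, n_samples = NULL) {
    p <- as.list(v_cont)
    if (lapse_fixed_zero) p$lapse <- 0
    if (!is.null(n_samples)) p$n_samples <- n_samples
    p
  }
  objective <- function(t_vec, n_samples = NULL) {
    v <- purrr::map2_dbl(t_vec, boxes[cont], .from_unconstrained)
    names(v) <- cont
    p <- assemble(v, n_samples)
    -(log_likelihood(trials, info$name, p, condition, mc) + .log_prior(p, priors))
  }

  start_seeds <- .child_seeds(seed, max(n_starts, 1L))
  starts <- vector("list", max(n_starts, 1L))
  starts[[1]] <- vapply(cont, function(nm)
    .to_unconstrained(.default_start(nm, priors, boxes), boxes[[nm]]),
    numeric(1))
  if (n_starts > 1) {
    for (i in 2:n_starts) {
      starts[[i]] <- withr::with_seed(start_seeds[i],
        vapply(cont, function(nm) {
          b <- boxes[[nm]]
          .to_unconstrained(runif(1, b[1] + 0.02 * diff(b),
                                  b[2] - 0.02 * diff(b)), b)
        }, numeric(1)))
    }
  }

  run_starts <- function(n_samples = NULL) {
    best <- NULL
    conv <- FALSE
    for (st in starts) {
      if (length(cont) == 0L) {
        res <- list(par = numeric(0), value = objective(numeric(0), n_samples),
                    convergence = 0L)
      } else if (length(cont) == 1L) {
        res <- optim(st, objective, n_samples = n_samples, method = "Brent",
                     lower = -20, upper = 20, control = list())
      } else {
        res <- optim(st, objective, n_samples = n_samples,
                     method = "Nelder-Mead", control = optim_control)
      }
      conv <- conv || res$convergence == 0L
      if (is.null(best) || res$value < best$value) best <- res
      if (length(cont) <= 1L) break  # Brent is global on its bracket
    }
    best$converged <- conv
    best
  }

  if (info$family == "sampling") {
    fits <- lapply(as.integer(n_grid), run_starts)
    best_i <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    best <- fits[[best_i]]
    n_hat <- as.integer(n_grid[best_i])
  } else {
    best <- run_starts()
    n_hat <- NULL
  }

  v_hat <- purrr::map2_dbl(as.numeric(best$par), boxes[cont], .from_unconstrained)
  names(v_hat) <- cont
  params_hat <- assemble(v_hat, n_hat)
  params_hat <- do.call(observer_params,
                        c(list(model = info$name, condition = condition),
                          params_hat[.active_params(info$name, condition)]))
  loglik <- log_likelihood(trials, info$name, params_hat, condition, mc)
  logpost <- loglik + .log_prior(params_hat, priors)
  k <- length(free)
  structure(list(
    model = info$name, id = info$id, label = info$label, family = info$family,
    condition = condition,
    params = params_hat,
    loglik = loglik,
    logpost = logpost,
    k_params = k,
    aic = 2 * k - 2 * loglik,
    converged = isTRUE(best$converged),
    n_starts = as.integer(n_starts),
    seed = as.integer(seed),
    n_trials = nrow(trials),
    priors = priors,
    lapse_fixed_zero = lapse_fixed_zero
  ), class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("<observer_fit> %s (model %s)\n", x$label, x$id))
  cat(sprintf("  n = %d trials | logLik = %.2f | AIC = %.2f | k = %d%s\n",
              x$n_trials, x$loglik, x$aic, x$k_params,
              if (x$converged) "" else " | NOT converged"))
  est <- tidy(x)
  cat("  ", paste(sprintf("%s = %.4g", est$term, est$estimate),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_observer
#' @param x An `observer_fit` object.
#' @method tidy observer_fit
#' @export
tidy.observer_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = as.numeric(unlist(x$params)))
}

#' @rdname fit_observer
#' @method glance observer_fit
#' @export
glance.observer_fit <- function(x, ...) {
  tibble(model = x$model, model_id = x$id, logLik = x$loglik,
         AIC = x$aic, k_params = x$k_params, n_trials = x$n_trials,
         converged = x$converged, n_starts = x$n_starts)
}

#' k-fold cross-validated log-likelihood
#'
#' Randomly partitions the trials into `k` equal folds; for each fold the
#' model is fitted to the complement and the held-out log-likelihood is
#' evaluated at the fitted parameters. The cross-validated log-likelihood
#' (CVLL) is the sum over folds.
#'
#' @inheritParams fit_observer
#' @param k Number of folds (`>= 2`).
#' @param ... Further arguments passed to [fit_observer()]
#'   (e.g. `n_starts`, `lapse_fixed_zero`).
#' @return An object of class `"observer_cv"`: a list with `cvll`, the
#'   per-fold tibble `folds`, `model` and `k`.
#' @export
cross_validate <- function(trials, model, condition = NULL, k = 5,
                           priors = NULL, mc = mc_config(), seed = 1L, ...) {
  condition <- .trials_condition(trials, condition)
  n <- nrow(trials)
  if (k < 2) abort("`k` must be at least 2.")
  if (n < k) abort("Need at least one trial per fold.")
  fold_of <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  fit_seeds <- .child_seeds(seed + 1L, k)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    train <- trials[fold_of != f, , drop = FALSE]
    test <- trials[fold_of == f, , drop = FALSE]
    fit <- fit_observer(train, model, condition, priors = priors, mc = mc,
                        seed = fit_seeds[f], ...)
    tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
           train_loglik = fit$loglik,
           test_loglik = log_likelihood(test, model, fit$params, condition, mc))
  })
  structure(list(cvll = sum(folds$test_loglik), folds = folds,
                 model = .model_info(model)$name, k = k, seed = seed),
            class = "observer_cv")
}

#' @export
print.observer_cv <- function(x, ...) {
  cat(sprintf("<observer_cv> %s | %d-fold | CVLL = %.2f\n",
              x$model, x$k, x$cvll))
  invisible(x)
}

#' Serialise a fit as flat JSON
#'
#' Writes the fitted parameter vector (every registry parameter present,
#' `null` for fields inactive in the model/regime) together with the
#' log-likelihood, AIC and fit metadata.
#'
#' @param fit An `observer_fit`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  all_params <- c("sigma_low", "sigma_high", "lapse", "sigma_single",
                  "mu_late", "sigma_late", "criterion", "beta", "n_samples")
  params <- stats::setNames(lapply(all_params, function(p)
    fit$params[[p]]), all_params)
  out <- list(model = fit$model, model_id = fit$id, family = fit$family,
              params = params, loglik = fit$loglik, logpost = fit$logpost,
              k_params = fit$k_params, aic = fit$aic,
              converged = fit$converged, n_starts = fit$n_starts,
              seed = fit$seed, n_trials = fit$n_trials)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
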