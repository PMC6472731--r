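# Discrimination-task psychometrics and the experiment-design solvers
# that customise mu_target and sigma_external per subject.

# Cumulative-Gaussian response probability with a zero-noise guard.
.p_clockwise <- function(s, sigma) {
  if (sigma == 0) return(ifelse(s > 0, 1, ifelse(s < 0, 0, 0.5)))
  pnorm(s / sigma)
}

.psy_negll <- function(log_sigma, s, resp) {
  p <- .clamp_prob(.p_clockwise(s, exp(log_sigma)))
  -sum(log(ifelse(resp, p, 1 - p)))
}

.fit_one_sigma <- function(s, resp) {
  if (all(resp == (s > 0))) {
    # perfect separation: cap at the lower bound and flag
    return(list(sigma = 0.05, loglik = -.psy_negll(log(0.05), s, resp),
                capped = TRUE))
  }
  opt <- optimize(.psy_negll, c(log(0.05), log(50)), s = s, resp = resp)
  list(sigma = exp(opt$minimum), loglik = -opt$objective, capped = FALSE)
}

#' Simulate an adaptive orientation-discrimination session
#'
#' A single tilted stimulus is shown per trial (low or high reliability,
#' 50/50) and the simulated responder reports clockwise with probability
#' `pnorm(s / sigma_reliability)`. The first 20 orientations are uniform
#' on [-5, +5] degrees; from trial 21 on, a cumulative Gaussian is refit
#' to all data collected so far after every trial and the next
#' orientation is drawn uniformly (random sign) from the tilt range where
#' the running fit predicts 55-95% correct. If the running fit is
#' degenerate (all responses identical) the uniform rule is used and the
#' session is flagged via `attr(, "fallback_trials")`.
#'
#' @param sigma_low,sigma_high True sensory noise SDs of the simulated
#'   responder (degrees).
#' @param n_trials Number of trials (`>= 21`).
#' @param seed Integer seed.
#' @return A tibble with columns `trial`, `orientation` (degrees),
#'   `reliability` and `response_cw`.
#' @export
simulate_discrimination <- function(sigma_low, sigma_high, n_trials = 500,
                                    seed = NULL) {
  .assert_scalar_number(sigma_low, "sigma_low", lower = 0)
  .assert_scalar_number(sigma_high, "sigma_high", lower = 0)
  .assert_scalar_number(n_trials, "n_trials", lower = 21)
  run <- function() {
    n <- as.integer(n_trials)
    rel_high <- runif(n) < 0.5
    s <- numeric(n)
    resp <- logical(n)
    fallback <- integer(0)
    for (t in seq_len(n)) {
      if (t <= 20L) {
        s[t] <- runif(1, -5, 5)
      } else {
        prev_resp <- resp[seq_len(t - 1L)]
        prev_s <- s[seq_len(t - 1L)]
        if (length(unique(prev_resp)) < 2L) {
          fallback <- c(fallback, t)
          s[t] <- runif(1, -5, 5)
        } else {
          sig_hat <- .fit_one_sigma(prev_s, prev_resp)$sigma
          band <- sig_hat * qnorm(c(0.55, 0.95))
          s[t] <- sample(c(-1, 1), 1) * runif(1, band[1], band[2])
        }
      }
      sigma_t <- if (rel_high[t]) sigma_high else sigma_low
      resp[t] <- runif(1) < .p_clockwise(s[t], sigma_t)
    }
    out <- tibble(trial = seq_len(n), orientation = s,
                  reliability = ifelse(rel_high, "high", "low"),
                  response_cw = resp)
    attr(out, "fallback_trials") <- fallback
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fit cumulative-Gaussian psychometric models to discrimination data
#'
#' The proportion of "clockwise" responses is modelled as
#' `pnorm(s / sigma)` (mean fixed at 0, no bias or lapse term). The
#' `"single"` variant fits one noise SD pooled over reliabilities; the
#' `"dual"` variant fits `sigma_tilde_low` and `sigma_tilde_high`
#' separately. AIC allows comparing the two.
#'
#' @param data Tibble with columns `orientation`, `reliability`
#'   (`"low"`/`"high"`) and `response_cw` (logical).
#' @param variant `"dual"` (default) or `"single"`.
#' @return An object of class `"psychometric_fit"` with elements
#'   `sigma_low`, `sigma_high` (equal in the single variant), `loglik`,
#'   `k_params`, `aic` and `capped`. Supports [tidy()] and [glance()].
#' @export
fit_psychometric <- function(data, variant = c("dual", "single")) {
  variant <- match.arg(variant)
  req <- c("orientation", "reliability", "response_cw")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns orientation, reliability, response_cw.")
  }
  if (variant == "single") {
    f <- .fit_one_sigma(data$orientation, data$response_cw)
    out <- list(variant = variant, sigma_low = f$sigma, sigma_high = f$sigma,
                loglik = f$loglik, k_params = 1L, capped = f$capped)
  } else {
    lo <- data$reliability == "low"
    f_lo <- .fit_one_sigma(data$orientation[lo], data$response_cw[lo])
    f_hi <- .fit_one_sigma(data$orientation[!lo], data$response_cw[!lo])
    out <- list(variant = variant, sigma_low = f_lo$sigma,
                sigma_high = f_hi$sigma,
                loglik = f_lo$loglik + f_hi$loglik, k_params = 2L,
                capped = f_lo$capped || f_hi$capped)
  }
  out$aic <- 2 * out$k_params - 2 * out$loglik
  out$n_trials <- nrow(data)
  out$data <- data
  structure(out, class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> %s-sigma | sigma_low = %.3g, sigma_high = %.3g | AIC = %.2f%s\n",
              x$variant, x$sigma_low, x$sigma_high, x$aic,
              if (x$capped) " | capped at bound" else ""))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x A `psychometric_fit` object.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble(term = c("sigma_tilde_low", "sigma_tilde_high"),
         estimate = c(x$sigma_low, x$sigma_high))
}

#' @rdname fit_psychometric
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(variant = x$variant, logLik = x$loglik, AIC = x$aic,
         k_params = x$k_params, n_trials = x$n_trials, capped = x$capped)
}

# Precomputed standardised variates for the accuracy engine; with a fixed
# seed, accuracy becomes a deterministic function of the task parameters
# (common random numbers), which the design solvers root-find on.
.accuracy_engine <- function(n, seed) {
  withr::with_seed(seed, {
    tp <- runif(n) < 0.5
    loc <- sample.int(4L, n, replace = TRUE)
    rel <- .random_reliability(n, 4L)
    list(n = n, tp = tp, loc = loc, rel_high = rel$high,
         z_s = matrix(rnorm(n * 4L), n, 4L),
         z_x = matrix(rnorm(n * 4L), n, 4L))
  })
}

.engine_accuracy <- function(eng, sigma_low, sigma_high, mu_target,
                             sigma_external) {
  s <- -mu_target + sigma_external * eng$z_s
  idx <- cbind(which(eng$tp), eng$loc[eng$tp])
  s[idx] <- mu_target + sigma_external * eng$z_s[idx]
  sig <- ifelse(eng$rel_high, sigma_high, sigma_low)
  x <- s + sig * eng$z_x
  cond <- search_condition("short", mu_target = mu_target,
                           sigma_external = sigma_external)
  d <- .dv_matrix(.model_info("flawless_bayes"), x, eng$rel_high,
                  list(sigma_low = sigma_low, sigma_high = sigma_high), cond)
  mean((d > 0) == eng$tp)
}

#' Accuracy of the optimal observer in a search condition
#'
#' Monte-Carlo proportion correct of the flawless Bayesian observer
#' (lapse-free) under the standard trial distribution: targets on half
#' the trials and a uniform 0-4 high-reliability count. Used by the
#' design solvers that customise `mu_target` (85%-correct rule) and
#' `sigma_external` (5/10/15-point accuracy-drop rule).
#'
#' @param sigma_low,sigma_high Sensory noise SDs (degrees).
#' @param mu_target Target mean tilt (degrees).
#' @param sigma_external External uncertainty SD (degrees).
#' @param n_mc Number of simulated trials (`>= 1e4`).
#' @param seed Integer seed (fixed seed gives a deterministic value).
#' @return Proportion correct in [0, 1].
#' @examples
#' \donttest{optimal_accuracy(7.1, 4.6, 8.0, 0)}
#' @export
optimal_accuracy <- function(sigma_low, sigma_high, mu_target,
                             sigma_external, n_mc = 1e5, seed = 1L) {
  .assert_scalar_number(n_mc, "n_mc", lower = 1e4)
  .assert_scalar_number(sigma_low, "sigma_low", lower = 0)
  .assert_scalar_number(sigma_high, "sigma_high", lower = 0)
  eng <- .accuracy_engine(as.integer(n_mc), seed)
  .engine_accuracy(eng, sigma_low, sigma_high, mu_target, sigma_external)
}

#' Solve for the target tilt giving a criterion optimal accuracy
#'
#' Root-finds `mu_target` such that the optimal observer's accuracy at
#' `sigma_external = 0` equals `target_accuracy` (the 85%-correct
#' calibration rule), using common random numbers so the objective is
#' deterministic.
#'
#' @param sigma_tilde_low,sigma_tilde_high Discrimination-task noise
#'   estimates (degrees).
#' @param target_accuracy Desired proportion correct, in (0.5, 1).
#' @param tol Accuracy tolerance of the root.
#' @param n_mc,seed Monte-Carlo controls.
#' @return `mu_target` in degrees.
#' @export
solve_mu_target <- function(sigma_tilde_low, sigma_tilde_high,
                            target_accuracy = 0.85, tol = 0.002,
                            n_mc = 2e5, seed = 1L) {
  if (target_accuracy <= 0.5 || target_accuracy >= 1) {
    abort("`target_accuracy` must be in (0.5, 1).")
  }
  eng <- .accuracy_engine(as.integer(n_mc), seed)
  f <- function(mu) .engine_accuracy(eng, sigma_tilde_low, sigma_tilde_high,
                                     mu, 0) - target_accuracy
  lo <- 0.1; hi <- 45
  if (f(lo) > 0 || f(hi) < 0) {
    abort("Target accuracy is not bracketed on mu_target in [0.1, 45] degrees.")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-3)
  if (abs(root$f.root) > tol) {
    # polish: accuracy is piecewise constant in mu at finite n_mc
    grid <- seq(root$root - 0.05, root$root + 0.05, length.out = 21)
    vals <- vapply(grid, f, numeric(1))
    root$root <- grid[which.min(abs(vals))]
  }
  root$root
}

#' Solve for the external uncertainty giving a criterion accuracy drop
#'
#' Root-finds `sigma_external` such that the optimal observer's accuracy
#' drops by `drop_level` percentage points relative to the same
#' condition with `sigma_external = 0`.
#'
#' @inheritParams solve_mu_target
#' @param mu_target Target mean tilt (degrees), typically from
#'   [solve_mu_target()].
#' @param drop_level Accuracy drop in percentage points (5, 10 or 15).
#' @return `sigma_external` in degrees.
#' @export
solve_sigma_external <- function(sigma_tilde_low, sigma_tilde_high,
                                 mu_target, drop_level, tol = 0.002,
                                 n_mc = 2e5, seed = 1L) {
  if (!drop_level %in% c(5, 10, 15)) {
    abort("`drop_level` must be 5, 10 or 15 (percentage points).")
  }
  eng <- .accuracy_engine(as.integer(n_mc), seed)
  base <- .engine_accuracy(eng, sigma_tilde_low, sigma_tilde_high,
                           mu_target, 0)
  target <- base - drop_level / 100
  if (target <= 0.5) abort("Requested drop is unattainable (floor at chance).")
  f <- function(se) .engine_accuracy(eng, sigma_tilde_low, sigma_tilde_high,
                                     mu_target, se) - target
  if (f(45) > 0) abort("Requested drop is not reached by sigma_external = 45.")
  uniroot(f, c(1e-6, 45), tol = 1e-3)$root
}

#' Customise task parameters for a table of subjects
#'
#' Data-frame-first wrapper over [solve_mu_target()] and
#' [solve_sigma_external()]: for each row (subject) it returns the
#' calibrated `mu_target` and the `sigma_external` value per requested
#' external-uncertainty level.
#'
#' @param data Tibble with columns `subject`, `sigma_tilde_low`,
#'   `sigma_tilde_high`.
#' @param levels External-uncertainty levels in percentage points.
#' @param target_accuracy,n_mc,seed Passed to the solvers.
#' @return A tibble with one row per subject x level (level 0 =
#'   no external uncertainty) and columns `subject`, `level`,
#'   `sigma_tilde_low`, `sigma_tilde_high`, `mu_target`,
#'   `sigma_external`.
#' @export
calibrate_subjects <- function(data, levels = c(5, 10, 15),
                               target_accuracy = 0.85, n_mc = 2e5,
                               seed = 1L) {
  req <- c("subject", "sigma_tilde_low", "sigma_tilde_high")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns subject, sigma_tilde_low, sigma_tilde_high.")
  }
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    mu <- solve_mu_target(row$sigma_tilde_low, row$sigma_tilde_high,
                          target_accuracy, n_mc = n_mc, seed = seed)
    se <- vapply(levels, function(lv)
      solve_sigma_external(row$sigma_tilde_low, row$sigma_tilde_high, mu,
                           lv, n_mc = n_mc, seed = seed), numeric(1))
    tibble(subject = row$subject, level = c(0, levels),
           sigma_tilde_low = row$sigma_tilde_low,
           sigma_tilde_high = row$sigma_tilde_high,
           mu_target = mu, sigma_external = c(0, se))
  })
}
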