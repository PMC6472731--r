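# Closed-form marginal response probability for the max rule: given s,
# P(present) = lapse/2 + (1 - lapse) * (1 - prod_i Phi((c - s_i)/sigma_i)).
# An independent check on the Monte-Carlo marginalisation path.
closed_form_max_prob <- function(trials, sigma_low, sigma_high, criterion,
                                 lapse) {
  s <- as.matrix(trials[paste0("s", 1:4)])
  sig <- ifelse(as.matrix(trials[paste0("rel", 1:4)]) == "high",
                sigma_high, sigma_low)
  p_below <- pnorm((criterion - s) / sig)
  lapse / 2 + (1 - lapse) * (1 - apply(p_below, 1, prod))
}

test_that("degenerate guessing likelihood is exact", {
  cond <- cond_short()
  trials <- simulate_search_trials(cond, 200, seed = 1)
  trials <- simulate_responses(trials, "flawless_bayes",
                               params_flawless(cond), cond, seed = 2)
  trials$x1 <- trials$x2 <- trials$x3 <- trials$x4 <- NULL
  p_guess <- params_flawless(cond, lapse = 1)
  ll <- log_likelihood(trials, "flawless_bayes", p_guess, cond,
                       mc = mc_config(n_mc = 100, seed = 3))
  expect_equal(ll, 200 * log(0.5))
})

test_that("common random numbers make the likelihood deterministic and additive", {
  cond <- cond_short()
  trials <- simulate_search_trials(cond, 120, seed = 4)
  trials <- simulate_responses(trials, "flawless_bayes",
                               params_flawless(cond), cond, seed = 5)
  trials$x1 <- trials$x2 <- trials$x3 <- trials$x4 <- NULL
  p <- params_flawless(cond, sigma_low = 5, sigma_high = 2.5)
  mc <- mc_config(n_mc = 300, seed = 6)
  ll1 <- log_likelihood(trials, "flawless_bayes", p, cond, mc)
  ll2 <- log_likelihood(trials, "flawless_bayes", p, cond,
                        mc_config(n_mc = 300, seed = 6))
  expect_identical(ll1, ll2)
  # per-trial noise substreams: the likelihood decomposes over any split
  a <- trials[1:50, ]
  b <- trials[51:120, ]
  expect_equal(log_likelihood(a, "flawless_bayes", p, cond, mc) +
                 log_likelihood(b, "flawless_bayes", p, cond, mc),
               ll1, tolerance = 1e-12)
})

test_that("Monte-Carlo marginalisation agrees with a closed-form oracle", {
  cond <- cond_short(mu = 5, sext = 3)
  trials <- simulate_search_trials(cond, 40, seed = 7)
  p <- observer_params("max", cond, sigma_low = 5, sigma_high = 2,
                       lapse = 0.06, criterion = 3)
  mc <- mc_config(n_mc = 4000, seed = 8)
  p_mc <- predict_response_prob(trials, "max", p, cond, mc)
  p_cf <- closed_form_max_prob(trials, 5, 2, 3, 0.06)
  se <- sqrt(pmax(p_cf * (1 - p_cf), 0.01) / 4000)
  expect_true(all(abs(p_mc - p_cf) < 4 * se))
})

test_that("noise-free unlimited regime yields exact two-point probabilities", {
  cond <- cond_unlimited(mu = 5, sext = 3.4, fixed = 0)
  trials <- simulate_search_trials(cond, 300, seed = 9)
  p <- observer_params("flawless_bayes", cond, lapse = 0.1)
  trials <- simulate_responses(trials, "flawless_bayes", p, cond, seed = 10)
  probs <- predict_response_prob(trials, "flawless_bayes", p, cond,
                                 mc_config(n_mc = 100, seed = 11))
  d <- compute_decision_variable(trials, "flawless_bayes", p, cond)$d
  expect_equal(probs, ifelse(d > 0, 0.95, 0.05))
})

test_that("the generating parameters beat perturbed parameters in likelihood", {
  cond <- cond_short(mu = 5, sext = 3.4)
  wins <- 0L
  for (k in 1:5) {
    trials <- simulate_search_trials(cond, 800, seed = 100 + k)
    truth <- params_flawless(cond, sigma_low = 6, sigma_high = 3,
                             lapse = 0.02)
    trials <- simulate_responses(trials, "flawless_bayes", truth, cond,
                                 seed = 200 + k)
    trials$x1 <- trials$x2 <- trials$x3 <- trials$x4 <- NULL
    mc <- mc_config(n_mc = 300, seed = 300 + k)
    ll_true <- log_likelihood(trials, "flawless_bayes", truth, cond, mc)
    worse <- params_flawless(cond, sigma_low = 9, sigma_high = 1.5,
                             lapse = 0.02)
    ll_worse <- log_likelihood(trials, "flawless_bayes", worse, cond, mc)
    wins <- wins + (ll_true >= ll_worse)
  }
  expect_gte(wins, 4L)
})

test_that("fitting recovers structure and satisfies the AIC identity", {
  cond <- cond_unlimited(mu = 5, sext = 3.4, fixed = 0)
  truth <- observer_params("imperfect_bayes", cond, lapse = 0.02,
                           mu_late = -0.3, sigma_late = 1)
  trials <- simulate_search_trials(cond, 800, seed = 20)
  trials <- simulate_responses(trials, "imperfect_bayes", truth, cond,
                               seed = 21)
  mc <- mc_config(n_mc = 100, seed = 22)
  fit <- fit_observer(trials, "imperfect_bayes", cond,
                      priors = prior_spec(6, 3), mc = mc, n_starts = 3,
                      seed = 23)
  expect_s3_class(fit, "observer_fit")
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$k_params - 2 * fit$loglik)
  expect_identical(fit$k_params, 3L)   # lapse, mu_late, sigma_late
  # fitted likelihood at least as good as the generating parameters
  ll_truth <- log_likelihood(trials, "imperfect_bayes", truth, cond, mc)
  expect_gte(fit$loglik + 1e-6, ll_truth - 2)
  expect_named(tidy(fit), c("term", "estimate"))
  expect_true(all(c("AIC", "logLik", "converged") %in% names(glance(fit))))
  # recovered late-noise scale in the right region
  expect_lt(abs(fit$params$sigma_late - 1), 0.5)
})

test_that("fits serialise to flat JSON with nulls for inactive fields", {
  cond <- cond_unlimited(mu = 5, sext = 3.4, fixed = 0)
  truth <- observer_params("flawless_bayes", cond, lapse = 0.1)
  trials <- simulate_search_trials(cond, 200, seed = 60)
  trials <- simulate_responses(trials, "flawless_bayes", truth, cond,
                               seed = 61)
  fit <- fit_observer(trials, "flawless_bayes", cond,
                      mc = mc_config(n_mc = 100, seed = 62), n_starts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$model, "flawless_bayes")
  expect_equal(back$params$lapse, fit$params$lapse, tolerance = 1e-9)
  expect_null(back$params$sigma_late)
  expect_equal(back$aic, fit$aic, tolerance = 1e-9)
})

test_that("the lapse prior shrinks lapse estimates on contaminated data", {
  cond <- cond_unlimited(mu = 5, sext = 3.4, fixed = 0)
  # heavy late noise masquerades as guessing for a lapse-only model
  truth <- observer_params("imperfect_bayes", cond, lapse = 0.05,
                           mu_late = 0, sigma_late = 2.5)
  trials <- simulate_search_trials(cond, 1000, seed = 30)
  trials <- simulate_responses(trials, "imperfect_bayes", truth, cond,
                               seed = 31)
  mc <- mc_config(n_mc = 100, seed = 32)
  fit_con <- fit_observer(trials, "flawless_bayes", cond,
                          priors = prior_spec(6, 3), mc = mc, n_starts = 2,
                          seed = 33)
  fit_unc <- fit_observer(trials, "flawless_bayes", cond, priors = NULL,
                          mc = mc, n_starts = 2, seed = 33)
  expect_gte(fit_unc$params$lapse, fit_con$params$lapse)
  expect_gt(fit_unc$params$lapse, 0.1)
})

test_that("cross-validation sums held-out likelihoods over equal folds", {
  cond <- cond_unlimited(mu = 5, sext = 3.4, fixed = 0)
  truth <- observer_params("flawless_bayes", cond, lapse = 0.1)
  trials <- simulate_search_trials(cond, 300, seed = 40)
  trials <- simulate_responses(trials, "flawless_bayes", truth, cond,
                               seed = 41)
  mc <- mc_config(n_mc = 100, seed = 42)
  cv <- cross_validate(trials, "flawless_bayes", cond, k = 5, mc = mc,
                       seed = 43, n_starts = 1)
  expect_equal(cv$folds$n_test, rep(60L, 5))
  expect_equal(cv$cvll, sum(cv$folds$test_loglik))
  # held-out fit does not beat training likelihood on the full data
  fit_full <- fit_observer(trials, "flawless_bayes", cond, mc = mc,
                           n_starts = 1, seed = 44)
  expect_lte(cv$cvll, fit_full$loglik + 2)
  expect_error(cross_validate(trials, "flawless_bayes", cond, k = 1),
               "at least 2")
})
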