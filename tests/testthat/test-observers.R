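test_that("local evidence matches its closed form and is monotone", {
  cond <- search_condition("short", mu_target = 5, sigma_external = 0)
  expect_equal(local_evidence(0, 5, cond), 1)
  expect_equal(local_evidence(5, 5, cond), exp(2), tolerance = 1e-12)
  cond2 <- cond_short(mu = 3, sext = 2)
  x <- seq(-20, 20, length.out = 81)
  ev <- local_evidence(x, 4, cond2)
  expect_equal(ev, exp(2 * 3 * x / (4^2 + 2^2)), tolerance = 1e-12)
  expect_true(all(diff(ev) > 0))
  cond0 <- search_condition("short", mu_target = 5, sigma_external = 0)
  expect_error(local_evidence(1, 0, cond0), "degenerate")
})

test_that("decision variables reproduce hand-computed examples", {
  cond <- cond_short(mu = 5, sext = 3.4)
  trials <- tibble::tibble(trial = 1L, target_present = FALSE,
                           target_location = NA_integer_)
  xs <- list(zero = c(0, 0, 0, 0), mixed = c(1, -3, 2, 0),
             alt = c(2, -2, 2, -2))
  for (nm in names(xs)) {
    for (j in 1:4) trials[[paste0("s", j)]] <- xs[[nm]][j]
    for (j in 1:4) trials[[paste0("rel", j)]] <- c("low", "high")[j %% 2 + 1]
    for (j in 1:4) trials[[paste0("x", j)]] <- xs[[nm]][j]
    dv <- function(model, params) {
      compute_decision_variable(trials, model, params, cond)$d
    }
    if (nm == "zero") {
      expect_equal(dv("flawless_bayes",
                      params_flawless(cond)), 0)
    }
    if (nm == "mixed") {
      p <- observer_params("max", cond, sigma_low = 6, sigma_high = 3,
                           lapse = 0, criterion = 1)
      expect_equal(dv("max", p), 2)
      p6 <- observer_params("min_dev", cond, sigma_low = 6, sigma_high = 3,
                            lapse = 0, criterion = 1)
      expect_equal(dv("min_dev", p6), 3)        # min |x - 5| over (1,-3,2,0)
      p7 <- observer_params("minkowski", cond, sigma_low = 6, sigma_high = 3,
                            lapse = 0, criterion = 1, beta = 2)
      expect_equal(dv("minkowski", p7),
                   sqrt(4^2 + 8^2 + 3^2 + 5^2))
      p8 <- observer_params("mean", cond, sigma_low = 6, sigma_high = 3,
                            lapse = 0, criterion = 1)
      expect_equal(dv("mean", p8), 0)
    }
    if (nm == "alt") {
      p9 <- observer_params("variance", cond, sigma_low = 6, sigma_high = 3,
                            lapse = 0, criterion = 1)
      expect_equal(dv("variance", p9), 4)       # population 1/N convention
    }
  }
})

test_that("flawless Bayesian equals brute-force marginalisation", {
  set.seed(42)
  for (i in 1:20) {
    mu <- runif(1, 2, 9)
    sext <- runif(1, 0, 6)
    sl <- runif(1, 2, 8)
    sh <- runif(1, 0.5, 4)
    cond <- search_condition("short", mu_target = mu, sigma_external = sext)
    rel <- sample(c("low", "high"), 4, replace = TRUE)
    sig <- ifelse(rel == "high", sh, sl)
    x <- rnorm(4, 0, 6)
    trials <- tibble::tibble(trial = 1L, target_present = TRUE,
                             target_location = 1L)
    for (j in 1:4) trials[[paste0("s", j)]] <- x[j]
    for (j in 1:4) trials[[paste0("rel", j)]] <- rel[j]
    for (j in 1:4) trials[[paste0("x", j)]] <- x[j]
    params <- observer_params("flawless_bayes", cond, sigma_low = sl,
                              sigma_high = sh, lapse = 0)
    d_pkg <- compute_decision_variable(trials, "flawless_bayes", params,
                                       cond)$d
    d_oracle <- oracle_log_posterior_ratio(x, sig, mu, sext)
    expect_equal(d_pkg, d_oracle, tolerance = 1e-6)
  }
})

test_that("decision variables are invariant to location permutation", {
  cond <- cond_short()
  trials <- simulate_search_trials(cond, 200, seed = 5)
  trials <- add_observations(trials, 6, 3, seed = 6)
  perm <- c(3L, 1L, 4L, 2L)
  shuffled <- trials
  for (j in 1:4) {
    shuffled[[paste0("s", j)]] <- trials[[paste0("s", perm[j])]]
    shuffled[[paste0("x", j)]] <- trials[[paste0("x", perm[j])]]
    shuffled[[paste0("rel", j)]] <- trials[[paste0("rel", perm[j])]]
  }
  for (m in c("flawless_bayes", "max", "min_dev", "variance")) {
    p <- switch(m,
      flawless_bayes = params_flawless(cond),
      observer_params(m, cond, sigma_low = 6, sigma_high = 3, lapse = 0,
                      criterion = 1))
    expect_equal(compute_decision_variable(shuffled, m, p, cond)$d,
                 compute_decision_variable(trials, m, p, cond)$d)
  }
})

test_that("ignorant Bayesian reduces to flawless when noise SDs coincide", {
  cond <- cond_short()
  trials <- add_observations(simulate_search_trials(cond, 300, seed = 8),
                             4, 4, seed = 9)
  p1 <- observer_params("flawless_bayes", cond, sigma_low = 4,
                        sigma_high = 4, lapse = 0.05)
  p3 <- observer_params("ignorant_bayes", cond, sigma_low = 4,
                        sigma_high = 4, lapse = 0.05, sigma_single = 4)
  expect_equal(compute_decision_variable(trials, "ignorant_bayes", p3, cond)$d,
               compute_decision_variable(trials, "flawless_bayes", p1, cond)$d)
  expect_equal(response_probability(trials, "ignorant_bayes", p3, cond)$p_present,
               response_probability(trials, "flawless_bayes", p1, cond)$p_present)
})

test_that("response probabilities follow the stated decision rules", {
  cond <- cond_short()
  mk <- function(x, rel = rep("low", 4)) {
    t <- tibble::tibble(trial = 1L, target_present = TRUE,
                        target_location = 1L)
    for (j in 1:4) t[[paste0("s", j)]] <- x[j]
    for (j in 1:4) t[[paste0("rel", j)]] <- rel[j]
    for (j in 1:4) t[[paste0("x", j)]] <- x[j]
    t
  }
  # imperfect Bayesian at d0 = 0, unbiased noise: probability one half
  t0 <- mk(c(0, 0, 0, 0))
  p2 <- observer_params("imperfect_bayes", cond, sigma_low = 6,
                        sigma_high = 3, lapse = 0, mu_late = 0,
                        sigma_late = 1)
  expect_equal(response_probability(t0, "imperfect_bayes", p2, cond)$p_present,
               0.5)
  # flawless with d0 > 0 and a 10% lapse: 0.95
  tpos <- mk(c(6, 5, 5, 5))
  p1 <- params_flawless(cond, lapse = 0.1)
  expect_equal(response_probability(tpos, "flawless_bayes", p1, cond)$p_present,
               0.95)
  # deviation-based rules respond "present" below criterion
  p6 <- observer_params("min_dev", cond, sigma_low = 6, sigma_high = 3,
                        lapse = 0, criterion = 2)
  expect_equal(response_probability(mk(c(5, -4, -4, -4)), "min_dev", p6,
                                    cond)$p_present, 1)
  expect_equal(response_probability(mk(c(0, -4, -4, -4)), "min_dev", p6,
                                    cond)$p_present, 0)
  # ties at the threshold count as "absent"
  p5 <- observer_params("max", cond, sigma_low = 6, sigma_high = 3,
                        lapse = 0, criterion = 5)
  expect_equal(response_probability(mk(c(5, 0, 0, 0)), "max", p5,
                                    cond)$p_present, 0)
})

test_that("sampling observer matches the exact binomial vote", {
  cond <- cond_short()
  # choose x so that p1 = 0.8, i.e. d0 = logit(0.8)
  d_target <- qlogis(0.8)
  # invert the pooled evidence for equal x at all locations:
  # d = 2 mu x / (sig^2 + sext^2) when all items identical
  p_base <- observer_params("sampling_bayes", cond, sigma_low = 4,
                            sigma_high = 4, lapse = 0, n_samples = 3)
  x_eq <- d_target * (4^2 + 3.4^2) / (2 * 5)
  t <- tibble::tibble(trial = 1L, target_present = TRUE, target_location = 1L)
  for (j in 1:4) t[[paste0("s", j)]] <- x_eq
  for (j in 1:4) t[[paste0("rel", j)]] <- "low"
  for (j in 1:4) t[[paste0("x", j)]] <- x_eq
  p <- response_probability(t, "sampling_bayes", p_base, cond)$p_present
  expect_equal(p, 1 - pbinom(1, 3, 0.8), tolerance = 1e-12)  # 0.896
  # odd n at p1 = 0.5 stays at one half; even-n ties split fairly
  t0 <- t
  for (j in 1:4) t0[[paste0("x", j)]] <- 0
  for (n in c(1L, 7L, 101L)) {
    pn <- observer_params("sampling_bayes", cond, sigma_low = 4,
                          sigma_high = 4, lapse = 0, n_samples = n)
    expect_equal(response_probability(t0, "sampling_bayes", pn,
                                      cond)$p_present, 0.5)
  }
  p2n <- observer_params("sampling_bayes", cond, sigma_low = 4,
                         sigma_high = 4, lapse = 0, n_samples = 2L)
  expect_equal(response_probability(t0, "sampling_bayes", p2n,
                                    cond)$p_present, 0.5)
})

test_that("limit equivalences hold across model families", {
  cond <- cond_short()
  trials <- add_observations(simulate_search_trials(cond, 400, seed = 30),
                             6, 3, seed = 31)
  p_fb <- params_flawless(cond, lapse = 0.02)
  p_fb_probs <- response_probability(trials, "flawless_bayes", p_fb,
                                     cond)$p_present

  # sampling observer converges to exact inference for many samples
  p_samp <- observer_params("sampling_bayes", cond, sigma_low = 6,
                            sigma_high = 3, lapse = 0.02, n_samples = 1001L)
  samp_probs <- response_probability(trials, "sampling_bayes", p_samp,
                                     cond)$p_present
  d0 <- compute_decision_variable(trials, "flawless_bayes", p_fb, cond)$d
  away <- abs(d0) > 0.15
  expect_gt(mean(away), 0.5)
  expect_lt(max(abs(samp_probs[away] - p_fb_probs[away])), 0.02)

  # imperfect models collapse onto their flawless counterparts
  p_ib <- observer_params("imperfect_bayes", cond, sigma_low = 6,
                          sigma_high = 3, lapse = 0.02, mu_late = 0,
                          sigma_late = 1e-9)
  ib_probs <- response_probability(trials, "imperfect_bayes", p_ib,
                                   cond)$p_present
  expect_equal(ib_probs[d0 != 0], p_fb_probs[d0 != 0], tolerance = 1e-9)
})

test_that("simulated responses are consistent with stated probabilities", {
  cond <- cond_short()
  trials <- simulate_search_trials(cond, 1e4, seed = 40)
  # full lapse: pure guessing regardless of the stimuli
  p_guess <- params_flawless(cond, lapse = 1)
  resp <- simulate_responses(trials, "flawless_bayes", p_guess, cond,
                             seed = 41)
  expect_lt(abs(mean(resp$response) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_lt(abs(mean(resp$response[resp$target_present]) -
                  mean(resp$response[!resp$target_present])),
            4 * sqrt(0.5 / 1e4))

  # marginal response rate of one fixed display matches the Monte-Carlo
  # marginalised probability
  one <- trials[rep(1L, 2e4), ]
  one$trial <- seq_len(nrow(one))
  p_ib <- observer_params("imperfect_bayes", cond, sigma_low = 6,
                          sigma_high = 3, lapse = 0.04, mu_late = -0.3,
                          sigma_late = 0.8)
  sim <- simulate_responses(one, "imperfect_bayes", p_ib, cond, seed = 42)
  p_marg <- predict_response_prob(trials[1L, ], "imperfect_bayes", p_ib,
                                  cond, mc = mc_config(n_mc = 2e4, seed = 43))
  se <- sqrt(p_marg * (1 - p_marg) / nrow(one)) + 1 / sqrt(2e4)
  expect_lt(abs(mean(sim$response) - p_marg), 4 * se)
})

test_that("zero-noise zero-uncertainty limit uses the sign of the maximum", {
  cond <- search_condition("unlimited", mu_target = 8, sigma_external = 0,
                           fixed_sensory_sd = 0)
  t <- tibble::tibble(trial = 1:2, target_present = c(TRUE, FALSE),
                      target_location = c(1L, NA))
  s <- rbind(c(8, -8, -8, -8), c(-8, -8, -8, -8))
  for (j in 1:4) t[[paste0("s", j)]] <- s[, j]
  for (j in 1:4) t[[paste0("rel", j)]] <- "high"
  p <- observer_params("flawless_bayes", cond, lapse = 0)
  probs <- response_probability(t, "flawless_bayes", p, cond)$p_present
  expect_equal(probs, c(1, 0))
})
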