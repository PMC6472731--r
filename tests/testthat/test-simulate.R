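test_that("generative model matches its stated distributions", {
  cond <- cond_short(mu = 5, sext = 3)
  n <- 1e5
  trials <- simulate_search_trials(cond, n, seed = 11)

  # target prevalence: Bernoulli(0.5), 3-SE band
  p_hat <- mean(trials$target_present)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))

  # high-reliability count uniform on 0..4
  chi <- suppressWarnings(
    stats::chisq.test(tabulate(trials$n_high + 1L, 5L),
                      p = rep(0.2, 5)))
  expect_gt(chi$p.value, 0.01)

  # exactly one target location when present, none otherwise
  expect_true(all(!is.na(trials$target_location[trials$target_present])))
  expect_true(all(is.na(trials$target_location[!trials$target_present])))
  expect_true(all(trials$target_location %in% c(1:4, NA)))

  # stimulus distribution means: +mu at target cells, -mu elsewhere
  s <- as.matrix(trials[paste0("s", 1:4)])
  tp <- which(trials$target_present)
  t_idx <- cbind(tp, trials$target_location[tp])
  targets <- s[t_idx]
  s[t_idx] <- NA
  distractors <- s[!is.na(s)]
  expect_lt(abs(mean(targets) - 5), 3 * 3 / sqrt(length(targets)))
  expect_lt(abs(mean(distractors) + 5), 3 * 3 / sqrt(length(distractors)))
  expect_lt(abs(sd(targets) - 3), 0.1)
})

test_that("zero external uncertainty degenerates to fixed orientations", {
  cond <- search_condition("short", mu_target = 8, sigma_external = 0)
  trials <- simulate_search_trials(cond, 2000, seed = 2)
  s <- as.matrix(trials[paste0("s", 1:4)])
  tp <- which(trials$target_present)
  t_idx <- cbind(tp, trials$target_location[tp])
  expect_true(all(s[t_idx] == 8))
  s[t_idx] <- NA
  expect_true(all(s[!is.na(s)] == -8))
})

test_that("trial simulation is reproducible and sized as requested", {
  cond <- cond_short()
  a <- simulate_search_trials(cond, 1500, seed = 7)
  b <- simulate_search_trials(cond, 1500, seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a), 1500L)
  expect_identical(nrow(simulate_search_trials(cond, 500, seed = 1)), 500L)
  expect_error(simulate_search_trials(cond, 0), "n_trials")
})

test_that("sensory observations have reliability-dependent noise", {
  cond <- cond_short(mu = 5, sext = 2)
  trials <- simulate_search_trials(cond, 1e5, seed = 3)

  clean <- add_observations(trials, 0, 0, seed = 4)
  expect_equal(as.matrix(clean[paste0("x", 1:4)]),
               as.matrix(clean[paste0("s", 1:4)]), ignore_attr = TRUE)

  noisy <- add_observations(trials, sigma_low = 4, sigma_high = 1.5, seed = 5)
  resid <- as.matrix(noisy[paste0("x", 1:4)]) -
    as.matrix(noisy[paste0("s", 1:4)])
  rel <- as.matrix(noisy[paste0("rel", 1:4)])
  sd_low <- sd(resid[rel == "low"])
  sd_high <- sd(resid[rel == "high"])
  n_low <- sum(rel == "low")
  expect_lt(abs(mean(resid[rel == "low"])), 3 * 4 / sqrt(n_low))
  expect_lt(abs(sd_low - 4), 0.02 * 4)
  expect_lt(abs(sd_high - 1.5), 0.02 * 1.5)
  expect_error(add_observations(trials, -1, 2), "sigma_low")
})

test_that("pop-out filter retains exactly the 0/2/4 high-count trials", {
  cond <- cond_short()
  trials <- simulate_search_trials(cond, 1e5, seed = 13)
  kept <- filter_popout(trials)
  expect_true(all(kept$n_high %in% c(0L, 2L, 4L)))
  expect_false(any(trials$trial[trials$n_high %in% c(1L, 3L)] %in% kept$trial))
  # retention probability is 3/5 under the uniform high-count rule
  frac <- nrow(kept) / nrow(trials)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(trials)))
})

test_that("trial sets round-trip through CSV plus JSON sidecar", {
  cond <- cond_short(mu = 6, sext = 2.1)
  trials <- simulate_search_trials(cond, 50, seed = 21)
  params <- params_flawless(cond)
  trials <- simulate_responses(trials, "flawless_bayes", params, cond,
                               seed = 22)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_set(trials, path)
  back <- read_trial_set(path)
  expect_equal(back$response, trials$response)
  expect_equal(back$s3, trials$s3)
  expect_equal(attr(back, "condition")$mu_target, 6)
  expect_equal(attr(back, "condition")$sigma_external, 2.1)
})
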