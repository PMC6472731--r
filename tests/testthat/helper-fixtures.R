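# Shared fixtures: small conditions and parameter sets used across tests.

cond_short <- function(mu = 5, sext = 3.4) {
  search_condition("short", mu_target = mu, sigma_external = sext)
}

cond_unlimited <- function(mu = 5, sext = 3.4, fixed = 0) {
  search_condition("unlimited", mu_target = mu, sigma_external = sext,
                   fixed_sensory_sd = fixed)
}

params_flawless <- function(cond, sigma_low = 6, sigma_high = 3,
                            lapse = 0.02) {
  if (cond$display_regime == "unlimited") {
    observer_params("flawless_bayes", cond, lapse = lapse)
  } else {
    observer_params("flawless_bayes", cond, sigma_low = sigma_low,
                    sigma_high = sigma_high, lapse = lapse)
  }
}

# Simple non-adaptive discrimination data: uniform orientations, exact
# cumulative-Gaussian responder. Used where the adaptive placement is not
# under test.
quick_discrimination <- function(sigma_low, sigma_high, n = 500, seed = 1) {
  withr::with_seed(seed, {
    rel <- ifelse(runif(n) < 0.5, "high", "low")
    s <- runif(n, -10, 10)
    sig <- ifelse(rel == "high", sigma_high, sigma_low)
    resp <- runif(n) < pnorm(ifelse(sig > 0, s / sig, sign(s) * Inf))
    tibble::tibble(orientation = s, reliability = rel, response_cw = resp)
  })
}
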