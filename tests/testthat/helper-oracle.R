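# The quadrature oracle: log posterior ratio of target presence computed
# by direct numerical marginalisation of the generative model, one item
# likelihood at a time. Independent of the package's pooled-evidence
# shortcut.
oracle_log_posterior_ratio <- function(x, sigma, mu, sext) {
  lik_item <- function(xi, si, target_mean) {
    if (sext == 0) return(dnorm(xi, target_mean, si))
    # the integrand is a product of two Gaussians: bracket the narrow
    # posterior spike explicitly or adaptive quadrature can miss it
    tau2 <- 1 / (1 / si^2 + 1 / sext^2)
    centre <- tau2 * (xi / si^2 + target_mean / sext^2)
    w <- sqrt(tau2)
    stats::integrate(function(s) dnorm(xi, s, si) * dnorm(s, target_mean, sext),
                     lower = centre - 12 * w, upper = centre + 12 * w,
                     rel.tol = 1e-10)$value
  }
  N <- length(x)
  lik_d <- vapply(seq_len(N), function(i) lik_item(x[i], sigma[i], -mu),
                  numeric(1))
  lik_t <- vapply(seq_len(N), function(i) lik_item(x[i], sigma[i], mu),
                  numeric(1))
  # p(x | T=1) averages over the uniform target location
  p_present <- mean(vapply(seq_len(N), function(L)
    lik_t[L] * prod(lik_d[-L]), numeric(1)))
  p_absent <- prod(lik_d)
  log(p_present) - log(p_absent)
}
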