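# Internal numerical helpers shared across modules.

# Row-wise log-mean-exp over the columns of a matrix; guards against
# overflow for large |x| (decision variables can reach exp(1000) scales
# when sigma_external is small).
.log_mean_exp_rows <- function(a) {
  m <- pmax(a[, 1], a[, 2])
  if (ncol(a) > 2) for (j in 3:ncol(a)) m <- pmax(m, a[, j])
  s <- exp(a[, 1] - m)
  for (j in 2:ncol(a)) s <- s + exp(a[, j] - m)
  m + log(s / ncol(a))
}

# Clamp probabilities away from 0/1 for stable log-likelihoods.
.clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Derive a stream of child seeds from one user-facing seed, keeping all
# values valid 32-bit integers.
.child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Random high-reliability label matrix: per row, a count drawn uniformly
# on 0..n_items is assigned to uniformly random positions. Vectorised via
# per-row ranks of iid uniforms (exchangeability makes this equivalent to
# an explicit permutation).
.random_reliability <- function(n, n_items) {
  counts <- sample.int(n_items + 1L, n, replace = TRUE) - 1L
  u <- matrix(runif(n * n_items), n, n_items)
  rk <- matrix(1L, n, n_items)
  for (j in seq_len(n_items)) {
    for (k in seq_len(n_items)) {
      if (k != j) rk[, j] <- rk[, j] + (u[, k] < u[, j])
    }
  }
  list(high = rk <= counts, count = counts)
}

.copy_trial_attrs <- function(out, trials) {
  attr(out, "condition") <- attr(trials, "condition")
  attr(out, "seed") <- attr(trials, "seed")
  out
}
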