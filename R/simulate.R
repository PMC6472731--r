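#' Simulate trials of the visual-search detection task
#'
#' Draws trials from the task's generative model. A target is present on
#' half of the trials (Bernoulli 0.5). On target-present trials one
#' uniformly chosen location holds an orientation drawn from
#' Normal(`mu_target`, `sigma_external`) and the remaining items are
#' distractors drawn from Normal(`-mu_target`, `sigma_external`); on
#' target-absent trials all items are distractors. The number of
#' high-reliability items is uniform on {0, ..., 4} and the labels are
#' randomly placed across locations. `sigma_external = 0` degenerates to
#' fixed orientations at exactly `±mu_target`.
#'
#' @param condition A [search_condition()].
#' @param n_trials Number of trials (`>= 1`).
#' @param seed Optional integer seed; when given the result is
#'   reproducible and the seed is stored as an attribute.
#'
#' @return A tibble with one row per trial and columns `trial`,
#'   `target_present` (logical), `target_location` (integer 1-4 or `NA`),
#'   `s1`..`s4` (orientations, degrees), `rel1`..`rel4` (`"low"`/`"high"`)
#'   and `n_high`. The condition and seed are stored in attributes
#'   `"condition"` and `"seed"`.
#' @examples
#' cond <- search_condition("short", mu_target = 8, sigma_external = 0)
#' trials <- simulate_search_trials(cond, 10, seed = 1)
#' @export
simulate_search_trials <- function(condition, n_trials, seed = NULL) {
  .check_condition(condition)
  .assert_scalar_number(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  draw <- function() .draw_search_trials(condition, n_trials)
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "condition") <- condition
  attr(out, "seed") <- seed
  out
}

.draw_search_trials <- function(condition, n) {
  N <- condition$n_items
  mu <- condition$mu_target
  sext <- condition$sigma_external
  target_present <- runif(n) < 0.5
  target_location <- ifelse(target_present,
                            sample.int(N, n, replace = TRUE), NA_integer_)
  s <- matrix(rnorm(n * N, mean = -mu, sd = sext), n, N)
  idx <- which(target_present)
  if (length(idx)) {
    s[cbind(idx, target_location[idx])] <- rnorm(length(idx), mu, sext)
  }
  rel <- .random_reliability(n, N)
  out <- tibble(
    trial = seq_len(n),
    target_present = target_present,
    target_location = as.integer(target_location)
  )
  for (j in seq_len(N)) out[[paste0("s", j)]] <- s[, j]
  for (j in seq_len(N)) {
    out[[paste0("rel", j)]] <- ifelse(rel$high[, j], "high", "low")
  }
  out$n_high <- as.integer(rel$count)
  out
}

#' Add noisy sensory observations to simulated trials
#'
#' Corrupts each stimulus orientation with zero-mean Gaussian noise whose
#' SD depends on the item's reliability label: `x_i = s_i + N(0, sigma_i)`
#' with `sigma_i = sigma_high` for high-reliability items and `sigma_low`
#' otherwise. With both SDs zero the observations equal the stimuli.
#'
#' @param trials A trial tibble from [simulate_search_trials()].
#' @param sigma_low,sigma_high Sensory noise SDs (degrees, `>= 0`) for
#'   low- and high-reliability items.
#' @param seed Optional integer seed for the noise draws.
#' @return The input tibble with observation columns `x1`..`x4` added.
#' @export
add_observations <- function(trials, sigma_low, sigma_high, seed = NULL) {
  .assert_scalar_number(sigma_low, "sigma_low", lower = 0)
  .assert_scalar_number(sigma_high, "sigma_high", lower = 0)
  s <- .trial_matrix(trials, "s")
  rel_high <- .trial_matrix(trials, "rel") == "high"
  sig <- ifelse(rel_high, sigma_high, sigma_low)
  draw <- function() matrix(rnorm(length(s)), nrow(s), ncol(s))
  z <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  x <- s + sig * z
  out <- trials
  for (j in seq_len(ncol(x))) out[[paste0("x", j)]] <- x[, j]
  .copy_trial_attrs(out, trials)
}

#' Remove pop-out trials from a trial set
#'
#' Pop-out trials are displays in which exactly one item's reliability
#' differs from the other three, i.e. displays with 1 or 3
#' high-reliability items. Filtering retains only trials with 0, 2 or 4
#' high-reliability items, which is 60% of trials in expectation under the
#' uniform high-count rule.
#'
#' @param trials A trial tibble with `rel1`..`rel4` columns.
#' @return The retained trials (attributes preserved).
#' @export
filter_popout <- function(trials) {
  n_high <- rowSums(.trial_matrix(trials, "rel") == "high")
  out <- trials[n_high %in% c(0, 2, 4), , drop = FALSE]
  .copy_trial_attrs(out, trials)
}

# Extract the n x 4 matrix of a per-item column family ("s", "x", "rel").
.trial_matrix <- function(trials, prefix) {
  cols <- paste0(prefix, 1:4)
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    abort(sprintf("trial data lack columns: %s", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(trials[cols])
  dimnames(m) <- NULL
  m
}

.trials_condition <- function(trials, condition = NULL) {
  condition <- condition %||% attr(trials, "condition")
  if (is.null(condition)) {
    abort("No `condition` supplied and none attached to the trial data.")
  }
  .check_condition(condition)
  condition
}

#' Write / read a trial set as CSV with a JSON sidecar
#'
#' The CSV holds one row per trial (`trial_index`, `target_present` as
#' 0/1, `target_location` 1-4 or `NA`, `s1..s4`, `rel1..rel4`,
#' `response` as 0/1 or `NA`, and observation columns when present); the
#' sidecar `<path>.json` records the condition parameters and seed so the
#' set can be regenerated.
#'
#' @param trials A trial tibble.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param condition Condition; defaults to the attribute on `trials`.
#' @return `write_trial_set()` returns `path` invisibly;
#'   `read_trial_set()` returns the trial tibble with the condition
#'   re-attached.
#' @export
write_trial_set <- function(trials, path, condition = NULL) {
  condition <- .trials_condition(trials, condition)
  out <- trials
  out$target_present <- as.integer(out$target_present)
  if ("response" %in% names(out)) out$response <- as.integer(out$response)
  names(out)[names(out) == "trial"] <- "trial_index"
  readr::write_csv(out, path, na = "NA")
  meta <- list(display_regime = condition$display_regime,
               mu_target = condition$mu_target,
               sigma_external = condition$sigma_external,
               n_items = condition$n_items,
               fixed_sensory_sd = condition$fixed_sensory_sd,
               seed = attr(trials, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  names(raw)[names(raw) == "trial_index"] <- "trial"
  raw$target_present <- as.logical(raw$target_present)
  raw$target_location <- as.integer(raw$target_location)
  if ("response" %in% names(raw)) raw$response <- as.logical(raw$response)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(raw, "condition") <- search_condition(
      display_regime = meta$display_regime,
      mu_target = meta$mu_target,
      sigma_external = meta$sigma_external,
      fixed_sensory_sd = meta$fixed_sensory_sd
    )
    attr(raw, "seed") <- meta$seed
  }
  raw
}
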