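# End-to-end pipeline on synthetic subjects: discrimination session ->
# psychometric calibration -> task-parameter solvers -> search datasets
# -> model fits -> comparison and optimality tables.

#' Run the full synthetic-subject analysis pipeline
#'
#' For each synthetic subject: (1) simulate an adaptive discrimination
#' session from the subject's true sensory noise SDs and fit the
#' dual-sigma psychometric model; (2) calibrate `mu_target` (85%-correct
#' rule) and, if the subject's condition has external uncertainty,
#' `sigma_external` (accuracy-drop rule); (3) generate a visual-search
#' dataset and simulate the subject's responses from a
#' generating observer model; (4) fit the candidate models with
#' prior-constrained likelihoods; (5) build the relative-AIC comparison
#' and the optimality report (using the best-fitting model's parameter
#' estimates for the benchmark observer).
#'
#' All randomness derives from `seed`; rerunning with the same
#' configuration reproduces the outputs. When `out_dir` is given, the
#' tables are also written as CSV.
#'
#' @param subjects Tibble with columns `subject`, `sigma_low`,
#'   `sigma_high` (true SDs, degrees), `level` (external-uncertainty
#'   level in points: 0, 5, 10 or 15) and optionally `lapse`, `mu_late`,
#'   `sigma_late` for the generating observer.
#' @param generator Observer model generating the synthetic responses.
#' @param models Candidate models to fit.
#' @param n_search_trials,n_discrimination_trials Trials per task.
#' @param mc,n_starts Fitting controls.
#' @param constrained Use discrimination-anchored priors when fitting
#'   (the constrained regime); `FALSE` fits unconstrained.
#' @param drop_popout Apply [filter_popout()] before fitting.
#' @param lapse_fixed_zero Fit with lapse rates fixed at 0.
#' @param n_sim_index Trials for the optimality-index benchmark
#'   simulations.
#' @param calib_n_mc Trials for the calibration solvers.
#' @param seed Master seed.
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A list of class `"search_pipeline"`: `calibration`,
#'   `psychometric`, `fits` (per-model summary tibble), `estimates`
#'   (long tibble: subject, model, parameter, estimate),
#'   `comparison` (an `observer_comparison`), `optimality` (per-subject
#'   tibble), and `config`.
#' @export
run_search_pipeline <- function(subjects,
                                generator = "imperfect_bayes",
                                models = c("flawless_bayes",
                                           "imperfect_bayes", "max"),
                                n_search_trials = 300,
                                n_discrimination_trials = 200,
                                mc = mc_config(n_mc = 200),
                                n_starts = 2,
                                constrained = TRUE,
                                drop_popout = FALSE,
                                lapse_fixed_zero = FALSE,
                                n_sim_index = 2e4,
                                calib_n_mc = 2e4,
                                seed = 1L,
                                out_dir = NULL) {
  req <- c("subject", "sigma_low", "sigma_high", "level")
  if (!all(req %in% names(subjects))) {
    abort("`subjects` needs columns subject, sigma_low, sigma_high, level.")
  }
  seeds <- .child_seeds(seed, nrow(subjects) * 6L)
  psychometric <- list(); calibration <- list(); fits <- list()
  optimality <- list(); estimates <- list()
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    s6 <- seeds[(i - 1L) * 6L + 1:6]
    disc <- simulate_discrimination(sub$sigma_low, sub$sigma_high,
                                    n_discrimination_trials, seed = s6[1])
    psy <- fit_psychometric(disc, "dual")
    psychometric[[i]] <- glance(psy) |> mutate(subject = sub$subject,
                                               sigma_tilde_low = psy$sigma_low,
                                               sigma_tilde_high = psy$sigma_high)
    mu <- solve_mu_target(psy$sigma_low, psy$sigma_high, n_mc = calib_n_mc,
                          seed = s6[2])
    sext <- if (sub$level > 0) {
      solve_sigma_external(psy$sigma_low, psy$sigma_high, mu, sub$level,
                           n_mc = calib_n_mc, seed = s6[2])
    } else 0
    calibration[[i]] <- tibble(subject = sub$subject, level = sub$level,
                               sigma_tilde_low = psy$sigma_low,
                               sigma_tilde_high = psy$sigma_high,
                               mu_target = mu, sigma_external = sext)
    cond <- search_condition("short", mu_target = mu, sigma_external = sext)
    gen_params <- do.call(observer_params, c(
      list(model = generator, condition = cond),
      .generator_defaults(generator, sub, cond)))
    trials <- simulate_search_trials(cond, n_search_trials, seed = s6[3])
    trials <- simulate_responses(trials, generator, gen_params, cond,
                                 seed = s6[4])
    trials$x1 <- trials$x2 <- trials$x3 <- trials$x4 <- NULL
    if (drop_popout) trials <- filter_popout(trials)
    priors <- if (constrained) prior_spec(psy$sigma_low, psy$sigma_high)
              else NULL
    sub_fits <- purrr::map(models, function(m) {
      use_priors <- if (.model_info(m)$family == "heuristic" && !constrained)
        NULL else priors
      fit_observer(trials, m, cond, priors = use_priors, mc = mc,
                   n_starts = n_starts, seed = s6[5],
                   lapse_fixed_zero = lapse_fixed_zero)
    })
    fits[[i]] <- purrr::map_dfr(sub_fits, glance) |>
      mutate(subject = sub$subject, dataset = sub$subject)
    estimates[[i]] <- purrr::map_dfr(sub_fits, function(f)
      tidy(f) |> mutate(model = f$model, model_id = f$id)) |>
      mutate(subject = sub$subject, level = sub$level)
    best <- sub_fits[[which.min(vapply(sub_fits, `[[`, numeric(1), "aic"))]]
    bp <- best$params
    optimality[[i]] <- optimality_report(
      trials,
      sigma_low = bp$sigma_low %||% sub$sigma_low,
      sigma_high = bp$sigma_high %||% sub$sigma_high,
      lapse = bp$lapse %||% 0,
      condition = cond, n_sim = n_sim_index, seed = s6[6]) |>
      mutate(subject = sub$subject, best_model = best$model)
  }
  fits_tbl <- bind_rows(fits)
  result <- list(
    psychometric = bind_rows(psychometric),
    calibration = bind_rows(calibration),
    fits = fits_tbl,
    estimates = bind_rows(estimates),
    comparison = delta_aic_table(
      fits_tbl |> dplyr::transmute(dataset = .data$dataset,
                                   model = .data$model, aic = .data$AIC)),
    optimality = bind_rows(optimality),
    config = list(generator = generator, models = models,
                  n_search_trials = n_search_trials,
                  n_discrimination_trials = n_discrimination_trials,
                  constrained = constrained, drop_popout = drop_popout,
                  lapse_fixed_zero = lapse_fixed_zero, seed = seed)
  )
  class(result) <- "search_pipeline"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result$psychometric, file.path(out_dir, "psychometric.csv"))
    readr::write_csv(result$calibration, file.path(out_dir, "calibration.csv"))
    readr::write_csv(result$fits, file.path(out_dir, "fits.csv"))
    readr::write_csv(result$estimates, file.path(out_dir, "estimates.csv"))
    readr::write_csv(as_tibble(result$comparison),
                     file.path(out_dir, "comparison.csv"))
    readr::write_csv(result$optimality, file.path(out_dir, "optimality.csv"))
    jsonlite::write_json(result$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

.generator_defaults <- function(generator, sub, cond) {
  col <- function(nm, default) {
    if (nm %in% names(sub)) sub[[nm]] else default
  }
  base <- list(sigma_low = sub$sigma_low, sigma_high = sub$sigma_high,
               lapse = col("lapse", 0.03))
  info <- .model_info(generator)
  if (.has_late_noise(info$name)) {
    if (info$family == "bayesian") base$mu_late <- col("mu_late", -0.2)
    base$sigma_late <- col("sigma_late", 1)
  }
  if (info$name %in% c("ignorant_bayes", "imperfect_ignorant_bayes")) {
    base$sigma_single <- mean(c(sub$sigma_low, sub$sigma_high))
  }
  if (info$family == "heuristic") base$criterion <- cond$mu_target / 2
  if (info$family == "sampling") base$n_samples <- 17L
  base[.active_params(info$name, cond)]
}

#' @export
print.search_pipeline <- function(x, ...) {
  cat("<search_pipeline>", nrow(x$calibration), "subject(s),",
      length(x$config$models), "candidate model(s)\n")
  cat("Comparison summary:\n")
  print(attr(x$comparison, "summary"))
  invisible(x)
}
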