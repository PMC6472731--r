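#' Define a visual-search experimental condition
#'
#' A condition bundles the stimulus parameters of one experimental cell of
#' the four-item detection task: the target mean tilt `mu_target` (degrees
#' clockwise from vertical; distractors are tilted `-mu_target`), the
#' external uncertainty `sigma_external` (SD, in degrees, of the Gaussian
#' target and distractor orientation distributions), and the display
#' regime. In the `"short"` regime sensory noise levels are free model
#' parameters (one SD per reliability class); in the `"unlimited"` regime
#' the per-item sensory noise SD is fixed to a prespecified value
#' (`fixed_sensory_sd`, typically 0 or 0.875 degrees).
#'
#' @param display_regime `"short"` or `"unlimited"`.
#' @param mu_target Target mean tilt in degrees, must be positive.
#' @param sigma_external SD of the target/distractor orientation
#'   distributions in degrees, `>= 0`. A value of 0 degenerates to fixed
#'   orientations at exactly `±mu_target`.
#' @param n_items Number of display items; the task uses 4.
#' @param fixed_sensory_sd Fixed per-item sensory noise SD in degrees.
#'   Required for (and only for) the unlimited regime.
#'
#' @return An object of class `"search_condition"` (a named list).
#' @examples
#' search_condition("short", mu_target = 8, sigma_external = 0)
#' search_condition("unlimited", mu_target = 5, sigma_external = 3.4,
#'                  fixed_sensory_sd = 0)
#' @export
search_condition <- function(display_regime = c("short", "unlimited"),
                             mu_target,
                             sigma_external,
                             n_items = 4L,
                             fixed_sensory_sd = NULL) {
  display_regime <- match.arg(display_regime)
  .assert_scalar_number(mu_target, "mu_target", lower = 1e-12)
  .assert_scalar_number(sigma_external, "sigma_external", lower = 0)
  if (n_items != 4L) abort("`n_items` is fixed at 4 for this task.")
  if (display_regime == "unlimited") {
    if (is.null(fixed_sensory_sd)) {
      abort("`fixed_sensory_sd` is required in the unlimited display regime.")
    }
    .assert_scalar_number(fixed_sensory_sd, "fixed_sensory_sd", lower = 0)
  } else if (!is.null(fixed_sensory_sd)) {
    abort("`fixed_sensory_sd` only applies to the unlimited display regime.")
  }
  structure(
    list(display_regime = display_regime,
         mu_target = as.numeric(mu_target),
         sigma_external = as.numeric(sigma_external),
         n_items = 4L,
         fixed_sensory_sd = if (is.null(fixed_sensory_sd)) NULL
                            else as.numeric(fixed_sensory_sd)),
    class = "search_condition"
  )
}

#' @export
print.search_condition <- function(x, ...) {
  cat("<search_condition>\n")
  cat("  display regime :", x$display_regime, "\n")
  cat("  mu_target      :", x$mu_target, "deg\n")
  cat("  sigma_external :", x$sigma_external, "deg\n")
  if (!is.null(x$fixed_sensory_sd)) {
    cat("  fixed sensory SD:", x$fixed_sensory_sd, "deg\n")
  }
  invisible(x)
}

.is_condition <- function(x) inherits(x, "search_condition")

.check_condition <- function(condition) {
  if (!.is_condition(condition)) {
    abort("`condition` must be created with `search_condition()`.")
  }
  invisible(condition)
}

# Condition for which the closed-form (noise-free) decision-variable path
# applies: unlimited display with the sensory noise fixed at exactly 0.
.is_noise_free <- function(condition) {
  condition$display_regime == "unlimited" && condition$fixed_sensory_sd == 0
}
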