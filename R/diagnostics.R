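#' Weight summaries for positivity verification
#'
#' Mean and maximum of the positive (observed-cell) stabilized ratios,
#' overall and per exposure level, with the implied probabilities
#' `1 / max` and `1 / mean`. A maximum weight of 50.1 implies every unit
#' had an estimated exposure probability of at least 1/50.1, about 2%.
#'
#' @param weights A `nuisance_weights` object from [stabilize_and_trim()].
#' @param trimmed Summarize the trimmed ratios (default, what is
#'   reported) or the raw stabilized ratios.
#'
#' @return A `weight_diagnostics` tibble with rows per level plus
#'   `Overall`: `n`, `mean_weight`, `max_weight`,
#'   `implied_min_probability`, `implied_mean_probability`.
#' @export
weight_summary <- function(weights, trimmed = TRUE) {
  stopifnot(inherits(weights, "nuisance_weights"))
  m <- if (trimmed) weights$ratios_trimmed else weights$ratios
  if (all(m == 0)) abort("No positive ratios to summarize.")
  lev <- colnames(m)
  one <- function(v, label) {
    v <- v[v > 0]
    tibble::tibble(level = label, n = length(v),
                   mean_weight = mean(v), max_weight = max(v),
                   implied_min_probability = 1 / max(v),
                   implied_mean_probability = 1 / mean(v))
  }
  per <- purrr::map_dfr(seq_along(lev), function(k) one(m[, k], lev[k]))
  out <- dplyr::bind_rows(per, one(as.vector(m), "Overall"))
  attr(out, "trimmed") <- trimmed
  attr(out, "trim_percentile") <- weights$trim_percentile
  class(out) <- c("weight_diagnostics", class(out))
  out
}

#' Minimum exposure probability implied by a maximum weight
#'
#' The reciprocal of the maximum inverse-probability weight bounds the
#' smallest estimated exposure probability from below: a maximum weight
#' of 50.1 implies a minimum probability of 1/50.1, about 2%; applying
#' the same reading to a mean weight of 4.8 gives a mean probability of
#' about 21%.
#'
#' @param max_weight Positive weight (or vector of weights).
#' @return `1 / max_weight`. Stabilized ratios can fall below 1, in which
#'   case the reciprocal exceeds 1 and a warning is raised.
#' @export
#'
#' @examples
#' implied_min_probability(50.1)  # ~0.02
#' implied_min_probability(4.8)   # ~0.21
implied_min_probability <- function(max_weight) {
  if (any(max_weight <= 0)) abort("Weights must be positive.")
  if (any(max_weight < 1)) {
    warn("Weight below 1 (stabilized ratios can be < 1); reciprocal exceeds 1.")
  }
  1 / max_weight
}

#' Positivity verification narrative
#'
#' Flags exposure levels whose implied minimum probability
#' (1 / maximum weight) falls below `threshold`, and renders a
#' human-readable verdict on the positivity assumption.
#'
#' @param diagnostics A `weight_diagnostics` tibble from
#'   [weight_summary()].
#' @param threshold Minimum acceptable implied probability (default 0.01).
#'
#' @return A `positivity_report` list: `pass`, `flagged_levels`,
#'   `threshold`, `message`.
#' @export
positivity_report <- function(diagnostics, threshold = 0.01) {
  stopifnot(inherits(diagnostics, "weight_diagnostics"))
  per <- diagnostics[diagnostics$level != "Overall", ]
  flagged <- per$level[per$implied_min_probability < threshold]
  pass <- length(flagged) == 0
  overall <- diagnostics[diagnostics$level == "Overall", ]
  msg <- if (pass) {
    sprintf(paste0(
      "Positivity verified: maximum weight %.1f, so each country had an ",
      "estimated probability of exposure of at least %.1f%% (threshold %g); ",
      "mean weight %.1f (mean probability at least %.0f%%)."),
      overall$max_weight, min(100, 100 / overall$max_weight), threshold,
      overall$mean_weight, min(100, 100 / overall$mean_weight))
  } else {
    sprintf(paste0(
      "Possible positivity violation at level(s) %s: implied minimum ",
      "probability below %g (maximum weight %.1f overall)."),
      paste(flagged, collapse = ", "), threshold, overall$max_weight)
  }
  structure(list(pass = pass, flagged_levels = flagged,
                 threshold = threshold, message = msg),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat(if (x$pass) "PASS: " else "FAIL: ", x$message, "\n", sep = "")
  invisible(x)
}
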