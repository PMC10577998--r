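#' Published 2018 globalization-level assignments
#'
#' The 87 countries of the analytic sample with their assigned
#' globalization level, as printed in the source table of the study the
#' package's defaults mirror (Low [41,64], Mid-Low (64,72],
#' Mid-High (72,82.5], High (82.5,91]). Level counts are 23/23/19/22.
#'
#' @return A tibble with `country` and `level` (ordered factor).
#' @export
#'
#' @examples
#' table(kof2018_level_assignments()$level)
kof2018_level_assignments <- function() {
  path <- system.file("extdata", "kof2018_levels.csv", package = "ecotmle",
                      mustWork = TRUE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d$level <- factor(d$level, levels = .level_labels, ordered = TRUE)
  tibble::as_tibble(d)
}
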