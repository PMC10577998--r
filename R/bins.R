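#' Exposure level bins
#'
#' A set of four contiguous intervals over a continuous exposure index,
#' defining an ordinal exposure with four levels. The first interval is
#' closed on both ends, the remaining three are left-open, right-closed:
#' `[e1, e2], (e2, e3], (e3, e4], (e4, e5]`. Values outside `[e1, e5]`
#' are not representable and raise an error at discretization time.
#'
#' @param edges Numeric vector of five strictly increasing cut points.
#' @param labels Character vector of four level names, lowest first.
#'
#' @return An object of class `level_bins`.
#' @export
#'
#' @examples
#' level_bins(c(41, 64, 72, 82.5, 91))
level_bins <- function(edges, labels = .level_labels) {
  if (!is.numeric(edges) || length(edges) != 5L || anyNA(edges)) {
    abort("`edges` must be five non-missing numeric cut points.")
  }
  if (any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing.")
  }
  if (length(labels) != 4L || anyDuplicated(labels)) {
    abort("`labels` must be four distinct level names.")
  }
  structure(list(edges = as.numeric(edges), labels = as.character(labels)),
            class = "level_bins")
}

#' @export
print.level_bins <- function(x, ...) {
  e <- x$edges
  iv <- c(
    sprintf("[%g, %g]", e[1], e[2]),
    sprintf("(%g, %g]", e[2], e[3]),
    sprintf("(%g, %g]", e[3], e[4]),
    sprintf("(%g, %g]", e[4], e[5])
  )
  cat("<level_bins>\n")
  cat(paste0("  ", format(x$labels), "  ", iv, collapse = "\n"), "\n")
  invisible(x)
}

#' Globalization-index bins used for the 2018 KOF index
#'
#' The published discretization of the 1-100 KOF Globalization Index into
#' four ordinal levels: Low `[41, 64]`, Mid-Low `(64, 72]`, Mid-High
#' `(72, 82.5]`, High `(82.5, 91]`.
#'
#' @return A [level_bins()] object.
#' @export
kof_level_bins <- function() {
  level_bins(c(41, 64, 72, 82.5, 91))
}

#' Discretize a continuous exposure index into ordinal levels
#'
#' Assigns each value to one of the four bins, honouring the boundary
#' convention of [level_bins()]: a value exactly on an interior edge maps
#' to the lower-labelled interval.
#'
#' @param index_values Numeric vector of exposure-index values.
#' @param bins A [level_bins()] object; defaults to [kof_level_bins()].
#' @param ids Optional identifiers (e.g. country names) used in error
#'   messages for out-of-range values.
#'
#' @return An ordered factor with the bin labels.
#' @export
#'
#' @examples
#' discretize_exposure(c(41, 64, 64.01, 82.5, 91))
discretize_exposure <- function(index_values, bins = kof_level_bins(),
                                ids = NULL) {
  stopifnot(inherits(bins, "level_bins"))
  if (!is.numeric(index_values)) abort("`index_values` must be numeric.")
  if (anyNA(index_values)) abort("`index_values` contains missing values.")
  out_of_range <- index_values < bins$edges[1] | index_values > bins$edges[5]
  if (any(out_of_range)) {
    who <- if (is.null(ids)) paste("position", which(out_of_range)) else
      ids[out_of_range]
    abort(sprintf(
      "Exposure index outside [%g, %g] for: %s",
      bins$edges[1], bins$edges[5], paste(who, collapse = ", ")
    ))
  }
  lev <- cut(index_values, breaks = bins$edges, labels = bins$labels,
             include.lowest = TRUE, right = TRUE)
  factor(lev, levels = bins$labels, ordered = TRUE)
}

#' Add an exposure-level column to a panel
#'
#' @param data A data frame with the exposure-index column.
#' @param bins A [level_bins()] object.
#' @param index_col Name of the exposure-index column.
#' @param id_col Name of the identifier column used in error messages.
#'
#' @return `data` as a tibble with an `exposure_level` ordered factor.
#' @export
assign_exposure_levels <- function(data, bins = kof_level_bins(),
                                   index_col = "exposure_index",
                                   id_col = "country") {
  data <- tibble::as_tibble(data)
  if (!index_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", index_col))
  }
  ids <- if (id_col %in% names(data)) data[[id_col]] else NULL
  data$exposure_level <- discretize_exposure(data[[index_col]], bins, ids)
  data
}
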