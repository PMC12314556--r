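#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, with no normal-consistency
#' scaling (the 1.4826 constant is deliberately omitted: every robust rule in
#' this package -- the 2-MAD well/time-point cuts and the modified robust
#' Z-prime -- is defined on the raw MAD scale).
#'
#' @param x Numeric vector.
#' @param na.rm Drop missing values first.
#' @return The raw MAD, a single non-negative number.
#' @examples
#' mad_raw(c(0, 1, 2)) # 1
#' @export
mad_raw <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

#' Metadata / feature column conventions
#'
#' Well-profile tables follow the standard profiling-export convention:
#' metadata columns share the reserved prefix `"Metadata_"`; every other
#' column is a feature. `feature_columns()` and `metadata_columns()` return
#' the respective column names.
#'
#' @param x A well-profile data.frame.
#' @return Character vector of column names.
#' @export
feature_columns <- function(x) {
  nm <- names(x)
  nm[!nm %in% metadata_columns(x)] # keeps duplicates so they can be reported
}

#' @rdname feature_columns
#' @export
metadata_columns <- function(x) {
  grep("^Metadata_", names(x), value = TRUE)
}

#' @keywords internal
feature_values <- function(x) {
  as.matrix(x[, feature_columns(x), drop = FALSE])
}

# unique well id used for distance matrices and masks
well_id <- function(x) {
  paste(x$Metadata_plate, x$Metadata_well, sep = ":")
}

# metadata required of every well-profile table
required_profile_metadata <- c(
  "Metadata_plate", "Metadata_well", "Metadata_genotype",
  "Metadata_treatment", "Metadata_family", "Metadata_concentration",
  "Metadata_replicate"
)

check_profile_metadata <- function(x) {
  missing <- setdiff(required_profile_metadata, names(x))
  if (length(missing) > 0) {
    stop("well-profile table is missing metadata column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

group_key <- function(x, cols) {
  interaction(x[cols], drop = TRUE, lex.order = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
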