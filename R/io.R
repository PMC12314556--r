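#' Read a per-cell morphometry table
#'
#' Reads the CSV export of a segmentation pipeline (one row per cell).
#' Required columns: `plate`, `well`, `genotype`, `treatment`,
#' `concentration`, `replicate`, `nuclear_intensity`,
#' `cytoplasmic_intensity`, `contact_percent`. Rows with missing nuclear or
#' cytoplasmic values are flagged (column `flagged`), never silently dropped.
#'
#' @param path CSV file path.
#' @return Typed data.frame with a logical `flagged` column.
#' @export
read_cell_table <- function(path) {
  x <- read_checked(path, c("plate", "well", "genotype", "treatment",
                            "concentration", "replicate",
                            "nuclear_intensity", "cytoplasmic_intensity",
                            "contact_percent"))
  x$flagged <- is.na(x$nuclear_intensity) | is.na(x$cytoplasmic_intensity)
  x
}

#' @rdname read_cell_table
#' @param cells Table to write.
#' @export
write_cell_table <- function(cells, path) {
  cells$flagged <- NULL
  write_csv_plain(cells, path)
}

#' Read / write a well-profile feature matrix
#'
#' Wells x features CSV with metadata columns carrying the reserved
#' `Metadata_` prefix (plate, well, genotype, treatment, family,
#' concentration, replicate); every other column is a numeric feature.
#' Duplicate feature names are a schema error.
#'
#' @param path CSV file path.
#' @return Well-profile data.frame.
#' @export
read_feature_matrix <- function(path) {
  x <- read_checked(path, required_profile_metadata)
  feats <- feature_columns(x)
  dup <- feats[duplicated(feats)]
  if (length(dup) > 0) {
    stop("duplicate feature name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_feature_matrix
#' @param profiles Table to write.
#' @export
write_feature_matrix <- function(profiles, path) {
  write_csv_plain(profiles, path)
}

#' Read / write growth-track tables
#'
#' Long-format CSV: `well`, `genotype`, `treatment`, `concentration`,
#' `replicate`, `time_h`, `area` (percent confluency for 2D assays).
#'
#' @param path CSV file path.
#' @return Track data.frame.
#' @export
read_growth_tracks <- function(path) {
  read_checked(path, c("well", "genotype", "treatment", "concentration",
                       "replicate", "time_h", "area"))
}

#' @rdname read_growth_tracks
#' @param tracks Table to write.
#' @export
write_growth_tracks <- function(tracks, path) {
  write_csv_plain(tracks, path)
}

# locale-independent CSV reading with schema checks
read_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) stop("empty input (header only): ", path, call. = FALSE)
  x
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible. Used by the command-line interface; CLI flags
#' override config keys.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
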