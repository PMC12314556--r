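#' Write / read a synthetic ground-truth file
#'
#' Ground truth emitted by the generators is stored as a flat key=value text
#' file: nested names are joined with `.`, vector values are
#' comma-separated, e.g. `affected_features.TEADi_sel = Ftr_003,Ftr_011`.
#' The seed is recorded under `seed`.
#'
#' @param truth Truth list from a generator.
#' @param path Output path.
#' @param seed Seed to record alongside the labels.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path, seed = NA) {
  flatten <- function(x, prefix = character(0)) {
    if (is.data.frame(x)) {
      # row-oriented: each row becomes "a,b,..." under an indexed key
      vals <- apply(x, 1, function(r) paste(r, collapse = ","))
      key <- paste(prefix, collapse = ".")
      return(stats::setNames(list(paste(vals, collapse = ";")), key))
    }
    if (is.list(x)) {
      out <- list()
      for (nm in names(x)) {
        out <- c(out, flatten(x[[nm]], c(prefix, nm)))
      }
      return(out)
    }
    key <- paste(prefix, collapse = ".")
    if (!is.null(names(x))) {
      stats::setNames(list(paste(names(x), x, sep = ":", collapse = ",")), key)
    } else {
      stats::setNames(list(paste(x, collapse = ",")), key)
    }
  }
  flat <- flatten(truth)
  lines <- c(paste("seed =", seed),
             vapply(names(flat), function(k) paste(k, "=", flat[[k]]),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}
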