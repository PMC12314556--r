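#' Curate a well-profile feature matrix
#'
#' Drops near-constant features (variance below `variance_threshold`) and then
#' greedily trims highly correlated features until no retained pair has
#' absolute Pearson correlation above `correlation_threshold`. The greedy
#' order is deterministic: at each step the feature with the highest mean
#' absolute correlation to all remaining features (among features involved in
#' a violating pair) is dropped, ties broken towards the later column, and
#' correlations are recomputed after each drop.
#'
#' @param profiles Well-profile data.frame (metadata columns prefixed
#'   `Metadata_`, remaining columns numeric features).
#' @param variance_threshold Features with variance strictly below this are
#'   dropped (default `1e-8`, i.e. near-constant).
#' @param correlation_threshold Maximum tolerated absolute pairwise
#'   correlation among retained features, in (0, 1] (default 0.9).
#' @return A list with `profiles` (the curated table) and `report`, a list
#'   with `n_input_features`, `n_retained`, `dropped_low_variance`
#'   (character vector) and `dropped_correlated` (data.frame with columns
#'   `feature`, `partner` -- the retained feature that triggered each drop).
#' @export
curate_features <- function(profiles, variance_threshold = 1e-8,
                            correlation_threshold = 0.9) {
  check_profile_metadata(profiles)
  if (nrow(profiles) < 2) stop("curation requires at least 2 wells", call. = FALSE)
  if (variance_threshold < 0) stop("variance_threshold must be >= 0", call. = FALSE)
  if (correlation_threshold <= 0 || correlation_threshold > 1) {
    stop("correlation_threshold must be in (0, 1]", call. = FALSE)
  }

  feats <- feature_columns(profiles)
  x <- feature_values(profiles)
  vars <- apply(x, 2, stats::var)
  low_var <- feats[vars < variance_threshold]
  keep <- setdiff(feats, low_var)

  dropped_cor <- data.frame(feature = character(0), partner = character(0),
                            stringsAsFactors = FALSE)
  if (length(keep) >= 2) {
    repeat {
      a <- abs(stats::cor(x[, keep, drop = FALSE]))
      a[is.na(a)] <- 0
      diag(a) <- 0
      if (max(a) <= correlation_threshold) break
      violating <- keep[apply(a > correlation_threshold, 2, any)]
      mean_abs <- colMeans(a)[violating]
      # highest mean |r| goes first; ties drop the later column
      worst <- violating[max(which(mean_abs == max(mean_abs)))]
      partner <- keep[which.max(a[, worst])]
      dropped_cor <- rbind(dropped_cor,
                           data.frame(feature = worst, partner = partner,
                                      stringsAsFactors = FALSE))
      keep <- setdiff(keep, worst)
      if (length(keep) < 2) break
    }
  }

  if (length(keep) == 0) {
    stop("curation dropped all features (", length(low_var), " low-variance, ",
         nrow(dropped_cor), " correlated)", call. = FALSE)
  }

  report <- list(
    n_input_features = length(feats),
    n_retained = length(keep),
    dropped_low_variance = low_var,
    dropped_correlated = dropped_cor
  )
  out <- profiles[, c(metadata_columns(profiles), keep), drop = FALSE]
  list(profiles = out, report = report)
}

#' Normalize retained features to vehicle-control wells
#'
#' Robust-standardizes every feature against the vehicle-control wells of the
#' designated control genotype: `(value - control_median) / control_MAD`,
#' with the raw (unscaled) MAD. When the table spans several plates the
#' statistics are computed per plate from that plate's own control wells,
#' containing plate effects. Features whose control MAD is zero on any plate
#' are dropped and reported.
#'
#' @param profiles Well-profile data.frame.
#' @param control_treatment Vehicle treatment label (default `"DMSO"`).
#' @param control_genotype Genotype whose vehicle wells define the baseline
#'   (default `"WT"`).
#' @param per_plate Compute control statistics within each plate
#'   (default TRUE; single-plate tables are unaffected).
#' @return A list with `profiles` (normalized table) and `dropped_zero_mad`
#'   (character vector of dropped features).
#' @export
normalize_to_control <- function(profiles, control_treatment = "DMSO",
                                 control_genotype = "WT", per_plate = TRUE) {
  check_profile_metadata(profiles)
  is_control <- profiles$Metadata_treatment == control_treatment &
    profiles$Metadata_genotype == control_genotype
  if (sum(is_control) < 2) {
    stop("need at least 2 control wells (treatment=", control_treatment,
         ", genotype=", control_genotype, ")", call. = FALSE)
  }

  feats <- feature_columns(profiles)
  plates <- if (per_plate) unique(profiles$Metadata_plate) else "all"
  out <- profiles
  zero_mad <- character(0)

  for (pl in plates) {
    in_plate <- if (per_plate) profiles$Metadata_plate == pl else rep(TRUE, nrow(profiles))
    ctrl <- in_plate & is_control
    if (sum(ctrl) < 2) {
      stop("plate ", pl, " has fewer than 2 control wells", call. = FALSE)
    }
    for (f in feats) {
      v <- profiles[[f]][ctrl]
      m <- stats::median(v)
      s <- mad_raw(v)
      if (s == 0) {
        zero_mad <- union(zero_mad, f)
      } else {
        out[[f]][in_plate] <- (profiles[[f]][in_plate] - m) / s
      }
    }
  }

  if (length(zero_mad) > 0) {
    out <- out[, setdiff(names(out), zero_mad), drop = FALSE]
  }
  list(profiles = out, dropped_zero_mad = zero_mad)
}

#' Remove outlier wells by the 2-MAD rule
#'
#' Within each group of replicate wells, flags values lying strictly more
#' than `n_mad` raw MADs from the group median. Statistics are computed once
#' on the full group (no iterative re-trimming), and the inequality is
#' strict, so an all-equal group (MAD 0, deviations 0) keeps every well.
#' Groups with fewer than 3 wells are passed through untouched with a
#' warning.
#'
#' @param values Numeric vector of per-well summaries.
#' @param groups Grouping factor/vector of the same length (biological
#'   replicate groups); a single group if NULL.
#' @param n_mad Cut in raw-MAD units (default 2).
#' @return Logical vector: TRUE for retained wells.
#' @export
remove_outlier_wells <- function(values, groups = NULL, n_mad = 2) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  stopifnot(length(groups) == length(values))
  keep <- rep(TRUE, length(values))
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 3) {
      warning("group '", g, "' has fewer than 3 wells; no outlier removal",
              call. = FALSE)
      next
    }
    m <- stats::median(values[i])
    s <- mad_raw(values[i])
    keep[i] <- abs(values[i] - m) <= n_mad * s
  }
  keep
}
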