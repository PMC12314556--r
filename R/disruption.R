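#' Modified robust Z-prime disruption score
#'
#' A robust simplification of the classical Z-factor used to decide whether a
#' treatment resolves a morphological feature from vehicle control:
#'
#' \deqn{Z'_{mod} = 1 - \frac{MAD_{treat} + MAD_{control}}
#'                          {|median_{treat} - median_{control}|}}
#'
#' The scaling constant 3 of the classical score is removed and median/raw
#' MAD replace mean/SD, so no normality is assumed. A feature is called
#' disrupted when the score is strictly positive, i.e. when the arms'
#' medians are separated by more than the two spreads combined. When the
#' medians tie the score is undefined (`NA`) and the feature is not
#' disrupted.
#'
#' @param treat,control Numeric vectors of per-well feature values
#'   (>= 2 wells each).
#' @return A one-row data.frame: `z_mod`, `disrupted`, `n_treat`,
#'   `n_control`, `median_treat`, `median_control`, `mad_treat`,
#'   `mad_control`.
#' @examples
#' modified_z_prime(c(4, 5, 6), c(0, 1, 2)) # z_mod 0.5, disrupted
#' @export
modified_z_prime <- function(treat, control) {
  if (length(treat) < 2 || length(control) < 2) {
    stop("modified Z-prime needs >= 2 values per arm", call. = FALSE)
  }
  mt <- stats::median(treat)
  mc <- stats::median(control)
  st <- mad_raw(treat)
  sc <- mad_raw(control)
  delta <- abs(mt - mc)
  z <- if (delta == 0) NA_real_ else 1 - (st + sc) / delta
  data.frame(
    z_mod = z,
    disrupted = !is.na(z) && z > 0,
    n_treat = length(treat), n_control = length(control),
    median_treat = mt, median_control = mc,
    mad_treat = st, mad_control = sc
  )
}

#' Per-feature disruption table
#'
#' Scores every feature of every treated (genotype, treatment, concentration)
#' group against the *same genotype's* vehicle wells with
#' [modified_z_prime()]. Groups with fewer than 2 wells, or genotypes without
#' >= 2 vehicle wells, are skipped and reported.
#'
#' @param profiles Normalized well-profile data.frame.
#' @param control_treatment Vehicle treatment label (default `"DMSO"`).
#' @return Data.frame with one row per (feature, group); skipped groups in
#'   the `"skipped"` attribute.
#' @export
disruption_table <- function(profiles, control_treatment = "DMSO") {
  check_profile_metadata(profiles)
  feats <- feature_columns(profiles)
  treated <- profiles[profiles$Metadata_treatment != control_treatment, ,
                      drop = FALSE]
  grp <- interaction(treated$Metadata_genotype, treated$Metadata_treatment,
                     treated$Metadata_concentration, drop = TRUE)
  rows <- vector("list", 0)
  skipped <- character(0)
  for (g in levels(grp)) {
    sub <- treated[grp == g, , drop = FALSE]
    genotype <- sub$Metadata_genotype[1]
    ctrl <- profiles[profiles$Metadata_treatment == control_treatment &
                       profiles$Metadata_genotype == genotype, , drop = FALSE]
    if (nrow(sub) < 2 || nrow(ctrl) < 2) {
      skipped <- c(skipped, g)
      next
    }
    for (f in feats) {
      sc <- modified_z_prime(sub[[f]], ctrl[[f]])
      sc <- cbind(data.frame(feature = f, genotype = genotype,
                             treatment = sub$Metadata_treatment[1],
                             concentration = sub$Metadata_concentration[1],
                             stringsAsFactors = FALSE), sc)
      rows[[length(rows) + 1]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Percent disrupted features per group
#'
#' Fraction (as a percentage) of scored features whose disruption flag is
#' set, per group. Undefined (tied-median) scores count as scored but not
#' disrupted.
#'
#' @param scores Disruption table from [disruption_table()].
#' @param by Grouping columns (default genotype, treatment, concentration).
#' @return Summary data.frame with `n_features`, `n_disrupted`,
#'   `percent_disrupted` per group.
#' @export
percent_disrupted <- function(scores,
                              by = c("genotype", "treatment", "concentration")) {
  if (nrow(scores) == 0) stop("empty disruption table", call. = FALSE)
  split_scores <- split(scores, scores[by], drop = TRUE)
  out <- do.call(rbind, lapply(split_scores, function(s) {
    cbind(s[1, by, drop = FALSE],
          data.frame(n_features = nrow(s),
                     n_disrupted = sum(s$disrupted),
                     percent_disrupted = 100 * sum(s$disrupted) / nrow(s)))
  }))
  rownames(out) <- NULL
  out
}

#' Genotype-dependency adjustment of disruption scores
#'
#' Quantifies how much of a feature's disruption requires the knocked-out
#' gene by subtracting the KO genotype's score from the WT score per
#' (feature, treatment, concentration). Scores below `clamp_floor`
#' (including undefined tied-median scores) are raised to `clamp_floor`
#' before subtraction, bounding the influence of near-tie denominators.
#' Positive adjusted values indicate disruption selectively in WT
#' (dependent); values <= 0 are classified independent. By default only
#' features with discriminatory potential in WT (`z_wt > 0`) are kept.
#'
#' @param scores Disruption table covering both genotypes.
#' @param wt,ko Genotype labels.
#' @param clamp_floor Lower clamp applied before subtraction (default -10).
#' @param restrict_wt_positive Keep only rows with unclamped `z_wt > 0`
#'   (default TRUE).
#' @return Data.frame: feature, treatment, concentration, `z_wt`, `z_ko`
#'   (clamped), `adjusted`, `classification`.
#' @export
dependency_adjust <- function(scores, wt = "WT", ko, clamp_floor = -10,
                              restrict_wt_positive = TRUE) {
  key_cols <- c("feature", "treatment", "concentration")
  s_wt <- scores[scores$genotype == wt, c(key_cols, "z_mod"), drop = FALSE]
  s_ko <- scores[scores$genotype == ko, c(key_cols, "z_mod"), drop = FALSE]
  names(s_wt)[4] <- "z_wt_raw"
  names(s_ko)[4] <- "z_ko_raw"
  # NA z_mod is a legitimate tied-median sentinel; a key present in only one
  # genotype is a reconciliation error
  k_wt <- do.call(paste, s_wt[key_cols])
  k_ko <- do.call(paste, s_ko[key_cols])
  unmatched <- c(setdiff(k_wt, k_ko), setdiff(k_ko, k_wt))
  if (length(unmatched) > 0) {
    stop("unmatched (feature, treatment, concentration) keys across genotypes: ",
         paste(utils::head(unmatched, 5), collapse = "; "), call. = FALSE)
  }
  merged <- merge(s_wt, s_ko, by = key_cols, sort = TRUE)
  clamp <- function(z) pmax(ifelse(is.na(z), clamp_floor, z), clamp_floor)
  z_wt <- clamp(merged$z_wt_raw)
  z_ko <- clamp(merged$z_ko_raw)
  out <- data.frame(merged[key_cols],
                    z_wt = z_wt, z_ko = z_ko,
                    adjusted = z_wt - z_ko,
                    stringsAsFactors = FALSE)
  out$classification <- ifelse(out$adjusted > 0, "dependent", "independent")
  if (restrict_wt_positive) {
    keep <- !is.na(merged$z_wt_raw) & merged$z_wt_raw > 0
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
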