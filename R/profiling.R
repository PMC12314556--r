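#' Correlation distance between two well profiles
#'
#' One minus the Pearson correlation of the two feature vectors, the standard
#' profile-similarity metric in image-based profiling: 0 for identical
#' profile shapes, 1 for uncorrelated, 2 for anti-correlated.
#'
#' @param a,b Numeric vectors over the same retained feature set.
#' @return Distance in [0, 2].
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation distance undefined for a zero-variance profile",
         call. = FALSE)
  }
  1 - stats::cor(a, b)
}

#' Pairwise correlation-distance matrix over wells
#'
#' @param profiles Normalized well-profile data.frame.
#' @return Symmetric matrix of correlation distances with `plate:well` ids as
#'   dimnames; zero diagonal, entries in [0, 2].
#' @export
distance_matrix <- function(profiles) {
  check_profile_metadata(profiles)
  x <- feature_values(profiles)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ", paste(well_id(profiles)[sds == 0],
         collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(x))
  diag(d) <- 0
  dimnames(d) <- list(well_id(profiles), well_id(profiles))
  d
}

#' Complete-linkage clustering of wells
#'
#' Agglomerative clustering of the well-well correlation-distance matrix with
#' complete linkage (merge height = maximum pairwise distance between the
#' merged clusters).
#'
#' @param d Square symmetric distance matrix (e.g. from [distance_matrix()]).
#' @return An `hclust` tree.
#' @export
cluster_wells <- function(d) {
  if (nrow(d) < 2) stop("clustering needs at least 2 wells", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' PCA embedding with dose-ordered centroid trajectories
#'
#' Projects normalized well profiles onto the first principal components and,
#' for every (genotype, treatment), returns the centroid per concentration in
#' increasing dose order, with the genotype's vehicle centroid prepended as
#' dose 0 -- the trajectory a treatment traces through morphological space as
#' dose increases.
#'
#' @param profiles Normalized well-profile data.frame (features already on a
#'   common robust scale; no second scaling is applied).
#' @param n_components Number of components (default 2).
#' @param vehicle_treatment Vehicle label supplying the dose-0 centroid.
#' @return A list with `embedding` (metadata + PC scores per well) and
#'   `paths` (genotype, treatment, concentration, centroid per PC).
#' @export
pca_trajectories <- function(profiles, n_components = 2,
                             vehicle_treatment = "DMSO") {
  check_profile_metadata(profiles)
  x <- feature_values(profiles)
  if (nrow(x) < n_components) {
    stop("fewer wells than requested components", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  embedding <- cbind(profiles[, metadata_columns(profiles), drop = FALSE],
                     as.data.frame(scores))

  paths <- do.call(rbind, lapply(
    split(embedding, embedding[c("Metadata_genotype", "Metadata_treatment")],
          drop = TRUE),
    function(g) {
      genotype <- g$Metadata_genotype[1]
      treatment <- g$Metadata_treatment[1]
      if (treatment == vehicle_treatment) return(NULL)
      veh <- embedding[embedding$Metadata_genotype == genotype &
                         embedding$Metadata_treatment == vehicle_treatment, ,
                       drop = FALSE]
      pieces <- list()
      if (nrow(veh) > 0) {
        pieces[[1]] <- data.frame(
          genotype = genotype, treatment = treatment, concentration = 0,
          t(colMeans(veh[, colnames(scores), drop = FALSE])),
          stringsAsFactors = FALSE)
      }
      for (conc in sort(unique(g$Metadata_concentration))) {
        gg <- g[g$Metadata_concentration == conc, , drop = FALSE]
        pieces[[length(pieces) + 1]] <- data.frame(
          genotype = genotype, treatment = treatment, concentration = conc,
          t(colMeans(gg[, colnames(scores), drop = FALSE])),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, pieces)
    }))
  rownames(paths) <- NULL
  list(embedding = embedding, paths = paths)
}

#' Per-well morphological-uniformity scores
#'
#' For every well in a group of like-treated wells (same genotype, treatment
#' and concentration), the mean correlation distance to all *other* members
#' of its group; `uniformity = 1 - mean_like_distance`, so that more uniform
#' replicate morphology scores higher. Singleton groups are omitted and
#' reported.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param profiles The well-profile table supplying group metadata, in the
#'   same well order used to build `d`.
#' @param include_self Include the zero self-distance in the mean
#'   (default FALSE; the self term only dilutes the statistic).
#' @return Data.frame with well id, group metadata, group size,
#'   `mean_like_distance` and `uniformity`; singleton-group wells are listed
#'   in the `"omitted"` attribute.
#' @export
uniformity_scores <- function(d, profiles, include_self = FALSE) {
  check_profile_metadata(profiles)
  ids <- well_id(profiles)
  stopifnot(identical(ids, rownames(d)))
  grp <- group_key(profiles, c("Metadata_genotype", "Metadata_treatment",
                               "Metadata_concentration"))
  rows <- list()
  omitted <- character(0)
  for (i in seq_along(ids)) {
    mates <- which(grp == grp[i])
    if (!include_self) mates <- setdiff(mates, i)
    if (length(mates) == 0) {
      omitted <- c(omitted, ids[i])
      next
    }
    mld <- mean(d[i, mates])
    rows[[length(rows) + 1]] <- data.frame(
      well = ids[i],
      genotype = profiles$Metadata_genotype[i],
      treatment = profiles$Metadata_treatment[i],
      concentration = profiles$Metadata_concentration[i],
      n_group = length(mates) + !include_self,
      mean_like_distance = mld,
      uniformity = 1 - mld,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "omitted") <- omitted
  out
}
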