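#' Trim spheroid time-points by the per-time 2-MAD rule
#'
#' Live-imaging spheroid area tracks carry sporadic segmentation artefacts.
#' For every group of like-treated wells (same genotype, treatment,
#' concentration and replicate batch) and every time-point, areas lying
#' strictly more than `n_mad` raw MADs from the group median at that time are
#' masked; wells with more than `exclude_fraction` of their time-points
#' masked are flagged excluded. Time-points with fewer than 3 wells in the
#' group are left untrimmed. Trimming operates on raw areas, before any
#' normalization.
#'
#' @param tracks Long-format data.frame with columns `well`, `genotype`,
#'   `treatment`, `concentration`, `replicate`, `time_h`, `area`.
#' @param n_mad Raw-MAD cut (default 2).
#' @param exclude_fraction Strict exclusion threshold on the trimmed fraction
#'   (default 0.5: a well with exactly half its points masked is retained).
#' @param pool_all_wells Pool across treatments when computing the per-time
#'   median/MAD (default FALSE: within like-treated groups).
#' @return `tracks` with logical columns `trimmed` (per row) and `excluded`
#'   (per well) added.
#' @export
trim_timepoints <- function(tracks, n_mad = 2, exclude_fraction = 0.5,
                            pool_all_wells = FALSE) {
  need <- c("well", "genotype", "treatment", "concentration", "replicate",
            "time_h", "area")
  missing <- setdiff(need, names(tracks))
  if (length(missing) > 0) {
    stop("tracks table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grp <- if (pool_all_wells) {
    rep("all", nrow(tracks))
  } else {
    paste(tracks$genotype, tracks$treatment, tracks$concentration,
          tracks$replicate)
  }
  tracks$trimmed <- FALSE
  for (g in unique(grp)) {
    for (tt in unique(tracks$time_h[grp == g])) {
      i <- which(grp == g & tracks$time_h == tt)
      if (length(i) < 3) next
      m <- stats::median(tracks$area[i])
      s <- mad_raw(tracks$area[i])
      tracks$trimmed[i] <- abs(tracks$area[i] - m) > n_mad * s
    }
  }
  frac <- tapply(tracks$trimmed, tracks$well, mean)
  tracks$excluded <- unname(frac[tracks$well] > exclude_fraction)
  tracks
}

#' Spheroid growth: day-7 area normalized to 24 h
#'
#' Per well, the ratio of the spheroid area at 168 h to the area at 24 h,
#' using the unmasked observation nearest each anchor within `tolerance`
#' hours. Excluded wells (from [trim_timepoints()]) and wells without a
#' usable anchor are skipped and reported.
#'
#' @param tracks Output of [trim_timepoints()].
#' @param anchor_start,anchor_end Anchor times in hours (defaults 24, 168).
#' @param tolerance Maximum distance to the nearest unmasked time-point
#'   (default 4 h); uses of a neighbouring time-point are logged in the
#'   `fallback` column.
#' @return Data.frame per retained well with metadata, anchor times actually
#'   used, `growth` (area ratio) and `fallback`; skipped wells in the
#'   `"skipped"` attribute.
#' @export
spheroid_growth <- function(tracks, anchor_start = 24, anchor_end = 168,
                            tolerance = 4) {
  if (is.null(tracks$trimmed)) tracks$trimmed <- FALSE
  if (is.null(tracks$excluded)) tracks$excluded <- FALSE
  pick <- function(w, anchor) {
    ok <- !w$trimmed
    if (!any(ok)) return(NULL)
    gap <- abs(w$time_h - anchor)
    gap[!ok] <- Inf
    i <- which.min(gap)
    if (gap[i] > tolerance) return(NULL)
    w[i, , drop = FALSE]
  }
  rows <- list()
  skipped <- character(0)
  for (w in split(tracks, tracks$well)) {
    if (w$excluded[1]) {
      skipped <- c(skipped, w$well[1])
      next
    }
    a <- pick(w, anchor_start)
    b <- pick(w, anchor_end)
    if (is.null(a) || is.null(b)) {
      skipped <- c(skipped, w$well[1])
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      well = w$well[1], genotype = w$genotype[1], treatment = w$treatment[1],
      concentration = w$concentration[1], replicate = w$replicate[1],
      time_start = a$time_h, time_end = b$time_h,
      growth = b$area / a$area,
      fallback = a$time_h != anchor_start || b$time_h != anchor_end,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(well = character(0), genotype = character(0),
                      treatment = character(0), concentration = numeric(0),
                      replicate = numeric(0), time_start = numeric(0),
                      time_end = numeric(0), growth = numeric(0),
                      fallback = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Fit a logistic growth curve
#'
#' Least-squares fit of `L / (1 + exp(-k (t - t0)))` to a confluency or area
#' time series, via Levenberg-Marquardt with deterministic initialization
#' (L from the observed maximum, t0 from the time of half-maximum, k from a
#' logit-linear pre-fit). The single-number growth rate is
#' `slope_stat = L * k / 4`, the curve's maximal derivative. Degenerate
#' (constant) series return `slope_stat = 0` with `fit_ok = FALSE`;
#' other fit failures fall back to the slope of a straight-line fit.
#'
#' @param times Strictly increasing times in hours (>= 4 points).
#' @param values Confluency (percent) or area at each time.
#' @return A one-row data.frame: `L`, `k`, `t0`, `slope_stat`, `fit_ok`.
#' @export
fit_logistic <- function(times, values) {
  if (length(times) < 4) stop("logistic fit needs >= 4 points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(values) != length(times)) stop("times/values length mismatch", call. = FALSE)

  if (stats::sd(values) == 0) {
    return(data.frame(L = values[1], k = 0, t0 = NA_real_, slope_stat = 0,
                      fit_ok = FALSE))
  }
  L0 <- max(values) * 1.05
  w <- pmin(pmax(values / L0, 1e-3), 1 - 1e-3)
  pre <- stats::lm(stats::qlogis(w) ~ times)
  k0 <- unname(stats::coef(pre)[2])
  if (!is.finite(k0) || k0 == 0) k0 <- 1e-3
  t00 <- -unname(stats::coef(pre)[1]) / k0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      values ~ L / (1 + exp(-k * (times - t0))),
      start = list(L = L0, k = k0, t0 = t00),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    lin <- stats::lm(values ~ times)
    return(data.frame(L = NA_real_, k = NA_real_, t0 = NA_real_,
                      slope_stat = unname(stats::coef(lin)[2]),
                      fit_ok = FALSE))
  }
  p <- stats::coef(fit)
  data.frame(L = unname(p["L"]), k = unname(p["k"]), t0 = unname(p["t0"]),
             slope_stat = unname(p["L"] * p["k"] / 4), fit_ok = TRUE)
}

#' Per-well logistic growth table with vehicle normalization
#'
#' Fits [fit_logistic()] to every well's confluency track and normalizes the
#' slope statistic to the mean slope statistic of the same genotype's vehicle
#' wells, with negative growth rates clipped to 0.
#'
#' @param tracks Long-format data.frame (`well`, `genotype`, `treatment`,
#'   `concentration`, `replicate`, `time_h`, `area`); `area` holds percent
#'   confluency for 2D assays.
#' @param vehicle_treatment Vehicle label (default `"DMSO"`).
#' @return Per-well data.frame with fit parameters, `slope_stat` and
#'   `normalized_growth` (>= 0).
#' @export
growth_table <- function(tracks, vehicle_treatment = "DMSO") {
  rows <- do.call(rbind, lapply(split(tracks, tracks$well), function(w) {
    w <- w[order(w$time_h), , drop = FALSE]
    fit <- fit_logistic(w$time_h, w$area)
    cbind(data.frame(well = w$well[1], genotype = w$genotype[1],
                     treatment = w$treatment[1],
                     concentration = w$concentration[1],
                     replicate = w$replicate[1], stringsAsFactors = FALSE),
          fit)
  }))
  rownames(rows) <- NULL
  rows$normalized_growth <- NA_real_
  for (g in unique(rows$genotype)) {
    i <- which(rows$genotype == g)
    veh <- rows$slope_stat[i][rows$treatment[i] == vehicle_treatment]
    if (length(veh) == 0) {
      stop("no vehicle wells for genotype '", g, "'", call. = FALSE)
    }
    rows$normalized_growth[i] <- pmax(rows$slope_stat[i], 0) / mean(veh)
  }
  rows
}

#' Genotype sensitivity to treatment
#'
#' Per well, the treatment response is `100 * (1 - normalized_growth)` (the
#' percent decrease in growth relative to vehicle). Sensitivity compares each
#' genotype's response to the mean response of the reference genotype within
#' the same treatment and concentration; negative values indicate reduced
#' sensitivity relative to the reference (or increased growth on treatment).
#'
#' @param growth Per-well growth table from [growth_table()].
#' @param reference_genotype Reference for the comparison (default `"WT"`).
#' @param vehicle_treatment Vehicle label, excluded from responses.
#' @return Data.frame per treated well: metadata, `response`, `sensitivity`.
#' @export
sensitivity <- function(growth, reference_genotype = "WT",
                        vehicle_treatment = "DMSO") {
  tr <- growth[growth$treatment != vehicle_treatment, , drop = FALSE]
  tr$response <- 100 * (1 - tr$normalized_growth)
  key <- paste(tr$treatment, tr$concentration)
  ref_mean <- tapply(tr$response[tr$genotype == reference_genotype],
                     key[tr$genotype == reference_genotype], mean)
  missing <- setdiff(unique(key), names(ref_mean))
  if (length(missing) > 0) {
    stop("no reference-genotype wells for: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  tr$sensitivity <- tr$response - as.numeric(ref_mean[key])
  rownames(tr) <- NULL
  tr
}
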