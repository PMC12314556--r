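#' Cell-contact window filter
#'
#' Retains cells whose percent cell-cell contact lies inside the closed
#' window `[low, high]`. Restricting to a narrow contact band controls for
#' the strong dependence of YAP localization on cell crowding, so that
#' treatment effects are compared at matched confluency.
#'
#' @param cells Per-cell data.frame with a `contact_percent` column.
#' @param low,high Window bounds in percent (defaults 45 and 55, inclusive).
#' @return The retained rows; the number of input and retained cells is
#'   attached as the `"retention"` attribute.
#' @export
contact_filter <- function(cells, low = 45, high = 55) {
  if (low >= high) stop("contact window requires low < high", call. = FALSE)
  keep <- !is.na(cells$contact_percent) &
    cells$contact_percent >= low & cells$contact_percent <= high
  out <- cells[keep, , drop = FALSE]
  attr(out, "retention") <- c(n_input = nrow(cells), n_retained = sum(keep))
  out
}

#' Per-cell nuclear:cytoplasmic intensity ratios
#'
#' Computes `nuclear_intensity / cytoplasmic_intensity` per cell. Cells
#' without detectable signal in both compartments (non-positive or missing
#' intensity in either) cannot yield a ratio; they are flagged and excluded,
#' and counted in the `"excluded"` attribute rather than silently dropped.
#'
#' @param cells Per-cell data.frame with `nuclear_intensity` and
#'   `cytoplasmic_intensity` columns.
#' @return The rows with a valid ratio, with a `ratio` column added;
#'   attribute `"excluded"` holds the number of flagged cells.
#' @export
cell_ratio <- function(cells) {
  ok <- !is.na(cells$nuclear_intensity) & !is.na(cells$cytoplasmic_intensity) &
    cells$nuclear_intensity > 0 & cells$cytoplasmic_intensity > 0
  out <- cells[ok, , drop = FALSE]
  out$ratio <- out$nuclear_intensity / out$cytoplasmic_intensity
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Per-well localization summary normalized to vehicle
#'
#' Aggregates per-cell nuclear:cytoplasmic ratios (contact filter already
#' applied) to per-well medians, expresses each well as a percentage of the
#' same-genotype vehicle wells, and removes outlier wells by the 2-MAD rule
#' across biological replicates within each (genotype, treatment,
#' concentration) group.
#'
#' @param cells Per-cell data.frame with metadata columns `plate`, `well`,
#'   `genotype`, `treatment`, `concentration`, `replicate` and intensity /
#'   contact columns.
#' @param vehicle_treatment Vehicle label (default `"DMSO"`).
#' @param vehicle_stat How vehicle-well medians are pooled into the baseline:
#'   `"mean"` (default, percent-of-control convention) or `"median"`.
#' @param per_plate Compute the vehicle baseline within each plate
#'   (default TRUE), making the percentages invariant to plate-wide
#'   intensity rescaling.
#' @param outlier_n_mad Raw-MAD cut for well removal (default 2).
#' @return Data.frame with one row per retained well: metadata,
#'   `n_cells_retained`, `median_ratio`, `percent_of_vehicle`, `outlier`
#'   (wells failing the 2-MAD rule are kept in the table, flagged, and
#'   excluded from nothing downstream by the caller's choice); wells with no
#'   valid cells are listed in the `"empty_wells"` attribute.
#' @export
well_summary <- function(cells, vehicle_treatment = "DMSO",
                         vehicle_stat = c("mean", "median"),
                         per_plate = TRUE, outlier_n_mad = 2) {
  vehicle_stat <- match.arg(vehicle_stat)
  all_wells <- unique(paste(cells$plate, cells$well, sep = ":"))
  cells <- cell_ratio(cells)
  kept_wells <- unique(paste(cells$plate, cells$well, sep = ":"))
  key <- interaction(cells$plate, cells$well, drop = TRUE)
  rows <- do.call(rbind, lapply(split(cells, key), function(w) {
    data.frame(plate = w$plate[1], well = w$well[1],
               genotype = w$genotype[1], treatment = w$treatment[1],
               concentration = w$concentration[1], replicate = w$replicate[1],
               n_cells_retained = nrow(w),
               median_ratio = stats::median(w$ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL

  pool <- if (vehicle_stat == "mean") mean else stats::median
  base_group <- if (per_plate) {
    interaction(rows$genotype, rows$plate, drop = TRUE)
  } else {
    factor(rows$genotype)
  }
  rows$percent_of_vehicle <- NA_real_
  for (g in levels(base_group)) {
    i <- which(base_group == g)
    veh <- rows$median_ratio[i][rows$treatment[i] == vehicle_treatment]
    if (length(veh) == 0) {
      stop("no vehicle wells for baseline group '", g, "'", call. = FALSE)
    }
    rows$percent_of_vehicle[i] <- 100 * rows$median_ratio[i] / pool(veh)
  }

  grp <- interaction(rows$genotype, rows$treatment, rows$concentration,
                     drop = TRUE)
  rows$outlier <- !remove_outlier_wells(rows$percent_of_vehicle, grp,
                                        n_mad = outlier_n_mad)
  attr(rows, "empty_wells") <- setdiff(all_wells, kept_wells)
  rows
}
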