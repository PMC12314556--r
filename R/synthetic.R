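#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the three generators. The defaults
#' emulate the measurement structure of a TEAD-inhibitor evaluation in an
#' immortalised mesothelial line: a WT and a YAP-KO genotype, vehicle (DMSO)
#' wells on every plate, two inhibitor families dosed in micromolar,
#' 3 biological replicates with 4 technical wells for the per-cell assay, and
#' logistic growth tracks.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_features Number of morphological features.
#' @param n_blocks Number of correlated feature blocks.
#' @param block_rho Within-block correlation in [0, 1).
#' @param genotypes Named character vector with elements `WT` and `KO`.
#' @param treatments Data.frame with columns `label`, `family` and a list
#'   column `concentrations` (micromolar).
#' @param n_replicate_wells Wells per (genotype, treatment, concentration)
#'   group in the feature matrix (>= 2).
#' @param effect_size Planted feature shift at top dose, in control-MAD
#'   units.
#' @param affected_fraction Fraction of features shifted by each treatment.
#' @param dependent_fraction Fraction of affected features whose shift is
#'   absent in the KO genotype (YAP-dependent features), in [0, 1].
#' @param ko_attenuation Residual effect multiplier on dependent features in
#'   KO (default 0 = all-or-none; set in (0,1) for partial attenuation).
#' @param outlier_well_rate Probability that a well is a gross outlier.
#' @param cells_per_well Cells per well in the per-cell table (>= 1).
#' @param n_bio_replicates,n_tech_wells Per-cell assay layout (defaults 3
#'   biological replicates of 4 technical wells).
#' @param intensity_scale Median cytoplasmic intensity (arbitrary units,
#'   > 0).
#' @param base_ratio Baseline nuclear:cytoplasmic ratio.
#' @param ratio_effect Multiplicative nuclear:cytoplasmic ratio at top dose
#'   relative to vehicle (1 = no effect, 0.5 = halved).
#' @param growth_params Data.frame with columns `genotype`, `L`, `k`, `t0`
#'   (confluency plateau in percent, rate per hour, midpoint in hours).
#' @param growth_effect Fractional reduction of the logistic rate `k` at top
#'   dose in the sensitive genotype.
#' @param genotype_sensitivity Named vector of multipliers on `growth_effect`
#'   per genotype (default WT 1, KO 0: the KO does not respond).
#' @param growth_noise_sd SD of multiplicative log-normal noise on tracks.
#' @param spike_rate Probability of a segmentation-artefact spike per
#'   (well, time-point) in spheroid tracks.
#' @param feature_noise_sd SD of the independent feature noise component
#'   (the block structure contributes the rest of the unit variance).
#' @return A validated `morphoscreen_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_features = 60,
    n_blocks = 12,
    block_rho = 0.5,
    genotypes = c(WT = "WT", KO = "YAP_KO"),
    treatments = data.frame(
      label = c("TEADi_sel", "TEADi_pan"),
      family = c("selective_TEAD", "non_selective"),
      concentrations = I(list(c(0.1, 1, 10), c(0.1, 1, 10))),
      stringsAsFactors = FALSE),
    n_replicate_wells = 3,
    effect_size = 6,
    affected_fraction = 0.3,
    dependent_fraction = 0.5,
    ko_attenuation = 0,
    outlier_well_rate = 0.02,
    cells_per_well = 300,
    n_bio_replicates = 3,
    n_tech_wells = 4,
    intensity_scale = 500,
    base_ratio = 1.2,
    ratio_effect = 0.5,
    growth_params = data.frame(
      genotype = c("WT", "YAP_KO"),
      L = c(100, 100), k = c(0.1, 0.07), t0 = c(36, 42),
      stringsAsFactors = FALSE),
    growth_effect = 0.5,
    genotype_sensitivity = c(WT = 1, YAP_KO = 0),
    growth_noise_sd = 0.05,
    spike_rate = 0.02,
    feature_noise_sd = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_replicate_wells < 2) {
    stop("n_replicate_wells must be >= 2 (zero or single replicate wells ",
         "cannot support robust statistics)", call. = FALSE)
  }
  if (cfg$dependent_fraction < 0 || cfg$dependent_fraction > 1) {
    stop("dependent_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) {
    stop("block_rho must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$outlier_well_rate < 0 || cfg$outlier_well_rate > 1) {
    stop("outlier_well_rate must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cells_per_well < 1) stop("cells_per_well must be >= 1", call. = FALSE)
  if (cfg$intensity_scale <= 0) {
    stop("intensity_scale must be positive", call. = FALSE)
  }
  if (!all(c("WT", "KO") %in% names(cfg$genotypes))) {
    stop("genotypes must name a WT and a KO label", call. = FALSE)
  }
  class(cfg) <- "morphoscreen_config"
  cfg
}

# log-linear dose scaling on [1/3, 1]: lowest configured dose carries a third
# of the full effect, the top dose the full effect
dose_scale <- function(conc, all_conc) {
  lo <- min(all_conc)
  hi <- max(all_conc)
  if (lo == hi) return(rep(1, length(conc)))
  1 / 3 + (2 / 3) * (log(conc) - log(lo)) / (log(hi) - log(lo))
}

feature_names <- function(n) sprintf("Ftr_%03d", seq_len(n))

# raw MAD of the standard-normal baseline; effect_size is in these units
.control_mad_unit <- stats::qnorm(0.75)

#' Generate a block-correlated well-profile matrix with planted effects
#'
#' Draws baseline features from a unit-variance distribution with shared
#' latent block factors (loading `sqrt(block_rho)`), shifts the affected
#' features of treated wells by `effect_size` control-MAD units scaled
#' log-linearly with dose, withholds the shift from YAP-dependent features in
#' the KO genotype, and contaminates wells with gross outliers at
#' `outlier_well_rate`. Vehicle (DMSO) wells are present for every genotype
#' and replicate plate.
#'
#' @param config A [synthetic_config()].
#' @return A list with `profiles` (well-profile data.frame) and `truth`
#'   (`affected_features`: treatment -> feature set; `dependency_labels`:
#'   treatment -> named label vector over features, in
#'   dependent/independent/null; `effect_signs`; `outlier_wells`).
#' @export
generate_feature_matrix <- function(config) {
  stopifnot(inherits(config, "morphoscreen_config"))
  set.seed(config$seed)
  nf <- config$n_features
  feats <- feature_names(nf)
  blocks <- rep(seq_len(config$n_blocks), length.out = nf)
  noise_load <- sqrt(1 - config$block_rho)

  # planted truth, per treatment
  affected <- list()
  labels <- list()
  signs <- list()
  n_aff <- if (config$effect_size == 0) 0 else
    round(config$affected_fraction * nf)
  for (tr in config$treatments$label) {
    aff <- if (n_aff > 0) sort(sample(feats, n_aff)) else character(0)
    lab <- stats::setNames(rep("null", nf), feats)
    if (length(aff) > 0) {
      n_dep <- round(config$dependent_fraction * length(aff))
      dep <- if (n_dep > 0) sort(sample(aff, n_dep)) else character(0)
      lab[aff] <- "independent"
      lab[dep] <- "dependent"
    }
    affected[[tr]] <- aff
    labels[[tr]] <- lab
    signs[[tr]] <- stats::setNames(sample(c(-1, 1), nf, replace = TRUE), feats)
  }

  # well layout: per genotype, vehicle + each treatment x concentration,
  # one plate per replicate index
  meta <- list()
  for (gt in config$genotypes) {
    for (r in seq_len(config$n_replicate_wells)) {
      meta[[length(meta) + 1]] <- data.frame(
        Metadata_genotype = gt, Metadata_treatment = "DMSO",
        Metadata_family = "vehicle", Metadata_concentration = 0,
        Metadata_replicate = r, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(config$treatments))) {
      tr <- config$treatments$label[i]
      for (conc in config$treatments$concentrations[[i]]) {
        for (r in seq_len(config$n_replicate_wells)) {
          meta[[length(meta) + 1]] <- data.frame(
            Metadata_genotype = gt, Metadata_treatment = tr,
            Metadata_family = config$treatments$family[i],
            Metadata_concentration = conc,
            Metadata_replicate = r, stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, meta)
  # one plate: replicate wells are technical-replicate wells side by side,
  # so vehicle wells are present on the (single) plate for every replicate
  meta <- cbind(data.frame(
    Metadata_plate = "P1",
    Metadata_well = sprintf("W%03d", seq_len(nrow(meta))),
    stringsAsFactors = FALSE), meta)

  n_wells <- nrow(meta)
  x <- matrix(0, n_wells, nf, dimnames = list(NULL, feats))
  outlier_wells <- character(0)
  for (w in seq_len(n_wells)) {
    z_block <- stats::rnorm(config$n_blocks)
    eps <- stats::rnorm(nf)
    row <- sqrt(config$block_rho) * z_block[blocks] + noise_load * eps
    tr <- meta$Metadata_treatment[w]
    if (tr != "DMSO" && config$effect_size != 0) {
      all_conc <- sort(unique(unlist(
        config$treatments$concentrations[config$treatments$label == tr])))
      sc <- dose_scale(meta$Metadata_concentration[w], all_conc)
      shift <- config$effect_size * .control_mad_unit * sc
      aff <- affected[[tr]]
      eff <- stats::setNames(rep(0, nf), feats)
      eff[aff] <- shift * signs[[tr]][aff]
      if (meta$Metadata_genotype[w] == config$genotypes[["KO"]]) {
        dep <- names(labels[[tr]])[labels[[tr]] == "dependent"]
        eff[dep] <- eff[dep] * config$ko_attenuation
      }
      row <- row + eff
    }
    if (stats::runif(1) < config$outlier_well_rate) {
      row <- row + 8
      outlier_wells <- c(outlier_wells,
                         paste(meta$Metadata_plate[w], meta$Metadata_well[w],
                               sep = ":"))
    }
    x[w, ] <- row
  }

  profiles <- cbind(meta, as.data.frame(x))
  truth <- list(affected_features = affected, dependency_labels = labels,
                effect_signs = signs, outlier_wells = outlier_wells)
  list(profiles = profiles, truth = truth)
}

#' Generate a per-cell intensity table with a dose-dependent ratio shift
#'
#' Emulates per-cell exports of a nuclear-localization assay: log-normal
#' cytoplasmic intensities, per-cell nuclear:cytoplasmic ratios around a
#' well-level target, percent cell-cell contact uniform on [0, 100], and a
#' multiplicative dose-dependent reduction of the ratio per treatment
#' (log-linear from no effect at dose 0 to `ratio_effect` at top dose).
#' Occasional gross outlier wells have their ratio multiplied by 4.
#'
#' @param config A [synthetic_config()].
#' @return A list with `cells` (per-cell data.frame) and `truth`
#'   (`well_target_ratio`: the per-well true ratio before cell noise;
#'   `ratio_effect_at`: treatment x concentration effect multipliers;
#'   `outlier_wells`).
#' @export
generate_cell_table <- function(config) {
  stopifnot(inherits(config, "morphoscreen_config"))
  set.seed(config$seed + 1L)
  rows <- list()
  target <- numeric(0)
  effects <- list()
  outlier_wells <- character(0)
  widx <- 0

  for (gt in config$genotypes) {
    combos <- data.frame(treatment = "DMSO", concentration = 0,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(config$treatments))) {
      combos <- rbind(combos, data.frame(
        treatment = config$treatments$label[i],
        concentration = config$treatments$concentrations[[i]],
        stringsAsFactors = FALSE))
    }
    for (ci in seq_len(nrow(combos))) {
      tr <- combos$treatment[ci]
      conc <- combos$concentration[ci]
      if (tr == "DMSO") {
        mult <- 1
      } else {
        all_conc <- sort(unique(unlist(
          config$treatments$concentrations[config$treatments$label == tr])))
        sc <- dose_scale(conc, all_conc)
        # log-linear interpolation towards ratio_effect at the top dose
        mult <- exp(sc * log(config$ratio_effect))
        effects[[paste(tr, conc)]] <- mult
      }
      for (br in seq_len(config$n_bio_replicates)) {
        for (tw in seq_len(config$n_tech_wells)) {
          widx <- widx + 1
          plate <- sprintf("P%d", br)
          well <- sprintf("W%03d", widx)
          wkey <- paste(plate, well, sep = ":")
          r_well <- config$base_ratio * mult * exp(stats::rnorm(1, 0, 0.05))
          if (stats::runif(1) < config$outlier_well_rate) {
            r_well <- r_well * 4
            outlier_wells <- c(outlier_wells, wkey)
          }
          n <- config$cells_per_well
          cyto <- stats::rlnorm(n, log(config$intensity_scale), 0.35)
          ratio <- r_well * stats::rlnorm(n, 0, 0.25)
          rows[[widx]] <- data.frame(
            plate = plate, well = well, genotype = gt, treatment = tr,
            concentration = conc, replicate = br,
            nuclear_intensity = cyto * ratio,
            cytoplasmic_intensity = cyto,
            contact_percent = stats::runif(n, 0, 100),
            stringsAsFactors = FALSE)
          target[wkey] <- r_well
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  truth <- list(well_target_ratio = target, ratio_effect_at = effects,
                outlier_wells = outlier_wells)
  list(cells = cells, truth = truth)
}

#' Generate logistic growth tracks
#'
#' Confluency mode samples 0-72 h every 4 h; spheroid mode samples 0-168 h
#' every 12 h (so the 24-h and 168-h anchors are always present). Areas
#' follow per-well logistic curves with multiplicative log-normal noise;
#' treatment reduces the rate `k` by `growth_effect x dose scale x genotype
#' sensitivity`; spheroid tracks receive sporadic artefact spikes (area x 3)
#' at rate `spike_rate`, recorded in the truth object.
#'
#' @param config A [synthetic_config()].
#' @param mode `"confluency"` (2D proliferation) or `"spheroid"`.
#' @param times Optional explicit strictly increasing time grid (hours).
#' @return A list with `tracks` (long data.frame: well, genotype, treatment,
#'   concentration, replicate, time_h, area) and `truth` (`true_growth`: per
#'   well L/k/t0; `outlier_timepoints`: data.frame well/time_h).
#' @export
generate_growth_tracks <- function(config,
                                   mode = c("confluency", "spheroid"),
                                   times = NULL) {
  stopifnot(inherits(config, "morphoscreen_config"))
  mode <- match.arg(mode)
  if (is.null(times)) {
    times <- if (mode == "confluency") seq(0, 72, by = 4) else seq(0, 168, by = 12)
  }
  if (any(diff(times) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  area_scale <- if (mode == "spheroid") 2e5 else 1
  rows <- list()
  true_growth <- list()
  spikes <- list()
  widx <- 0

  for (gt in config$genotypes) {
    gp <- config$growth_params[config$growth_params$genotype == gt, ]
    if (nrow(gp) == 0) stop("no growth_params for genotype ", gt, call. = FALSE)
    sens <- if (gt %in% names(config$genotype_sensitivity)) {
      unname(config$genotype_sensitivity[[gt]])
    } else 1
    combos <- data.frame(treatment = "DMSO", concentration = 0,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(config$treatments))) {
      combos <- rbind(combos, data.frame(
        treatment = config$treatments$label[i],
        concentration = config$treatments$concentrations[[i]],
        stringsAsFactors = FALSE))
    }
    for (ci in seq_len(nrow(combos))) {
      tr <- combos$treatment[ci]
      conc <- combos$concentration[ci]
      k_mult <- 1
      if (tr != "DMSO") {
        all_conc <- sort(unique(unlist(
          config$treatments$concentrations[config$treatments$label == tr])))
        k_mult <- 1 - config$growth_effect * sens * dose_scale(conc, all_conc)
      }
      for (r in seq_len(config$n_replicate_wells)) {
        widx <- widx + 1
        well <- sprintf("W%03d", widx)
        L <- gp$L * area_scale
        k <- gp$k * k_mult
        t0 <- gp$t0
        mu <- L / (1 + exp(-k * (times - t0)))
        noise <- if (config$growth_noise_sd > 0) {
          exp(stats::rnorm(length(times), 0, config$growth_noise_sd))
        } else rep(1, length(times))
        area <- mu * noise
        if (mode == "spheroid" && config$spike_rate > 0) {
          hit <- stats::runif(length(times)) < config$spike_rate
          if (any(hit)) {
            area[hit] <- area[hit] * 3
            spikes[[length(spikes) + 1]] <- data.frame(
              well = well, time_h = times[hit], stringsAsFactors = FALSE)
          }
        }
        rows[[widx]] <- data.frame(
          well = well, genotype = gt, treatment = tr, concentration = conc,
          replicate = r, time_h = times, area = area,
          stringsAsFactors = FALSE)
        true_growth[[well]] <- c(L = L, k = k, t0 = t0)
      }
    }
  }
  tracks <- do.call(rbind, rows)
  rownames(tracks) <- NULL
  outlier_timepoints <- if (length(spikes) > 0) {
    do.call(rbind, spikes)
  } else {
    data.frame(well = character(0), time_h = numeric(0))
  }
  truth <- list(true_growth = true_growth,
                outlier_timepoints = outlier_timepoints)
  list(tracks = tracks, truth = truth)
}
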