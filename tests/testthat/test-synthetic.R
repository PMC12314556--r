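test_that("generators are deterministic given (config, seed)", {
  cfg <- synthetic_config(seed = 101, n_features = 20, cells_per_well = 30,
                          n_replicate_wells = 2)
  expect_identical(generate_feature_matrix(cfg), generate_feature_matrix(cfg))
  expect_identical(generate_cell_table(cfg), generate_cell_table(cfg))
  expect_identical(generate_growth_tracks(cfg, "spheroid"),
                   generate_growth_tracks(cfg, "spheroid"))
  cfg2 <- synthetic_config(seed = 102, n_features = 20, cells_per_well = 30,
                           n_replicate_wells = 2)
  expect_false(identical(generate_feature_matrix(cfg)$profiles,
                         generate_feature_matrix(cfg2)$profiles))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(n_replicate_wells = 0), "n_replicate_wells")
  expect_error(synthetic_config(dependent_fraction = 1.2), "dependent_fraction")
  expect_error(synthetic_config(block_rho = 1), "block_rho")
  expect_error(synthetic_config(cells_per_well = 0), "cells_per_well")
  expect_error(synthetic_config(intensity_scale = -1), "intensity_scale")
  expect_error(synthetic_config(genotypes = c(A = "x")), "WT and a KO")
  expect_error(generate_growth_tracks(synthetic_config(), times = c(1, 1, 2, 3)),
               "strictly increasing")
})

test_that("planted labels are sound and disjoint; zero effect plants nothing", {
  cfg <- recovery_config(seed = 103)
  out <- generate_feature_matrix(cfg)
  truth <- out$truth
  for (tr in names(truth$affected_features)) {
    lab <- truth$dependency_labels[[tr]]
    aff <- truth$affected_features[[tr]]
    expect_setequal(names(lab)[lab != "null"], aff)
    expect_equal(sum(lab == "dependent") + sum(lab == "independent"),
                 length(aff))
    # shifted features really differ between treated-WT and vehicle-WT wells
    p <- out$profiles
    wt_treat <- p$Metadata_genotype == "WT" & p$Metadata_treatment == tr
    wt_veh <- p$Metadata_genotype == "WT" & p$Metadata_treatment == "DMSO"
    gaps <- vapply(feature_columns(p), function(f) {
      abs(median(p[[f]][wt_treat]) - median(p[[f]][wt_veh]))
    }, numeric(1))
    expect_gt(min(gaps[aff]), max(1, median(gaps[lab == "null"])))
  }

  null_cfg <- recovery_config(seed = 104, effect = 0)
  null_truth <- generate_feature_matrix(null_cfg)$truth
  expect_true(all(lengths(null_truth$affected_features) == 0))
})

test_that("KO wells carry the shift only on independent features", {
  cfg <- recovery_config(seed = 105, n_wells = 12, effect = 8)
  out <- generate_feature_matrix(cfg)
  p <- out$profiles
  lab <- out$truth$dependency_labels[["TEADi_sel"]]
  ko_treat <- p$Metadata_genotype == "YAP_KO" & p$Metadata_treatment == "TEADi_sel"
  ko_veh <- p$Metadata_genotype == "YAP_KO" & p$Metadata_treatment == "DMSO"
  gaps <- vapply(feature_columns(p), function(f) {
    abs(median(p[[f]][ko_treat]) - median(p[[f]][ko_veh]))
  }, numeric(1))
  expect_gt(min(gaps[lab == "independent"]), 2)
  expect_lt(max(gaps[lab == "dependent"]), 2)
})

test_that("cell table has positive intensities and recoverable ratio targets", {
  cfg <- synthetic_config(seed = 106, cells_per_well = 200,
                          n_replicate_wells = 2, outlier_well_rate = 0)
  out <- generate_cell_table(cfg)
  cells <- out$cells
  expect_true(all(cells$nuclear_intensity > 0))
  expect_true(all(cells$cytoplasmic_intensity > 0))
  expect_true(all(cells$contact_percent >= 0 & cells$contact_percent <= 100))
  # per-well median ratios track the planted targets (log-normal cell noise
  # has median 1)
  wkey <- paste(cells$plate, cells$well, sep = ":")
  med <- tapply(cells$nuclear_intensity / cells$cytoplasmic_intensity,
                wkey, median)
  target <- out$truth$well_target_ratio[names(med)]
  expect_lt(max(abs(med / target - 1)), 0.15)
})

test_that("growth tracks are exact logistic curves when noiseless", {
  cfg <- synthetic_config(seed = 107, growth_noise_sd = 0, spike_rate = 0,
                          n_replicate_wells = 2)
  out <- generate_growth_tracks(cfg, mode = "confluency")
  tr <- out$tracks
  for (w in unique(tr$well)[1:5]) {
    p <- out$truth$true_growth[[w]]
    sub <- tr[tr$well == w, ]
    expect_equal(sub$area,
                 p["L"] / (1 + exp(-p["k"] * (sub$time_h - p["t0"]))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # spheroid grids always contain both anchors
  sph <- generate_growth_tracks(cfg, mode = "spheroid")$tracks
  expect_true(all(c(24, 168) %in% sph$time_h))
})

test_that("injected spikes are recorded in the truth object and vice versa", {
  cfg <- synthetic_config(seed = 108, growth_noise_sd = 0, spike_rate = 0.05,
                          n_replicate_wells = 3)
  out <- generate_growth_tracks(cfg, mode = "spheroid")
  spikes <- out$truth$outlier_timepoints
  expect_gt(nrow(spikes), 0)
  for (i in seq_len(nrow(spikes))) {
    w <- spikes$well[i]
    tt <- spikes$time_h[i]
    p <- out$truth$true_growth[[w]]
    expected <- 3 * p["L"] / (1 + exp(-p["k"] * (tt - p["t0"])))
    got <- out$tracks$area[out$tracks$well == w & out$tracks$time_h == tt]
    expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("generate-and-refit recovers the planted logistic rate", {
  cfg <- synthetic_config(seed = 109, growth_noise_sd = 0, spike_rate = 0,
                          n_replicate_wells = 2,
                          growth_params = data.frame(
                            genotype = c("WT", "YAP_KO"),
                            L = c(100, 100), k = c(0.1, 0.1), t0 = c(36, 36)))
  out <- generate_growth_tracks(cfg, mode = "confluency")
  veh <- out$tracks[out$tracks$treatment == "DMSO" &
                      out$tracks$genotype == "WT", ]
  w <- veh[veh$well == veh$well[1], ]
  fit <- fit_logistic(w$time_h, w$area)
  expect_equal(fit$k, 0.1, tolerance = 1e-3)
})
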