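# Shared fixtures and independent oracles.

# Build a well-profile table from a numeric matrix (wells x features).
make_profiles <- function(x, genotype = "WT", treatment = "DMSO",
                          concentration = 0, replicate = NULL,
                          plate = "P1", family = "vehicle") {
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("Ftr_%03d", seq_len(ncol(x)))
  meta <- data.frame(
    Metadata_plate = rep_len(plate, n),
    Metadata_well = sprintf("W%03d", seq_len(n)),
    Metadata_genotype = rep_len(genotype, n),
    Metadata_treatment = rep_len(treatment, n),
    Metadata_family = rep_len(family, n),
    Metadata_concentration = rep_len(concentration, n),
    Metadata_replicate = if (is.null(replicate)) seq_len(n) else rep_len(replicate, n),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(x))
}

# Independent sort-based median and raw MAD (no calls into the package or
# stats::median), used as the brute-force oracle for the modified Z-prime.
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

sort_mad <- function(x) sort_median(abs(x - sort_median(x)))

brute_z_prime <- function(treat, control) {
  mt <- sort_median(treat)
  mc <- sort_median(control)
  delta <- abs(mt - mc)
  if (delta == 0) return(NA_real_)
  1 - (sort_mad(treat) + sort_mad(control)) / delta
}

# Double-loop correlation-distance oracle.
brute_distance_matrix <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - cor(x[i, ], x[j, ])
    }
  }
  d
}

# Small config used by the simulation-heavy tests: one treatment at one dose,
# planted effect in control-MAD units, no gross outlier wells.
recovery_config <- function(seed, n_wells = 8, effect = 6, n_features = 40) {
  synthetic_config(
    seed = seed,
    n_features = n_features, n_blocks = 8, block_rho = 0.3,
    treatments = data.frame(label = "TEADi_sel", family = "selective_TEAD",
                            concentrations = I(list(10)),
                            stringsAsFactors = FALSE),
    n_replicate_wells = n_wells,
    effect_size = effect,
    affected_fraction = 0.3, dependent_fraction = 0.5,
    outlier_well_rate = 0)
}

# Group-mean uniformity difference between two well sets, computed directly
# from a distance matrix (test-side statistic for permutation checks).
uniformity_stat <- function(d, idx_a, idx_b) {
  mean_unif <- function(idx) {
    mean(vapply(idx, function(i) 1 - mean(d[i, setdiff(idx, i)]), numeric(1)))
  }
  mean_unif(idx_a) - mean_unif(idx_b)
}
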