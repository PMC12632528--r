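# Shared fixture builders and independent oracles. Fixtures are built in
# code; nothing is read from disk except round-trip temp files.

# minimal design: g genotypes x r replicates x timepoints x (treated, vehicle)
toy_design <- function(n_knockouts = 1, n_controls = 1, n_replicates = 4,
                       timepoints = 240, donors = "d1", assay = "global",
                       ...) {
  generate_design(n_knockouts, n_controls, n_replicates, timepoints,
                  include_vehicle = TRUE, donors = donors, assay = assay, ...)
}

# hand-built intensity matrix from a plain numeric matrix
toy_matrix <- function(values, scale = "log2") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
  }
  intensity_matrix(values, scale = scale)
}

# a kinase-substrate map with n kinases x m substrates, disjoint
toy_ks_map <- function(n_kinases = 5, n_substrates = 8) {
  stats::setNames(lapply(seq_len(n_kinases), function(i) {
    sprintf("K%02dSUB%02d_S%d", i, seq_len(n_substrates), 100 + seq_len(n_substrates))
  }), sprintf("KIN%02d", seq_len(n_kinases)))
}

# standard simulated phospho dataset used across impute/ksea tests
simulate_toy <- function(seed, design = NULL, n_features = 300,
                         induced = character(), induced_effect = 2,
                         kinases = numeric(), ks_map = NULL,
                         ablation = numeric(), noise = 0.5, donor = 0.5,
                         ...) {
  if (is.null(design)) design <- toy_design(assay = "phospho")
  induced_set <- stats::setNames(rep(induced_effect, length(induced)), induced)
  truth <- ground_truth(induced_set = induced_set, active_kinases = kinases,
                        ablation_map = ablation, noise_sigma = noise,
                        donor_sigma = donor, seed = seed, ...)
  sim <- simulate_dataset(design, truth, n_features = n_features,
                          ks_map = ks_map)
  sim$design <- design
  sim
}

# ---- independent oracles ---------------------------------------------------

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n / i * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# pooled two-sample t by direct formula evaluation
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# exhaustive kNN imputation: enumerate every candidate pair, rms distance
# over mutually observed samples, candidates need >= min_shared shared and
# an observed value in the gap's sample
knn_oracle <- function(values, k, min_shared = 3) {
  out <- values
  for (g in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (!is.na(values[g, j])) next
      cand <- data.frame(idx = integer(), dist = numeric())
      for (h in seq_len(nrow(values))) {
        if (h == g || is.na(values[h, j])) next
        shared <- which(!is.na(values[g, ]) & !is.na(values[h, ]))
        if (length(shared) < min_shared) next
        d <- sqrt(mean((values[g, shared] - values[h, shared])^2))
        cand <- rbind(cand, data.frame(idx = h, dist = d))
      }
      if (!nrow(cand)) next
      cand <- cand[order(cand$dist), , drop = FALSE]
      use <- cand$idx[seq_len(min(k, nrow(cand)))]
      out[g, j] <- mean(values[use, j])
    }
  }
  out
}

expect_no_change_observed <- function(before, after) {
  obs <- !is.na(before$values)
  expect_identical(before$values[obs], after$values[obs])
}
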