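#' Ground-truth parameter set for the synthetic-data generator
#'
#' Collects every generative assumption the simulator makes: which proteins
#' are stimulation-induced (the "ISG" analog) and by how much, which kinases
#' are activated and the log2 effect applied to their substrates, how each
#' knockout genotype ablates those pathway effects, donor and residual noise
#' magnitudes, and the missingness mechanism parameters.
#'
#' @param induced_set Named numeric vector: protein id -> log2 induction
#'   effect in treated samples at timepoints >= `induction_onset`.
#' @param active_kinases Named numeric vector: kinase -> log2 effect applied
#'   to that kinase's substrate sites in all treated samples.
#' @param ablation_map Named numeric vector in \[0, 1\]: genotype ->
#'   multiplier on all pathway effects (0 = full ablation). Genotypes absent
#'   from the map keep the full effect (multiplier 1).
#' @param donor_sigma SD of the additive per-(donor, feature) log2 offset.
#' @param noise_sigma SD of the residual per-measurement log2 noise.
#' @param mar_rate Probability that an entry is removed uniformly at random.
#' @param mnar_midpoint Log2 intensity at which the detection probability is
#'   0.5 (the limit-of-detection midpoint).
#' @param mnar_slope Steepness of the logistic dropout curve; dropout
#'   probability is `plogis(-(x - midpoint) * slope)` at log2 intensity `x`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param induction_onset Minutes; induced-protein effects apply only at
#'   timepoints at or after this onset (protein synthesis is slow), whereas
#'   kinase effects apply at every treated timepoint (phosphorylation is
#'   fast).
#' @param baseline_mean,baseline_sd Mean and SD of per-feature baseline log2
#'   intensities.
#' @param ambiguous_fraction Fraction of phosphosites with ambiguous
#'   localization; their probabilities are drawn Beta(2, 2), confident sites
#'   Beta(9, 1).
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(induced_set = numeric(),
                         active_kinases = numeric(),
                         ablation_map = numeric(),
                         donor_sigma = 0.5,
                         noise_sigma = 0.5,
                         mar_rate = 0.05,
                         mnar_midpoint = 16,
                         mnar_slope = 3,
                         seed = 1L,
                         induction_onset = 240,
                         baseline_mean = 20,
                         baseline_sd = 2,
                         ambiguous_fraction = 0.2) {
  if (length(ablation_map) && any(ablation_map < 0 | ablation_map > 1)) {
    stop("ablation multipliers must lie in [0, 1]", call. = FALSE)
  }
  if (mar_rate < 0 || mar_rate > 1) stop("mar_rate must lie in [0, 1]", call. = FALSE)
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("ambiguous_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!all(is.finite(induced_set)) || !all(is.finite(active_kinases))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  structure(list(induced_set = induced_set,
                 active_kinases = active_kinases,
                 ablation_map = ablation_map,
                 donor_sigma = donor_sigma,
                 noise_sigma = noise_sigma,
                 mar_rate = mar_rate,
                 mnar_midpoint = mnar_midpoint,
                 mnar_slope = mnar_slope,
                 seed = as.integer(seed),
                 induction_onset = induction_onset,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 ambiguous_fraction = ambiguous_fraction),
            class = "ground_truth")
}

# ablation multiplier for a genotype; unlisted genotypes keep the full effect
ablation_of <- function(truth, genotype) {
  out <- rep(1, length(genotype))
  hit <- genotype %in% names(truth$ablation_map)
  out[hit] <- truth$ablation_map[genotype[hit]]
  out
}

#' Simulate a long-format DIA report with known effect structure
#'
#' Generates linear-scale precursor intensities
#' `2^(baseline + treated * effect * ablation + donor + noise)` for every
#' (feature, sample) pair of the design. Substrate sites of active kinases
#' receive the kinase effect in every treated sample; proteins in the induced
#' set receive their effect in treated samples at timepoints at or after the
#' induction onset; both are scaled by the genotype's ablation multiplier.
#' Localization probabilities are drawn per site, a configurable fraction
#' from an ambiguous Beta(2, 2) and the rest from a confident Beta(9, 1).
#' Deterministic given `truth$seed`.
#'
#' @param design A design manifest (see [generate_design()]).
#' @param truth A [ground_truth()] object.
#' @param n_features Total number of quantified features (>= substrates +
#'   induced proteins).
#' @param ks_map Optional named list: kinase -> character vector of substrate
#'   site keys (`PROTEIN_[STY]POS`); every named active kinase must appear in
#'   it. Substrate sites become features of the simulated report.
#' @return A list with `report` (long-format data.frame: `sample_id`,
#'   `protein_group`, `stripped_sequence`, `modified_sequence`, `site_key`,
#'   `localization_probability`, `intensity`, `is_phospho`), `truth` (the
#'   input truth augmented with per-feature baselines and true effects), and
#'   `matrix` (the complete, gap-free `intensity_matrix` on linear scale).
#' @export
simulate_dataset <- function(design, truth, n_features, ks_map = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  assay <- design$assay[1L]
  set.seed(truth$seed)

  substrate_sites <- unique(unlist(ks_map, use.names = FALSE))
  if (length(truth$active_kinases)) {
    unknown <- setdiff(names(truth$active_kinases), names(ks_map))
    if (length(unknown)) {
      stop("active kinases absent from kinase-substrate map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  induced_proteins <- names(truth$induced_set)

  n_named <- length(substrate_sites) + length(induced_proteins)
  if (n_features < n_named) {
    stop(sprintf("n_features (%d) smaller than substrates + induced proteins (%d)",
                 n_features, n_named), call. = FALSE)
  }

  # feature universe: substrate sites, sites on induced proteins, background
  n_background <- n_features - n_named
  if (assay == "phospho") {
    bg_sites <- if (n_background)
      sprintf("BG%04d_S%d", seq_len(n_background), sample(10:999, n_background, replace = TRUE))
    else character()
    induced_feats <- if (length(induced_proteins))
      paste0(induced_proteins, "_S", sample(10:999, length(induced_proteins), replace = TRUE))
    else character()
    feature_id <- c(substrate_sites, induced_feats, bg_sites)
    protein <- sub("_[STY][0-9]+$", "", feature_id)
  } else {
    bg <- if (n_background) sprintf("BGP%04d", seq_len(n_background)) else character()
    feature_id <- c(substrate_sites, induced_proteins, bg)
    protein <- ifelse(grepl("_[STY][0-9]+$", feature_id),
                      sub("_[STY][0-9]+$", "", feature_id), feature_id)
  }
  if (anyDuplicated(feature_id)) {
    feature_id <- make.unique(feature_id, sep = "x")
  }
  nf <- length(feature_id)
  ns <- nrow(design)

  baseline <- stats::rnorm(nf, truth$baseline_mean, truth$baseline_sd)

  # per-feature treatment effects, split by response speed
  kinase_effect <- numeric(nf)
  if (length(truth$active_kinases)) {
    for (k in names(truth$active_kinases)) {
      idx <- match(intersect(ks_map[[k]], feature_id), feature_id)
      kinase_effect[idx] <- kinase_effect[idx] + truth$active_kinases[[k]]
    }
  }
  induced_effect <- numeric(nf)
  if (length(induced_proteins)) {
    hit <- protein %in% induced_proteins
    induced_effect[hit] <- truth$induced_set[protein[hit]]
  }

  donors <- unique(design$donor)
  donor_offsets <- matrix(stats::rnorm(nf * length(donors), 0, truth$donor_sigma),
                          nrow = nf, dimnames = list(feature_id, donors))

  treated <- design$treatment != "vehicle"
  late <- design$timepoint >= truth$induction_onset
  ablate <- ablation_of(truth, design$genotype)

  effect_matrix <- outer(kinase_effect, as.numeric(treated)) +
    outer(induced_effect, as.numeric(treated & late))
  effect_matrix <- sweep(effect_matrix, 2, ablate, `*`)

  log2_values <- matrix(baseline, nf, ns) +
    effect_matrix +
    donor_offsets[, design$donor, drop = FALSE] +
    matrix(stats::rnorm(nf * ns, 0, truth$noise_sigma), nf, ns)
  dimnames(log2_values) <- list(feature_id, design$sample_id)

  is_phospho <- grepl("_[STY][0-9]+$", feature_id)
  loc_prob <- rep(NA_real_, nf)
  if (any(is_phospho)) {
    np <- sum(is_phospho)
    ambiguous <- stats::runif(np) < truth$ambiguous_fraction
    p <- numeric(np)
    p[ambiguous] <- stats::rbeta(sum(ambiguous), 2, 2)
    p[!ambiguous] <- stats::rbeta(sum(!ambiguous), 9, 1)
    loc_prob[is_phospho] <- p
  }

  feature_info <- data.frame(
    feature_id = feature_id,
    protein = protein,
    is_phospho = is_phospho,
    localization_probability = loc_prob,
    baseline = baseline,
    kinase_effect = kinase_effect,
    induced_effect = induced_effect,
    stringsAsFactors = FALSE)

  report <- data.frame(
    sample_id = rep(design$sample_id, each = nf),
    protein_group = rep(protein, ns),
    stripped_sequence = rep(paste0("PEP", feature_id), ns),
    modified_sequence = rep(ifelse(is_phospho,
                                   paste0("PEP", feature_id, "[ph]"),
                                   paste0("PEP", feature_id)), ns),
    site_key = rep(ifelse(is_phospho, feature_id, NA_character_), ns),
    localization_probability = rep(loc_prob, ns),
    intensity = as.vector(2^log2_values),
    is_phospho = rep(is_phospho, ns),
    stringsAsFactors = FALSE)

  mat <- intensity_matrix(2^log2_values, scale = "linear",
                          feature_info = feature_info)
  truth$feature_info <- feature_info
  truth$log2_matrix <- log2_values
  list(report = report, truth = truth, matrix = mat)
}

#' Remove entries from a matrix by MNAR and MAR mechanisms
#'
#' Applies intensity-dependent (missing-not-at-random) dropout with
#' probability `plogis(-(x - midpoint) * slope)` at log2 intensity `x`, then
#' uniform missing-at-random dropout at `mar_rate`, and returns both the
#' gapped matrix and the true mechanism label of every removed entry.
#'
#' When a design manifest is supplied, MNAR dropout is decided once per
#' (feature, condition) replicate block, from the logistic detection
#' probability evaluated at the block-mean log2 intensity, so a feature below
#' the detection limit in a condition disappears from all of that condition's
#' replicates together — the way limit-of-detection dropout behaves in DIA
#' data. Without a design, entries drop independently.
#'
#' @param mat An `intensity_matrix` (either scale; probabilities are always
#'   evaluated on log2 intensities).
#' @param truth A [ground_truth()] carrying `mar_rate`, `mnar_midpoint`,
#'   `mnar_slope` and `seed`.
#' @param design Optional design manifest enabling block-correlated MNAR.
#' @return A list with `matrix` (same scale, gaps as `NA`) and `labels`
#'   (character matrix over the same dimensions with entries `"observed"`,
#'   `"MAR"`, `"MNAR"`).
#' @export
apply_missingness <- function(mat, truth, design = NULL) {
  stopifnot(inherits(mat, "intensity_matrix"), inherits(truth, "ground_truth"))
  x <- if (mat$scale == "log2") mat$values else log2(mat$values)
  set.seed(truth$seed + 104729L)  # offset so gap pattern is independent of intensities

  drop_mnar <- matrix(FALSE, nrow(x), ncol(x))
  if (!is.null(design)) {
    d <- design_for_columns(mat, design)
    cond <- condition_key(d)
    for (cc in unique(cond)) {
      cols <- which(cond == cc)
      block_mean <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
      p <- stats::plogis(-(block_mean - truth$mnar_midpoint) * truth$mnar_slope)
      dropped <- stats::runif(nrow(x)) < p
      drop_mnar[dropped, cols] <- TRUE
    }
  } else {
    p <- stats::plogis(-(x - truth$mnar_midpoint) * truth$mnar_slope)
    drop_mnar <- matrix(stats::runif(length(x)) < p, nrow(x), ncol(x))
  }
  drop_mnar[is.na(x)] <- FALSE

  drop_mar <- matrix(stats::runif(length(x)) < truth$mar_rate, nrow(x), ncol(x))
  drop_mar[is.na(x) | drop_mnar] <- FALSE

  labels <- matrix("observed", nrow(x), ncol(x),
                   dimnames = dimnames(x))
  labels[drop_mnar] <- "MNAR"
  labels[drop_mar] <- "MAR"

  values <- mat$values
  values[drop_mnar | drop_mar] <- NA_real_
  list(matrix = im_replace(mat, values), labels = labels)
}
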