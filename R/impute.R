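#' Classify missing entries as MAR or MNAR
#'
#' Applies the partially-observed-value / missing-in-entire-condition
#' convention: within each (feature, condition) replicate block, a gap is
#' missing-at-random (MAR) if at least one replicate of the block was
#' observed, and missing-not-at-random (MNAR) if the entire block is missing
#' — the signature of a feature below the detection limit in that condition.
#'
#' @param mat A log2-scale `intensity_matrix`, post replicate filtering.
#' @param design The design manifest.
#' @return A character matrix over the matrix dimensions with entries
#'   `"observed"`, `"MAR"`, `"MNAR"`.
#' @export
classify_missingness <- function(mat, design) {
  stopifnot(inherits(mat, "intensity_matrix"))
  d <- design_for_columns(mat, design)
  cond <- condition_key(d)
  v <- mat$values
  labels <- matrix("observed", nrow(v), ncol(v), dimnames = dimnames(v))
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    block <- v[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(block))
    gap <- is.na(block)
    mech <- ifelse(n_obs > 0, "MAR", "MNAR")
    for (jj in seq_along(cols)) {
      labels[gap[, jj], cols[jj]] <- mech[gap[, jj]]
    }
  }
  labels
}

# mask helper: logical gap matrix for one mechanism
mask_for <- function(labels, mechanism) labels == mechanism

#' k-nearest-neighbour imputation of MAR gaps
#'
#' For each feature with MAR gaps, the k nearest features are found by
#' root-mean-square Euclidean distance over mutually observed samples
#' (candidates must share at least `min_shared` observed samples and have an
#' observed value in the gap's sample). The imputed value is the mean of the
#' neighbours' observed values in that sample. Observed entries are never
#' touched. Gaps with no eligible neighbour are left missing with a warning.
#'
#' @param mat A log2-scale `intensity_matrix`.
#' @param mask Logical matrix marking the gaps to impute (e.g. the MAR
#'   entries of [classify_missingness()]); defaults to all missing entries.
#' @param k Number of neighbours.
#' @param min_shared Minimum mutually observed samples for a candidate.
#' @return The matrix with masked gaps filled.
#' @export
impute_knn <- function(mat, mask = NULL, k = 10L, min_shared = 3L) {
  stopifnot(inherits(mat, "intensity_matrix"), k >= 1)
  v <- mat$values
  if (is.null(mask)) mask <- is.na(v)
  mask <- mask & is.na(v)
  if (!any(mask)) return(mat)
  obs <- !is.na(v)
  todo <- which(rowSums(mask) > 0)
  n_unfilled <- 0L
  for (g in todo) {
    shared <- obs %*% obs[g, ]  # per-feature count of mutually observed samples
    cand <- which(shared >= min_shared)
    cand <- setdiff(cand, g)
    if (!length(cand)) { n_unfilled <- n_unfilled + sum(mask[g, ]); next }
    diffs <- sweep(v[cand, , drop = FALSE], 2, v[g, ], `-`)
    dist <- sqrt(rowMeans(diffs^2, na.rm = TRUE))
    ord <- cand[order(dist)]
    for (j in which(mask[g, ])) {
      donors <- ord[obs[ord, j]]
      if (!length(donors)) { n_unfilled <- n_unfilled + 1L; next }
      use <- donors[seq_len(min(k, length(donors)))]
      if (length(use) < k) {
        warning("feature ", rownames(v)[g], ": only ", length(use),
                " neighbour(s) available (k = ", k, ")", call. = FALSE)
      }
      v[g, j] <- mean(v[use, j])
    }
  }
  if (n_unfilled) {
    warning(n_unfilled, " gap(s) left missing: no eligible neighbour", call. = FALSE)
  }
  im_replace(mat, v)
}

#' Structured least-squares-style imputation of MAR gaps
#'
#' Deterministic replicate-structure imputation for phosphoproteomics: a gap
#' at (feature g, sample j) is filled with the mean of g's observed
#' replicates in j's condition plus a sample offset. The offset of sample j
#' is the median, over features fully observed in that condition, of
#' (value in j − mean of the feature's other replicates), i.e. the typical
#' deviation of sample j from its replicates. Conditions with a single
#' sample get offset 0 with a warning.
#'
#' @param mat A log2-scale `intensity_matrix`.
#' @param mask Logical gap mask (defaults to all missing entries).
#' @param design The design manifest defining replicate blocks.
#' @return The matrix with masked gaps filled where a replicate mean exists;
#'   gaps in fully missing blocks are left missing.
#' @export
impute_slsa <- function(mat, mask = NULL, design) {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- mat$values
  if (is.null(mask)) mask <- is.na(v)
  mask <- mask & is.na(v)
  if (!any(mask)) return(mat)
  d <- design_for_columns(mat, design)
  cond <- condition_key(d)
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    block <- v[, cols, drop = FALSE]
    gaps <- mask[, cols, drop = FALSE]
    if (!any(gaps)) next
    if (length(cols) == 1) {
      warning("condition ", cc, " has a single sample; offset 0", call. = FALSE)
    }
    full <- rowSums(is.na(block)) == 0
    for (jj in seq_along(cols)) {
      rows <- which(gaps[, jj])
      if (!length(rows)) next
      offset <- 0
      if (length(cols) > 1 && sum(full) > 0) {
        others <- rowMeans(block[full, -jj, drop = FALSE])
        offset <- stats::median(block[full, jj] - others)
      }
      rep_mean <- rowMeans(block[rows, -jj, drop = FALSE], na.rm = TRUE)
      fill <- rep_mean + offset
      ok <- is.finite(fill)
      v[rows[ok], cols[jj]] <- fill[ok]
    }
  }
  im_replace(mat, v)
}

#' Downshift-sampling imputation of MNAR gaps
#'
#' Fills gaps left by below-detection-limit features by drawing from a
#' normal distribution shifted below, and narrower than, the observed
#' distribution of each sample column: `Normal(mu - shift * sigma,
#' (width * sigma)^2)` with `mu`, `sigma` the observed column mean and SD.
#' Columns with fewer than two observed values fall back to the global mean
#' and SD with a warning. Deterministic given `seed`.
#'
#' @param mat A log2-scale `intensity_matrix`.
#' @param mask Logical gap mask (defaults to all missing entries).
#' @param shift Downshift in column SD units.
#' @param width Width of the imputation distribution in column SD units.
#' @param seed Integer seed.
#' @return The matrix with masked gaps filled.
#' @export
impute_downshift <- function(mat, mask = NULL, shift = 1.8, width = 0.3,
                             seed = 1L) {
  stopifnot(inherits(mat, "intensity_matrix"), width >= 0)
  v <- mat$values
  if (is.null(mask)) mask <- is.na(v)
  mask <- mask & is.na(v)
  if (!any(mask)) return(mat)
  set.seed(as.integer(seed))
  global_mu <- mean(v, na.rm = TRUE)
  global_sd <- stats::sd(as.vector(v), na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    rows <- which(mask[, j])
    if (!length(rows)) next
    col_obs <- v[!is.na(v[, j]), j]
    if (length(col_obs) < 2) {
      warning("sample ", colnames(v)[j],
              " has < 2 observed values; using global mean and SD", call. = FALSE)
      mu <- global_mu; sigma <- global_sd
    } else {
      mu <- mean(col_obs); sigma <- stats::sd(col_obs)
    }
    v[rows, j] <- stats::rnorm(length(rows), mu - shift * sigma, width * sigma)
  }
  im_replace(mat, v)
}

#' Mechanism-matched mixed imputation
#'
#' The full imputation stage: classify every gap as MAR or MNAR by the
#' replicate-block rule, fill MAR gaps with k-NN (global proteomics) or SLSA
#' (phosphoproteomics), then fill MNAR gaps with downshift sampling. MAR gaps
#' the primary method cannot fill (no eligible neighbour, no observed
#' replicate) also fall back to downshift so the result is complete.
#'
#' @param mat A log2-scale `intensity_matrix`, post replicate filtering.
#' @param design The design manifest.
#' @param mode `"global"` (k-NN for MAR) or `"phospho"` (SLSA for MAR).
#' @param k Neighbours for k-NN.
#' @param shift,width Downshift parameters.
#' @param seed Integer seed for the downshift draws.
#' @return A list with `matrix` (gap-free `intensity_matrix`) and `labels`
#'   (the mechanism classification used).
#' @export
impute_mixed <- function(mat, design, mode = c("phospho", "global"),
                         k = 10L, shift = 1.8, width = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "intensity_matrix"))
  labels <- classify_missingness(mat, design)
  mar <- mask_for(labels, "MAR")
  out <- if (mode == "global") {
    impute_knn(mat, mask = mar, k = k)
  } else {
    impute_slsa(mat, mask = mar, design = design)
  }
  # MNAR gaps plus any MAR leftovers go through downshift
  out <- impute_downshift(out, mask = is.na(out$values), shift = shift,
                          width = width, seed = seed)
  list(matrix = out, labels = labels)
}
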