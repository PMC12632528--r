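#' Collapse precursor records to phosphosites
#'
#' Reduces a precursor-level report to one record per (sample, site): the
#' collapsed intensity is the maximum over contributing precursors and the
#' collapsed localization probability is likewise the maximum. Both rules are
#' order-independent. Non-phospho records pass through unchanged.
#'
#' @param report A long-report data.frame.
#' @return A site-level long report.
#' @export
collapse_to_sites <- function(report) {
  phospho <- report[report$is_phospho, , drop = FALSE]
  other <- report[!report$is_phospho, , drop = FALSE]
  if (!nrow(phospho)) return(report)
  if (any(is.na(phospho$site_key))) {
    stop("phospho record without site_key", call. = FALSE)
  }
  key <- paste(phospho$sample_id, phospho$site_key, sep = "\r")
  first <- !duplicated(key)
  out <- phospho[first, , drop = FALSE]
  grp <- match(key, key[first])
  out$intensity <- vapply(split(phospho$intensity, grp), max, numeric(1))
  out$localization_probability <-
    vapply(split(phospho$localization_probability, grp),
           function(p) if (all(is.na(p))) NA_real_ else max(p, na.rm = TRUE),
           numeric(1))
  out <- rbind(out, other)
  rownames(out) <- NULL
  out
}

#' Keep Class-I phosphosites
#'
#' Retains site-level records whose localization probability is strictly
#' greater than the threshold (default 0.75, the Class-I convention). The
#' inequality is strict: a probability of exactly 0.75 is dropped. Many tools
#' use `>=`; the strict boundary is deliberate here.
#'
#' @param report A site-level long report.
#' @param threshold Localization-probability cutoff.
#' @return The filtered report (non-phospho records are kept).
#' @export
filter_class1 <- function(report, threshold = 0.75) {
  keep <- !report$is_phospho |
    (!is.na(report$localization_probability) &
       report$localization_probability > threshold)
  out <- report[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# parse a replicate-presence rule: c(k, n), "3:4", or a fraction in (0, 1]
parse_min_present <- function(min_present) {
  if (is.character(min_present)) {
    parts <- as.integer(strsplit(min_present, ":", fixed = TRUE)[[1L]])
    return(list(k = parts[[1L]], n = parts[[2L]], fraction = NULL))
  }
  if (length(min_present) == 2) {
    return(list(k = as.integer(min_present[[1L]]), n = as.integer(min_present[[2L]]),
                fraction = NULL))
  }
  if (length(min_present) == 1 && min_present > 0 && min_present <= 1) {
    return(list(k = NULL, n = NULL, fraction = as.numeric(min_present)))
  }
  stop("min_present must be c(k, n), \"k:n\", or a fraction in (0, 1]", call. = FALSE)
}

#' Filter features by replicate presence
#'
#' Keeps a feature if, in at least one condition (genotype x treatment x
#' dose x timepoint x cell type), at least `k` of that condition's replicates
#' were quantified — e.g. 3 of 4, or 2 of 3 for macrophage designs. A
#' fractional rule applies `ceiling(fraction * n_condition)` per condition.
#'
#' @param mat An `intensity_matrix`.
#' @param design The design manifest covering the matrix columns.
#' @param min_present `c(k, n)`, `"k:n"`, or a fraction.
#' @return The filtered `intensity_matrix` (a row subset; rerunning is a
#'   no-op).
#' @export
filter_by_replicates <- function(mat, design, min_present = c(3L, 4L)) {
  stopifnot(inherits(mat, "intensity_matrix"))
  rule <- parse_min_present(min_present)
  d <- design_for_columns(mat, design)
  cond <- condition_key(d)
  if (any(table(cond) == 0)) stop("condition with zero samples", call. = FALSE)
  observed <- !is.na(mat$values)
  keep <- rep(FALSE, nrow(mat$values))
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    k <- if (is.null(rule$fraction)) rule$k else ceiling(rule$fraction * length(cols))
    keep <- keep | rowSums(observed[, cols, drop = FALSE]) >= k
  }
  im_subset_rows(mat, keep)
}

im_subset_rows <- function(mat, keep) {
  fi <- mat$feature_info
  if (!is.null(fi)) fi <- fi[keep, , drop = FALSE]
  intensity_matrix(mat$values[keep, , drop = FALSE], scale = mat$scale,
                   feature_info = fi)
}

#' Log2-transform and median-center an intensity matrix
#'
#' Transforms linear intensities to log2 and shifts each sample column so the
#' median of its observed values is zero. Missing entries are untouched.
#' Idempotent: applying it to an already normalized matrix changes nothing.
#'
#' @param mat An `intensity_matrix` on linear or log2 scale.
#' @return A log2-scale, median-centered `intensity_matrix`.
#' @export
normalize_intensity <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- to_log2(mat)$values
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    if (all(is.na(col))) {
      warning("sample ", colnames(v)[j], " has no observed values; left unchanged")
      next
    }
    v[, j] <- col - stats::median(col, na.rm = TRUE)
  }
  im_replace(mat, v, scale = "log2")
}

#' Quality-control metrics for a run
#'
#' Computes the standard depth/precision readouts of a phosphoproteomics
#' experiment:
#' \describe{
#'   \item{purity}{per sample, the fraction of phospho precursors among all
#'     quantified precursors (identification-count based).}
#'   \item{localized_site_count}{per sample, the number of distinct Class-I
#'     sites (localization probability > `class1_threshold`).}
#'   \item{cv}{per feature and condition, the coefficient of variation
#'     (sd/mean) of linear-scale replicate intensities; scale-free.}
#'   \item{replicate_correlation}{Pearson r of log2 intensities for every
#'     within-condition sample pair, over mutually observed features.}
#'   \item{linearity}{per feature, Pearson r of linear intensity against
#'     `cell_input`, for features observed at >= 3 input levels; only
#'     computed when the design carries `cell_input`.}
#' }
#'
#' @param report A long report (precursor- or site-level) for the count-based
#'   metrics.
#' @param mat An `intensity_matrix` for the quantitative metrics.
#' @param design The design manifest.
#' @param class1_threshold Localization cutoff for the site counts.
#' @param linearity Set `TRUE` to request input-linearity; errors if the
#'   design has no usable `cell_input`.
#' @return A list of class `qc_bundle` with data.frames `purity`,
#'   `localized_site_count`, `cv`, `replicate_correlation` and (optionally)
#'   `linearity`.
#' @export
qc_metrics <- function(report, mat, design, class1_threshold = 0.75,
                       linearity = FALSE) {
  stopifnot(inherits(mat, "intensity_matrix"))
  d <- design_for_columns(mat, design)

  purity <- do.call(rbind, lapply(split(report, report$sample_id), function(r) {
    data.frame(sample_id = r$sample_id[[1L]],
               n_precursors = nrow(r),
               purity = mean(r$is_phospho),
               stringsAsFactors = FALSE)
  }))
  rownames(purity) <- NULL

  loc <- report[report$is_phospho & !is.na(report$localization_probability) &
                  report$localization_probability > class1_threshold, , drop = FALSE]
  if (nrow(loc)) {
    site_count <- stats::aggregate(site_key ~ sample_id, data = loc,
                                   FUN = function(x) length(unique(x)))
    names(site_count)[2L] <- "localized_site_count"
  } else {
    site_count <- data.frame(sample_id = character(),
                             localized_site_count = integer(),
                             stringsAsFactors = FALSE)
  }

  lin_values <- if (mat$scale == "log2") 2^mat$values else mat$values
  cond <- condition_key(d)
  cv_rows <- lapply(unique(cond), function(cc) {
    cols <- which(cond == cc)
    if (length(cols) < 2) return(NULL)
    m <- lin_values[, cols, drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
    n_obs <- rowSums(!is.na(m))
    ok <- n_obs >= 2
    if (!any(ok)) return(NULL)
    data.frame(feature_id = rownames(m)[ok], condition = cc,
               cv = (sdv / mu)[ok], n_observed = n_obs[ok],
               stringsAsFactors = FALSE)
  })
  cv <- do.call(rbind, cv_rows)
  rownames(cv) <- NULL

  log_values <- to_log2(mat)$values
  cor_rows <- lapply(unique(cond), function(cc) {
    cols <- which(cond == cc)
    if (length(cols) < 2) return(NULL)
    pairs <- utils::combn(cols, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      both <- stats::complete.cases(log_values[, c(i, j)])
      r <- if (sum(both) >= 3)
        stats::cor(log_values[both, i], log_values[both, j]) else NA_real_
      data.frame(condition = cc,
                 sample_a = colnames(log_values)[i],
                 sample_b = colnames(log_values)[j],
                 n_shared = sum(both), pearson_r = r,
                 stringsAsFactors = FALSE)
    }))
  })
  repcor <- do.call(rbind, cor_rows)
  rownames(repcor) <- NULL

  out <- list(purity = purity, localized_site_count = site_count,
              cv = cv, replicate_correlation = repcor)

  if (linearity) {
    if (all(is.na(d$cell_input))) {
      stop("linearity requested but the design has no cell_input", call. = FALSE)
    }
    input <- d$cell_input
    lin_rows <- lapply(seq_len(nrow(lin_values)), function(i) {
      obs <- !is.na(lin_values[i, ]) & !is.na(input)
      if (length(unique(input[obs])) < 3) return(NULL)
      data.frame(feature_id = rownames(lin_values)[i],
                 n_levels = length(unique(input[obs])),
                 linearity_r = stats::cor(lin_values[i, obs], input[obs]),
                 stringsAsFactors = FALSE)
    })
    out$linearity <- do.call(rbind, lin_rows)
    rownames(out$linearity) <- NULL
  }
  structure(out, class = "qc_bundle")
}
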