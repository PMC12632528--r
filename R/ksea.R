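#' Kinase-substrate enrichment analysis (KSEA) z-scores
#'
#' For each comparison and each kinase with at least `min_substrates`
#' quantified substrate sites, computes the mean-based enrichment z-score
#' against the whole-dataset background:
#' `z = (mean(FC_substrates) - mean(FC_all)) * sqrt(m) / sd(FC_all)`
#' with `m` the number of quantified substrates. Two-sided p-values come
#' from the standard normal, with Benjamini-Hochberg correction across
#' kinases within each comparison. Substrate sites remain part of the
#' background. Kinases below the substrate minimum are omitted (reported as
#' not quantifiable via the `dropped` attribute).
#'
#' @param diff A differential table (site-level; see [differential_table()]).
#' @param ks_map Named list: kinase -> substrate site keys.
#' @param min_substrates Minimum quantified substrates per kinase.
#' @return A data.frame per (kinase, comparison): `kinase`, `comparison`,
#'   `z`, `p`, `adj_p`, `m`, `mean_substrate_fc`, `background_mean`,
#'   `background_sd`. Attribute `dropped` lists omitted kinases.
#' @export
ksea_z <- function(diff, ks_map, min_substrates = 3L) {
  stopifnot(is.list(ks_map), length(ks_map) > 0)
  dropped <- character()
  out <- lapply(split(diff, diff$comparison), function(dc) {
    fc <- dc$log2fc
    names(fc) <- dc$feature_id
    bg_mean <- mean(fc)
    bg_sd <- stats::sd(fc)
    rows <- lapply(names(ks_map), function(kin) {
      subs <- intersect(ks_map[[kin]], names(fc))
      m <- length(subs)
      if (m < min_substrates) {
        dropped <<- union(dropped, kin)
        return(NULL)
      }
      sub_mean <- mean(fc[subs])
      z <- (sub_mean - bg_mean) * sqrt(m) / bg_sd
      data.frame(kinase = kin, comparison = dc$comparison[[1L]],
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 m = m, mean_substrate_fc = sub_mean,
                 background_mean = bg_mean, background_sd = bg_sd,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) return(NULL)
    rows$adj_p <- bh_adjust(pmin(pmax(rows$p, .Machine$double.xmin), 1))
    rows[, c("kinase", "comparison", "z", "p", "adj_p", "m",
             "mean_substrate_fc", "background_mean", "background_sd")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "dropped") <- sort(dropped)
  out
}

#' Substrate coverage per kinase
#'
#' Counts, for each kinase and condition, how many of its annotated
#' substrate sites were detected, and expresses coverage relative to a
#' designated reference condition (capped at 1 when a condition exceeds the
#' reference).
#'
#' @param detections A data.frame with columns `condition` and `site_key`
#'   listing detected sites per condition (one row per detection; duplicates
#'   are fine).
#' @param ks_map Named list: kinase -> substrate site keys.
#' @param reference Reference condition label for relative coverage; `NULL`
#'   skips the relative column.
#' @return A data.frame per (kinase, condition): `kinase`, `condition`,
#'   `n_detected`, `n_annotated`, and `relative_coverage` when a reference
#'   is given.
#' @export
substrate_coverage <- function(detections, ks_map, reference = NULL) {
  stopifnot(all(c("condition", "site_key") %in% names(detections)))
  conds <- unique(detections$condition)
  if (!is.null(reference) && !reference %in% conds) {
    stop("reference condition not present: ", reference, call. = FALSE)
  }
  sites_by_cond <- lapply(split(detections$site_key, detections$condition), unique)
  out <- do.call(rbind, lapply(names(ks_map), function(kin) {
    data.frame(kinase = kin, condition = conds,
               n_detected = vapply(conds, function(cc) {
                 length(intersect(ks_map[[kin]], sites_by_cond[[cc]]))
               }, integer(1)),
               n_annotated = length(ks_map[[kin]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(reference)) {
    ref_counts <- out$n_detected[out$condition == reference]
    names(ref_counts) <- out$kinase[out$condition == reference]
    out$relative_coverage <- pmin(1, out$n_detected / ref_counts[out$kinase])
    out$relative_coverage[!is.finite(out$relative_coverage)] <- NA_real_
  }
  out
}
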