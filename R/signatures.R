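#' Derive an empirical stimulation signature from control arms
#'
#' The signature is the set of features consistently upregulated in every
#' control (scrambled) comparison: adjusted p strictly below `alpha` and
#' log2 fold change strictly above `fc_min` in each one. Derivation is
#' monotone in the thresholds (raising `alpha` or lowering `fc_min` never
#' removes a member).
#'
#' @param control_diffs A list of differential tables, one per control
#'   comparison (each covering one comparison; tables with several
#'   comparisons are split internally).
#' @param alpha Adjusted-p threshold (strict).
#' @param fc_min Log2 fold-change threshold (strict).
#' @return An object of class `signature_set`: list with `members`
#'   (character), `alpha`, `fc_min`, `provenance` (comparison keys). An
#'   empty member set triggers a warning but is returned.
#' @export
derive_signature <- function(control_diffs, alpha = 0.05, fc_min = 0.75) {
  if (is.data.frame(control_diffs)) control_diffs <- list(control_diffs)
  pieces <- unlist(lapply(control_diffs, function(d) split(d, d$comparison)),
                   recursive = FALSE)
  if (!length(pieces)) stop("need at least one control comparison", call. = FALSE)
  passing <- lapply(pieces, function(d) {
    d$feature_id[d$adj_p < alpha & d$log2fc > fc_min]
  })
  members <- Reduce(intersect, passing)
  if (!length(members)) {
    warning("signature is empty at the given thresholds", call. = FALSE)
  }
  structure(list(members = sort(members), alpha = alpha, fc_min = fc_min,
                 provenance = vapply(pieces, function(d) d$comparison[[1L]],
                                     character(1))),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d members (adj_p < %g, log2FC > %g; %d control comparisons)\n",
              length(x$members), x$alpha, x$fc_min, length(x$provenance)))
  invisible(x)
}

#' Score a perturbation against a stimulation signature
#'
#' Counts how many signature members remain significantly induced in a
#' knockout (or base-edited) comparison at the signature's own thresholds,
#' and summarizes the density shift: mean log2 fold change over members and
#' over non-members. Members never quantified in the comparison are
#' excluded from the denominators.
#'
#' @param ko_diff A differential table for one comparison (treated KO vs its
#'   vehicle).
#' @param sig A [derive_signature()] result.
#' @return A list of class `perturbation_score`: `genotype`, `comparison`,
#'   `n_significant_members`, `n_members_quantified`, `mean_member_fc`,
#'   `mean_nonmember_fc`, `member_fc` (named vector).
#' @export
score_perturbation <- function(ko_diff, sig) {
  stopifnot(inherits(sig, "signature_set"))
  if (length(unique(ko_diff$comparison)) != 1) {
    stop("score_perturbation expects a single comparison", call. = FALSE)
  }
  in_sig <- ko_diff$feature_id %in% sig$members
  members <- ko_diff[in_sig, , drop = FALSE]
  missing_members <- setdiff(sig$members, ko_diff$feature_id)
  if (length(missing_members)) {
    message(length(missing_members), " signature member(s) not quantified in ",
            ko_diff$comparison[[1L]])
  }
  sig_hit <- members$adj_p < sig$alpha & members$log2fc > sig$fc_min
  structure(list(
    genotype = ko_diff$genotype[[1L]],
    comparison = ko_diff$comparison[[1L]],
    n_significant_members = sum(sig_hit),
    n_members_quantified = nrow(members),
    mean_member_fc = mean(members$log2fc),
    mean_nonmember_fc = mean(ko_diff$log2fc[!in_sig]),
    member_fc = stats::setNames(members$log2fc, members$feature_id)),
    class = "perturbation_score")
}

#' Classify signature members by their response in a perturbation
#'
#' Partitions members into `abolished` (no longer significant and fold
#' change below `abolish_ratio` of the control's), `retained` (still
#' significant with at least `retain_ratio` of the control fold change) and
#' `attenuated` (everything else). Thresholds are package defaults exposed
#' for tuning; they encode the grey/red partition of knockout response
#' plots.
#'
#' @param ko_diff,ctrl_diff Differential tables (single comparison each) for
#'   the perturbation and its matched control arm.
#' @param sig A [derive_signature()] result.
#' @param abolish_ratio,retain_ratio Fold-change ratio cutoffs.
#' @return A data.frame per quantified member: `feature_id`, `fc_ctrl`,
#'   `fc_ko`, `adj_p_ko`, `label`.
#' @export
classify_members <- function(ko_diff, ctrl_diff, sig,
                             abolish_ratio = 0.25, retain_ratio = 0.75) {
  stopifnot(inherits(sig, "signature_set"))
  shared <- intersect(sig$members,
                      intersect(ko_diff$feature_id, ctrl_diff$feature_id))
  ko <- ko_diff[match(shared, ko_diff$feature_id), , drop = FALSE]
  ctrl <- ctrl_diff[match(shared, ctrl_diff$feature_id), , drop = FALSE]
  significant <- ko$adj_p < sig$alpha & ko$log2fc > sig$fc_min
  label <- ifelse(!significant & ko$log2fc < abolish_ratio * ctrl$log2fc,
                  "abolished",
                  ifelse(significant & ko$log2fc >= retain_ratio * ctrl$log2fc,
                         "retained", "attenuated"))
  data.frame(feature_id = shared, fc_ctrl = ctrl$log2fc, fc_ko = ko$log2fc,
             adj_p_ko = ko$adj_p, label = label, stringsAsFactors = FALSE)
}

#' Compare two perturbations on the signature
#'
#' Over signature members quantified in both comparisons, computes the
#' Pearson correlation of log2 fold changes, the ordinary least-squares
#' regression of B on A (with intercept), and the Jaccard index of the two
#' significant-member sets at the signature's thresholds.
#'
#' @param diff_a,diff_b Differential tables (single comparison each); A goes
#'   on the x axis of the regression.
#' @param sig A [derive_signature()] result.
#' @return A list: `pearson_r`, `slope`, `intercept`, `jaccard`,
#'   `n_shared_members`.
#' @export
compare_perturbations <- function(diff_a, diff_b, sig) {
  stopifnot(inherits(sig, "signature_set"))
  shared <- intersect(sig$members,
                      intersect(diff_a$feature_id, diff_b$feature_id))
  if (length(shared) < 3) {
    stop("fewer than 3 signature members quantified in both comparisons",
         call. = FALSE)
  }
  a <- diff_a[match(shared, diff_a$feature_id), , drop = FALSE]
  b <- diff_b[match(shared, diff_b$feature_id), , drop = FALSE]
  fit <- stats::lm(b$log2fc ~ a$log2fc)
  sig_a <- shared[a$adj_p < sig$alpha & a$log2fc > sig$fc_min]
  sig_b <- shared[b$adj_p < sig$alpha & b$log2fc > sig$fc_min]
  union_n <- length(union(sig_a, sig_b))
  list(pearson_r = stats::cor(a$log2fc, b$log2fc),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       jaccard = if (union_n) length(intersect(sig_a, sig_b)) / union_n else NA_real_,
       n_shared_members = length(shared))
}
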