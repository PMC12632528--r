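#' Enumerate a perturbation-experiment design manifest
#'
#' Builds the full factorial sample manifest for a genetic-perturbation
#' stimulation experiment: (knockout genotypes + non-targeting controls) x
#' replicates x timepoints x (treated and, optionally, a time-matched vehicle
#' arm). Every treated sample therefore has a vehicle sample collected at the
#' same timepoint in the same genotype and donor, which is the unit the
#' fold-change machinery relies on.
#'
#' With 11 knockouts, 3 controls, quadruplicates, two timepoints and matched
#' vehicles the manifest enumerates 14 x 4 x 2 x 2 = 224 samples.
#'
#' @param n_knockouts Number of knockout genotypes (>= 0).
#' @param n_controls Number of non-targeting (scrambled) control genotypes
#'   (>= 1 if `n_knockouts` is 0).
#' @param n_replicates Replicates per (genotype, treatment, timepoint) cell.
#' @param timepoints Numeric vector of stimulation timepoints in minutes.
#' @param include_vehicle If `TRUE`, add a time-matched vehicle sample for
#'   every treated sample.
#' @param donors Character vector of donor labels; replicates are assigned to
#'   donors in rotation so each donor contributes to every condition.
#' @param assay `"phospho"` or `"global"`.
#' @param knockout_genes Optional character vector of knockout gene names
#'   (length `n_knockouts`); defaults to `KO01..`.
#' @param treatment Stimulus label for the treated arm.
#' @param dose Stimulus dose (U/mL) for the treated arm; vehicle gets 0.
#' @param cell_type Cell-type label carried through to condition grouping.
#' @param cell_input Optional per-sample input amount (cells or µg); recycled.
#' @return A data.frame with one row per sample and columns `sample_id`,
#'   `genotype`, `donor`, `replicate`, `treatment`, `dose`, `timepoint`,
#'   `cell_input`, `assay`, `cell_type`.
#' @examples
#' d <- generate_design(11, 3, 4, c(5, 30))
#' nrow(d)  # 224
#' @export
generate_design <- function(n_knockouts, n_controls, n_replicates, timepoints,
                            include_vehicle = TRUE,
                            donors = "donor1",
                            assay = c("phospho", "global"),
                            knockout_genes = NULL,
                            treatment = "IFN-b",
                            dose = 1000,
                            cell_type = "CD4T",
                            cell_input = NA_real_) {
  assay <- match.arg(assay)
  if (n_knockouts < 0 || n_controls < 0 || n_knockouts + n_controls < 1) {
    stop("invalid design: need at least one genotype", call. = FALSE)
  }
  if (n_replicates < 1) stop("invalid design: n_replicates must be >= 1", call. = FALSE)
  if (length(timepoints) < 1) stop("invalid design: timepoints must be non-empty", call. = FALSE)
  if (any(timepoints < 0)) stop("invalid design: negative timepoint", call. = FALSE)

  if (is.null(knockout_genes)) {
    knockout_genes <- sprintf("KO%02d", seq_len(n_knockouts))
  } else if (length(knockout_genes) != n_knockouts) {
    stop("invalid design: knockout_genes length must equal n_knockouts", call. = FALSE)
  }
  genotypes <- c(knockout_genes,
                 if (n_controls > 0) sprintf("scramble%d", seq_len(n_controls)))

  treatments <- if (include_vehicle) c(treatment, "vehicle") else treatment
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      timepoint = timepoints,
                      treatment = treatments,
                      genotype  = genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$genotype, grid$treatment, grid$timepoint,
                     grid$replicate), , drop = FALSE]
  grid$donor <- donors[(grid$replicate - 1L) %% length(donors) + 1L]
  grid$dose <- ifelse(grid$treatment == "vehicle", 0, dose)
  grid$assay <- assay
  grid$cell_type <- cell_type
  grid$cell_input <- rep_len(cell_input, nrow(grid))
  grid$sample_id <- sprintf("%s_%s_t%g_r%d", grid$genotype, grid$treatment,
                            grid$timepoint, grid$replicate)
  rownames(grid) <- NULL
  grid[, c("sample_id", "genotype", "donor", "replicate", "treatment",
           "dose", "timepoint", "cell_input", "assay", "cell_type")]
}

#' Validate a design manifest
#'
#' Checks the structural assumptions downstream stages rely on: unique sample
#' ids, a time-matched vehicle arm for every treated condition within
#' genotype and donor, replicate counts compatible with the
#' replicate-presence filter, and donor balance. Issues are reported, never
#' thrown.
#'
#' @param design A design manifest data.frame.
#' @param min_present Integer pair `c(k, n)` of the replicate-presence rule
#'   to check feasibility against, or `NULL` to skip.
#' @param control_treatment Label of the vehicle arm.
#' @return A data.frame of issues with columns `severity`, `issue`,
#'   `condition`; zero rows when the design is clean.
#' @export
validate_design <- function(design, min_present = c(3L, 4L),
                            control_treatment = "vehicle") {
  issues <- list()
  add <- function(severity, issue, condition = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, issue = issue, condition = condition,
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    add("error", "duplicate sample_id",
        paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ","))
  }
  treated <- design[design$treatment != control_treatment, , drop = FALSE]
  if (nrow(treated)) {
    key <- function(d) paste(d$genotype, d$timepoint, d$donor, d$cell_type, sep = "|")
    ctrl <- design[design$treatment == control_treatment, , drop = FALSE]
    missing_ctrl <- setdiff(unique(key(treated)), unique(key(ctrl)))
    for (m in missing_ctrl) add("error", "no time-matched vehicle sample", m)
  }
  if (!is.null(min_present)) {
    k <- min_present[[1L]]
    cond <- condition_key(design)
    counts <- table(cond)
    low <- names(counts)[counts < k]
    for (m in low) add("warning", sprintf("fewer than %d replicates; replicate filter cannot be met", k), m)
  }
  donor_tab <- table(design$donor)
  if (length(donor_tab) > 1 && (max(donor_tab) - min(donor_tab)) > 0) {
    add("note", "donors contribute unequal sample counts", "")
  }
  if (!length(issues)) {
    return(data.frame(severity = character(), issue = character(),
                      condition = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
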