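#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated object.
#' Inputs may be file paths (TSV report, CSV design, TSV/GMT kinase map) or
#' in-memory objects.
#'
#' @param report Long report path or data.frame.
#' @param design Design manifest path or data.frame.
#' @param ks_map Kinase-substrate map path or named list; `NULL` skips KSEA.
#' @param out_dir Output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @param mode `"phospho"` (site level, SLSA, moderated t) or `"global"`
#'   (protein level, k-NN, Student's t) — engines can be overridden.
#' @param class1 Localization-probability cutoff (phospho mode).
#' @param min_present Replicate-presence rule, `c(k, n)` or fraction.
#' @param alpha,fc_min Significance thresholds for signatures and scoring.
#' @param min_substrates KSEA substrate minimum.
#' @param k,shift,width Imputation parameters.
#' @param seed Integer seed recorded in every output.
#' @param engine Test engine; defaults to the mode's convention.
#' @param control_genotype_pattern Regex identifying control (scrambled)
#'   genotypes for signature derivation.
#' @param control_treatment Vehicle arm label.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(report, design, ks_map = NULL, out_dir = NULL,
                            mode = c("phospho", "global"),
                            class1 = 0.75, min_present = c(3L, 4L),
                            alpha = 0.05, fc_min = 0.75, min_substrates = 3L,
                            k = 10L, shift = 1.8, width = 0.3, seed = 1L,
                            engine = NULL,
                            control_genotype_pattern = "^scramble",
                            control_treatment = "vehicle") {
  mode <- match.arg(mode)
  if (is.null(engine)) engine <- if (mode == "phospho") "moderated" else "student"
  engine <- match.arg(engine, c("moderated", "student"))
  stopifnot(class1 >= 0, class1 <= 1, alpha > 0, alpha <= 1,
            min_substrates >= 1, k >= 1, width >= 0)
  structure(list(report = report, design = design, ks_map = ks_map,
                 out_dir = out_dir, mode = mode, class1 = class1,
                 min_present = min_present, alpha = alpha, fc_min = fc_min,
                 min_substrates = min_substrates, k = k, shift = shift,
                 width = width, seed = as.integer(seed), engine = engine,
                 control_genotype_pattern = control_genotype_pattern,
                 control_treatment = control_treatment),
            class = "pipeline_config")
}

# hash of the configuration scalars (not the data), for the run manifest
config_hash <- function(config) {
  scalars <- config[setdiff(names(config), c("report", "design", "ks_map", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(scalars, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order: read inputs, site collapse
#' and Class-I filtering (phospho mode), pivot to a feature-by-sample
#' matrix, replicate-presence filter, log2 + median-centering
#' normalization, mechanism-matched imputation, donor centering,
#' differential testing with BH correction per comparison, KSEA (when a
#' kinase map is given), signature derivation from the control genotypes,
#' and per-perturbation signature scoring. Per-stage feature counts are
#' recorded, and a rerun with an identical configuration and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `qc`, `matrix_imputed`,
#'   `missingness`, `diff`, `ksea`, `signature`, `scores`, `stage_counts`,
#'   `manifest`. When `out_dir` is set, the standard files (`qc_*.tsv`,
#'   `matrix_imputed.tsv`, `diff.tsv`, `ksea.tsv`, `signature.json`,
#'   `scores.tsv`, `run_manifest.json`) are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- if (is.character(config$report)) read_long_report(config$report) else config$report
  design <- if (is.character(config$design)) read_design(config$design) else config$design
  ks_map <- if (is.character(config$ks_map)) read_kinase_substrate_map(config$ks_map) else config$ks_map

  counts <- list(precursor_records = nrow(report))
  if (config$mode == "phospho") {
    report <- collapse_to_sites(report)
    counts$site_records <- nrow(report)
    report <- filter_class1(report, threshold = config$class1)
    counts$class1_records <- nrow(report)
    level <- "site"
  } else {
    level <- "protein"
  }

  mat <- pivot_to_matrix(report, design, level = level)
  counts$features_quantified <- nrow(mat$values)

  qc <- qc_metrics(report, mat, design, class1_threshold = config$class1,
                   linearity = FALSE)

  mat <- filter_by_replicates(mat, design, min_present = config$min_present)
  counts$features_after_replicate_filter <- nrow(mat$values)

  mat <- normalize_intensity(mat)
  imp <- impute_mixed(mat, design, mode = config$mode, k = config$k,
                      shift = config$shift, width = config$width,
                      seed = config$seed)
  mat <- center_by_donor(imp$matrix, design)

  diff <- differential_table(mat, design, engine = config$engine,
                             control_treatment = config$control_treatment)

  ksea <- if (!is.null(ks_map) && config$mode == "phospho") {
    ksea_z(diff, ks_map, min_substrates = config$min_substrates)
  } else NULL

  is_control <- grepl(config$control_genotype_pattern, diff$genotype)
  signature <- NULL
  scores <- NULL
  if (any(is_control)) {
    ctrl_diffs <- split(diff[is_control, , drop = FALSE],
                        diff$comparison[is_control])
    signature <- withCallingHandlers(
      derive_signature(ctrl_diffs, alpha = config$alpha, fc_min = config$fc_min),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(signature$members)) {
      ko_pieces <- split(diff[!is_control, , drop = FALSE],
                         diff$comparison[!is_control])
      score_list <- lapply(ko_pieces, score_perturbation, sig = signature)
      scores <- do.call(rbind, lapply(score_list, function(s) {
        data.frame(genotype = s$genotype, comparison = s$comparison,
                   n_significant_members = s$n_significant_members,
                   n_members_quantified = s$n_members_quantified,
                   mean_member_fc = s$mean_member_fc,
                   mean_nonmember_fc = s$mean_nonmember_fc,
                   stringsAsFactors = FALSE)
      }))
      scores <- scores[order(scores$comparison), , drop = FALSE]
      rownames(scores) <- NULL
    }
  }

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   mode = config$mode, engine = config$engine,
                   stage_counts = counts)

  result <- structure(list(qc = qc, matrix_imputed = mat,
                           missingness = imp$labels, diff = diff, ksea = ksea,
                           signature = signature, scores = scores,
                           stage_counts = counts, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

# fixed-name, deterministically ordered outputs under out_dir
write_pipeline_result <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  tidy_write <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  for (nm in names(result$qc)) {
    tidy_write(result$qc[[nm]], out(paste0("qc_", nm, ".tsv")))
  }
  write_matrix_tsv(result$matrix_imputed, out("matrix_imputed.tsv"))
  d <- result$diff[order(result$diff$comparison, result$diff$feature_id), ]
  tidy_write(d, out("diff.tsv"))
  if (!is.null(result$ksea)) {
    kk <- result$ksea[order(result$ksea$comparison, result$ksea$kinase), ]
    tidy_write(kk, out("ksea.tsv"))
  }
  if (!is.null(result$signature)) {
    jsonlite::write_json(list(members = result$signature$members,
                              alpha = result$signature$alpha,
                              fc_min = result$signature$fc_min,
                              provenance = result$signature$provenance),
                         out("signature.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(result$scores)) tidy_write(result$scores, out("scores.tsv"))
  jsonlite::write_json(result$manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %s: %d\n", nm, x$stage_counts[[nm]]))
  }
  if (!is.null(x$signature)) {
    cat(sprintf("  signature members: %d\n", length(x$signature$members)))
  }
  invisible(x)
}
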