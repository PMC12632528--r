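# Column aliases accepted on input. Canonical names are lower_snake; the
# aliases cover common Spectronaut-style report headers (v18-v20).
.report_aliases <- list(
  sample_id = c("sample_id", "R.FileName", "R.Condition", "run"),
  protein_group = c("protein_group", "PG.ProteinGroups", "PG.ProteinAccessions"),
  stripped_sequence = c("stripped_sequence", "PEP.StrippedSequence"),
  modified_sequence = c("modified_sequence", "EG.ModifiedSequence", "EG.PrecursorId"),
  site_key = c("site_key", "PTM.SiteKey", "PTM.CollapseKey"),
  localization_probability = c("localization_probability", "EG.PTMAssayProbability",
                               "PTM.SiteProbability"),
  intensity = c("intensity", "FG.Quantity", "PG.Quantity", "EG.TotalQuantity"),
  is_phospho = c("is_phospho")
)

.required_report_cols <- c("sample_id", "protein_group", "modified_sequence",
                           "intensity")

rename_by_alias <- function(df, aliases) {
  for (canon in names(aliases)) {
    if (canon %in% names(df)) next
    hit <- intersect(aliases[[canon]], names(df))
    if (length(hit)) names(df)[names(df) == hit[[1L]]] <- canon
  }
  df
}

#' Read a long-format DIA search report
#'
#' Reads a tab-separated precursor-level report (canonical lower-snake
#' headers or Spectronaut-style aliases such as `PG.ProteinGroups`,
#' `EG.ModifiedSequence`, `EG.PTMAssayProbability`, `R.FileName`,
#' `FG.Quantity`). Rows whose intensity is non-numeric or not strictly
#' positive are dropped with a message reporting the count. Empty fields and
#' `"NaN"` are read as missing.
#'
#' @param path Path to a TSV report.
#' @return A long-report data.frame with columns `sample_id`,
#'   `protein_group`, `stripped_sequence`, `modified_sequence`, `site_key`,
#'   `localization_probability`, `intensity`, `is_phospho`.
#' @export
read_long_report <- function(path) {
  df <- read_table_checked(path, sep = "\t")
  df <- rename_by_alias(df, .report_aliases)
  missing_cols <- setdiff(.required_report_cols, names(df))
  if (length(missing_cols)) {
    stop("report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"stripped_sequence" %in% names(df)) {
    df$stripped_sequence <- gsub("\\[[^]]*\\]", "", df$modified_sequence)
  }
  if (!"site_key" %in% names(df)) df$site_key <- NA_character_
  if (!"localization_probability" %in% names(df)) {
    df$localization_probability <- NA_real_
  }
  df$localization_probability <- suppressWarnings(as.numeric(df$localization_probability))
  if (any(!is.na(df$localization_probability) &
          (df$localization_probability < 0 | df$localization_probability > 1))) {
    stop("localization probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!"is_phospho" %in% names(df)) {
    df$is_phospho <- !is.na(df$site_key) & df$site_key != ""
  } else {
    df$is_phospho <- as.logical(df$is_phospho)
  }
  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- is.na(intensity) | intensity <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) dropped: non-numeric or non-positive intensity")
    df <- df[!bad, , drop = FALSE]
    intensity <- intensity[!bad]
  }
  df$intensity <- intensity
  df$site_key[!is.na(df$site_key) & df$site_key == ""] <- NA_character_
  rownames(df) <- NULL
  df[, c("sample_id", "protein_group", "stripped_sequence", "modified_sequence",
         "site_key", "localization_probability", "intensity", "is_phospho")]
}

# shared reader: rejects empty files distinctly, treats "", "NA", "NaN" as missing
read_table_checked <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"), comment.char = "")
  if (nrow(df) == 0) stop("file has a header but no records: ", path, call. = FALSE)
  df
}

#' Write a long report to TSV
#'
#' Output ordering is stable (sample, then modified sequence, lexicographic)
#' so identical inputs produce byte-identical files. Missing values are
#' written as empty fields.
#'
#' @param report A long-report data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_report <- function(report, path) {
  report <- report[order(report$sample_id, report$modified_sequence), , drop = FALSE]
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a design manifest (CSV)
#'
#' @param path Path to a CSV manifest with at least `sample_id`, `genotype`,
#'   `donor`, `replicate`, `treatment`, `dose`, `timepoint`, `assay`,
#'   `cell_type` columns.
#' @return A design data.frame.
#' @export
read_design <- function(path) {
  df <- read_table_checked(path, sep = ",")
  required <- c("sample_id", "genotype", "donor", "replicate", "treatment",
                "dose", "timepoint", "assay", "cell_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design", call. = FALSE)
  if (!"cell_input" %in% names(df)) df$cell_input <- NA_real_
  df$cell_input <- as.numeric(df$cell_input)
  df
}

#' @rdname read_design
#' @param design A design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, na = "")
  invisible(path)
}

# site keys are PROTEIN_[STY]POS, 1-based position
is_valid_site_key <- function(x) grepl("^[A-Za-z0-9.-]+_[STY][0-9]+$", x)

#' Read a kinase-substrate annotation map
#'
#' Accepts either a TSV with columns `kinase`, `site_key` (or `kinase`,
#' `protein`, `site` to be combined), or a GMT file (set name = kinase,
#' members = site keys). Duplicate pairs are deduplicated. Site keys must be
#' `PROTEIN_[STY]POS` with 1-based positions.
#'
#' @param path Path to a `.tsv`/`.txt` or `.gmt` file.
#' @return A named list: kinase -> character vector of substrate site keys.
#' @export
read_kinase_substrate_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty file: ", path, call. = FALSE)
    pairs <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3) stop("malformed GMT line ", i, call. = FALSE)
      data.frame(kinase = f[[1L]], site_key = f[-(1:2)], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pairs)
  } else {
    df <- read_table_checked(path, sep = "\t")
    if (all(c("protein", "site") %in% names(df)) && !"site_key" %in% names(df)) {
      df$site_key <- paste0(df$protein, "_", df$site)
    }
    if (!all(c("kinase", "site_key") %in% names(df))) {
      stop("kinase-substrate table needs columns kinase and site_key (or kinase, protein, site)",
           call. = FALSE)
    }
  }
  bad <- which(!is_valid_site_key(df$site_key))
  if (length(bad)) {
    stop("malformed site_key at record ", bad[[1L]], ": ", df$site_key[bad[[1L]]],
         call. = FALSE)
  }
  out <- lapply(split(df$site_key, df$kinase), function(x) sort(unique(x)))
  if (any(!lengths(out))) stop("kinase with empty substrate set", call. = FALSE)
  out[order(names(out))]
}

#' Write a kinase-substrate map as GMT
#'
#' @param ks_map Named list: kinase -> site keys.
#' @param path Output path.
#' @export
write_kinase_substrate_map <- function(ks_map, path) {
  lines <- vapply(names(ks_map), function(k) {
    paste(c(k, "na", sort(ks_map[[k]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ground truth as JSON
#'
#' Only the generative parameters are serialized (per-feature annotations are
#' regenerated from the seed).
#'
#' @param truth A [ground_truth()] object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  fields <- setdiff(names(truth), c("feature_info", "log2_matrix"))
  out <- truth[fields]
  # named effect vectors become JSON objects so names survive the round trip
  for (f in c("induced_set", "active_kinases", "ablation_map")) {
    out[[f]] <- as.list(out[[f]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("induced_set", "active_kinases", "ablation_map")) {
    v <- unlist(x[[f]])
    x[[f]] <- if (is.null(v)) numeric() else v
  }
  do.call(ground_truth, x)
}

#' Pivot a long report into a feature-by-sample intensity matrix
#'
#' At protein level, precursor intensities mapping to the same protein group
#' in the same sample are summed. At site level, phospho records are first
#' collapsed per (sample, site) with [collapse_to_sites()] (maximum intensity
#' and maximum localization probability). Measurements absent from the report
#' are missing (`NA`) in the matrix, never zero.
#'
#' @param report A long-report data.frame.
#' @param design A design manifest; every report sample must appear in it,
#'   and the matrix gets one column per design sample.
#' @param level `"site"` or `"protein"`.
#' @return An `intensity_matrix` on linear scale with feature metadata.
#' @export
pivot_to_matrix <- function(report, design, level = c("site", "protein")) {
  level <- match.arg(level)
  unknown <- setdiff(unique(report$sample_id), design$sample_id)
  if (length(unknown)) {
    stop("report samples absent from design manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (level == "site") {
    report <- collapse_to_sites(report)
    report <- report[report$is_phospho, , drop = FALSE]
    feature <- report$site_key
    agg <- stats::aggregate(intensity ~ feature + sample_id,
                            data = data.frame(feature = feature,
                                              sample_id = report$sample_id,
                                              intensity = report$intensity),
                            FUN = max)
  } else {
    feature <- report$protein_group
    agg <- stats::aggregate(intensity ~ feature + sample_id,
                            data = data.frame(feature = feature,
                                              sample_id = report$sample_id,
                                              intensity = report$intensity),
                            FUN = sum)
  }
  features <- sort(unique(agg$feature))
  samples <- design$sample_id
  values <- matrix(NA_real_, length(features), length(samples),
                   dimnames = list(features, samples))
  values[cbind(match(agg$feature, features), match(agg$sample_id, samples))] <-
    agg$intensity

  if (level == "site") {
    loc <- vapply(split(report$localization_probability, report$site_key),
                  function(p) suppressWarnings(max(p, na.rm = TRUE)), numeric(1))
    feature_info <- data.frame(
      feature_id = features,
      protein = sub("_[STY][0-9]+$", "", features),
      residue = sub("^.*_([STY])[0-9]+$", "\\1", features),
      position = as.integer(sub("^.*_[STY]([0-9]+)$", "\\1", features)),
      localization_probability = unname(loc[features]),
      stringsAsFactors = FALSE)
  } else {
    feature_info <- data.frame(feature_id = features, protein = features,
                               stringsAsFactors = FALSE)
  }
  intensity_matrix(values, scale = "linear", feature_info = feature_info)
}

#' Write an intensity matrix as TSV
#'
#' First column `feature_id`, then one column per sample; missing entries are
#' empty fields; rows sorted by feature id for byte-stable output.
#'
#' @param mat An `intensity_matrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  v <- mat$values[order(rownames(mat$values)), , drop = FALSE]
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
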