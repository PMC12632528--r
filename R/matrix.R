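#' Construct an intensity matrix
#'
#' The central quantitative container of the package: a numeric
#' feature-by-sample matrix together with an explicit scale flag and optional
#' per-feature metadata. Missing measurements are `NA`; they are never encoded
#' as zero.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Both
#'   dimnames must be set and unique.
#' @param scale Either `"linear"` (all observed values strictly positive) or
#'   `"log2"`.
#' @param feature_info Optional data.frame of per-feature metadata with a
#'   `feature_id` column matching `rownames(values)`.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `scale` and `feature_info`.
#' @export
intensity_matrix <- function(values, scale = c("linear", "log2"),
                             feature_info = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("`values` must have row (feature) names", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (ncol(values) > 0 && is.null(colnames(values))) {
    stop("`values` must have column (sample) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("feature and sample ids must be unique", call. = FALSE)
  }
  if (scale == "linear" && any(values <= 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be strictly positive", call. = FALSE)
  }
  if (!is.null(feature_info)) {
    if (!"feature_id" %in% names(feature_info) ||
        !setequal(feature_info$feature_id, rownames(values))) {
      stop("`feature_info` must carry a feature_id column matching the matrix rows",
           call. = FALSE)
    }
    feature_info <- feature_info[match(rownames(values), feature_info$feature_id), ,
                                 drop = FALSE]
    rownames(feature_info) <- NULL
  }
  structure(list(values = values, scale = scale, feature_info = feature_info),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  v <- x$values
  n_missing <- sum(is.na(v))
  cat(sprintf("intensity_matrix: %d features x %d samples (%s scale), %.1f%% missing\n",
              nrow(v), ncol(v), x$scale, 100 * n_missing / length(v)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

# replace the value slot, keeping metadata; used internally after transforms
im_replace <- function(mat, values, scale = mat$scale) {
  intensity_matrix(values, scale = scale, feature_info = mat$feature_info)
}

#' Convert an intensity matrix to log2 scale
#'
#' @param mat An `intensity_matrix`.
#' @return The same matrix on log2 scale (a no-op if already log2).
#' @export
to_log2 <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (mat$scale == "log2") return(mat)
  im_replace(mat, log2(mat$values), scale = "log2")
}

# The condition of a sample: the unit within which replicates are exchangeable.
condition_key <- function(design) {
  paste(design$genotype, design$treatment, design$dose, design$timepoint,
        design$cell_type, sep = "|")
}

# match matrix columns to design rows, erroring on unknown samples
design_for_columns <- function(mat, design) {
  idx <- match(colnames(mat$values), design$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from design manifest: ",
         paste(colnames(mat$values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  design[idx, , drop = FALSE]
}
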