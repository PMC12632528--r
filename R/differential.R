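#' Center a matrix by donor
#'
#' Removes additive donor batch effects: for every feature and donor, the
#' donor's mean over its observed samples is subtracted. Within-donor
#' contrasts (treated minus time-matched vehicle) are preserved exactly; with
#' a single donor the matrix is returned unchanged.
#'
#' @param mat A log2-scale `intensity_matrix`.
#' @param design The design manifest.
#' @return The donor-centered matrix.
#' @export
center_by_donor <- function(mat, design) {
  stopifnot(inherits(mat, "intensity_matrix"))
  d <- design_for_columns(mat, design)
  donors <- unique(d$donor)
  if (length(donors) < 2) return(mat)
  v <- mat$values
  for (dn in donors) {
    cols <- which(d$donor == dn)
    mu <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    v[, cols] <- v[, cols, drop = FALSE] - mu
  }
  im_replace(mat, v)
}

# enumerate treated comparisons and their time-matched vehicle columns
comparison_groups <- function(d, control_treatment = "vehicle") {
  treated <- d$treatment != control_treatment
  keys <- unique(condition_key(d)[treated])
  lapply(keys, function(kk) {
    cols_a <- which(condition_key(d) == kk)
    a <- d[cols_a[1L], ]
    cols_b <- which(d$treatment == control_treatment &
                      d$genotype == a$genotype &
                      d$timepoint == a$timepoint &
                      d$cell_type == a$cell_type)
    if (!length(cols_b)) {
      stop("no time-matched ", control_treatment, " samples for condition ", kk,
           call. = FALSE)
    }
    list(key = kk, genotype = a$genotype, treatment = a$treatment,
         dose = a$dose, timepoint = a$timepoint, cell_type = a$cell_type,
         treated_cols = cols_a, control_cols = cols_b)
  })
}

#' Log2 fold change against time-matched vehicle controls
#'
#' For every treated condition, computes per feature
#' `mean(log2 treated) - mean(log2 vehicle)` where the vehicle samples share
#' the condition's genotype, timepoint and cell type. Errors if a treated
#' condition lacks its matched control.
#'
#' @param mat A log2-scale `intensity_matrix`.
#' @param design The design manifest.
#' @param control_treatment Label of the vehicle arm.
#' @return A data.frame with one row per (feature, comparison):
#'   `feature_id`, comparison fields, `log2fc`, `n_treated`, `n_control`.
#' @export
fold_change_vs_control <- function(mat, design, control_treatment = "vehicle") {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (mat$scale != "log2") stop("fold changes require a log2-scale matrix", call. = FALSE)
  d <- design_for_columns(mat, design)
  v <- mat$values
  groups <- comparison_groups(d, control_treatment)
  out <- lapply(groups, function(g) {
    a <- v[, g$treated_cols, drop = FALSE]
    b <- v[, g$control_cols, drop = FALSE]
    data.frame(feature_id = rownames(v),
               comparison = g$key,
               genotype = g$genotype, treatment = g$treatment,
               dose = g$dose, timepoint = g$timepoint, cell_type = g$cell_type,
               log2fc = rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE),
               n_treated = rowSums(!is.na(a)),
               n_control = rowSums(!is.na(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sided pooled-variance Student's t-test
#'
#' Equal-variance two-sample t-test (not Welch). Degenerate inputs are
#' resolved explicitly: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero variance with unequal means gives infinite `t`,
#' `p = 0` and a `degenerate` flag.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A list with `t`, `p`, `df`, `degenerate`.
#' @export
student_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("student_t needs at least 2 values per group", call. = FALSE)
  }
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2, degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2, degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), degenerate = FALSE)
}

# --- empirical-Bayes variance moderation -----------------------------------
#
# Prior (d0, s0^2) is estimated by method of moments on z_g = log(s_g^2):
#   z_g - digamma(d_g/2) + log(d_g/2)  has mean  log(s0^2) - digamma(d0/2)*(-1)...
# concretely, with e_g = z_g - digamma(d_g/2) + log(d_g/2):
#   E[e_g]   = log(s0^2) + digamma(d0/2) - log(d0/2)
#   Var[e_g] = trigamma(d_g/2) + trigamma(d0/2)
# so trigamma(d0/2) is recovered from the excess variance of e_g and inverted
# by Newton iteration.

trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate the variance prior (d0, s0^2) from per-feature variances
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to observed
#' residual variances `s2` with `df` degrees of freedom each, via the
#' log-variance moments and trigamma inversion. When the observed spread of
#' log variances does not exceed its sampling expectation, the prior
#' degrees of freedom are infinite and every feature shares `s0^2`.
#'
#' @param s2 Per-feature residual variances (> 0).
#' @param df Residual degrees of freedom (scalar or per feature).
#' @return A list with `d0` (possibly `Inf`) and `s0_2`.
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  if (length(s2) < 2) stop("need >= 2 positive variances", call. = FALSE)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics for a two-group comparison
#'
#' Empirical-Bayes moderation of per-feature pooled variances: the posterior
#' variance is `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t
#' is the mean difference over `sqrt(posterior * (1/nA + 1/nB))`, referred to
#' a t distribution on `d0 + d_g` degrees of freedom (normal when
#' `d0 = Inf`). `prior_df = 0` reproduces plain Student's t;
#' `prior_df = Inf` uses `s0^2` for every feature.
#'
#' @param a,b Numeric matrices (features x replicates) of the two groups.
#' @param prior_df Optional fixed prior degrees of freedom (otherwise
#'   estimated).
#' @param prior_var Optional fixed prior variance `s0^2` (otherwise
#'   estimated).
#' @return A data.frame per feature: `log2fc`, `t`, `p`, `df_total`, `s2`,
#'   plus attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(a, b, prior_df = NULL, prior_var = NULL) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b))
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  if (any(na < 2 | nb < 2)) stop("moderated_t needs >= 2 values per group", call. = FALSE)
  mean_a <- rowMeans(a, na.rm = TRUE); mean_b <- rowMeans(b, na.rm = TRUE)
  var_a <- apply(a, 1, stats::var, na.rm = TRUE)
  var_b <- apply(b, 1, stats::var, na.rm = TRUE)
  dg <- na + nb - 2
  s2 <- ((na - 1) * var_a + (nb - 1) * var_b) / dg

  if (is.null(prior_df) || is.null(prior_var)) {
    prior <- estimate_variance_prior(pmax(s2, .Machine$double.xmin), dg)
    if (is.null(prior_df)) prior_df <- prior$d0
    if (is.null(prior_var)) prior_var <- prior$s0_2
  }
  d0 <- prior_df; s0_2 <- prior_var

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- (mean_a - mean_b) / se
  df_total <- d0 + dg
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(tstat)) else {
    2 * stats::pt(-abs(tstat), df = df_total)
  }
  out <- data.frame(log2fc = mean_a - mean_b, t = tstat, p = p,
                    df_total = df_total, s2 = s2, stringsAsFactors = FALSE)
  if (!is.null(rownames(a))) out <- cbind(feature_id = rownames(a), out,
                                          stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validation wrapper around
#' the standard implementation. Inputs must lie in (0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (clipped at 1, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-abundance table across all comparisons
#'
#' For every treated condition, tests each feature against the time-matched
#' vehicle samples with either plain Student's t (`"student"`, the global
#' proteomics convention) or the empirical-Bayes moderated t
#' (`"moderated"`, the phosphoproteomics convention), and applies
#' Benjamini-Hochberg correction within each comparison.
#'
#' @param mat An imputed, donor-centered, log2-scale `intensity_matrix`.
#' @param design The design manifest.
#' @param engine `"moderated"` or `"student"`.
#' @param control_treatment Label of the vehicle arm.
#' @return A data.frame with one row per (feature, comparison): comparison
#'   fields, `log2fc`, `t_statistic`, `p_value`, `adj_p`, `n_treated`,
#'   `n_control`.
#' @export
differential_table <- function(mat, design, engine = c("moderated", "student"),
                               control_treatment = "vehicle") {
  engine <- match.arg(engine)
  stopifnot(inherits(mat, "intensity_matrix"))
  if (mat$scale != "log2") stop("differential tests require a log2-scale matrix", call. = FALSE)
  d <- design_for_columns(mat, design)
  v <- mat$values
  groups <- comparison_groups(d, control_treatment)
  out <- lapply(groups, function(g) {
    a <- v[, g$treated_cols, drop = FALSE]
    b <- v[, g$control_cols, drop = FALSE]
    if (engine == "moderated") {
      fit <- moderated_t(a, b)
      tstat <- fit$t; p <- fit$p; fc <- fit$log2fc
    } else {
      res <- lapply(seq_len(nrow(v)), function(i) student_t(a[i, ], b[i, ]))
      tstat <- vapply(res, `[[`, numeric(1), "t")
      p <- vapply(res, `[[`, numeric(1), "p")
      fc <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
    }
    p <- pmin(pmax(p, .Machine$double.xmin), 1)  # BH domain
    data.frame(feature_id = rownames(v),
               comparison = g$key,
               genotype = g$genotype, treatment = g$treatment,
               dose = g$dose, timepoint = g$timepoint, cell_type = g$cell_type,
               log2fc = fc, t_statistic = tstat, p_value = p,
               adj_p = bh_adjust(p),
               n_treated = rowSums(!is.na(a)), n_control = rowSums(!is.na(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
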