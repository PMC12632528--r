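# design with two conditions of 4 replicates each (treated + vehicle)
impute_design <- function(n_replicates = 4) {
  toy_design(n_knockouts = 0, n_controls = 1, n_replicates = n_replicates,
             timepoints = 240)
}

test_that("missingness classification follows the block rule", {
  design <- impute_design()
  treated <- design$sample_id[design$treatment != "vehicle"]
  vehicle <- design$sample_id[design$treatment == "vehicle"]
  v <- matrix(20, 3, 8, dimnames = list(c("pov", "mec", "full"),
                                        design$sample_id))
  v["pov", treated[c(2, 4)]] <- NA     # partially observed block -> MAR
  v["mec", treated] <- NA              # entire condition missing -> MNAR
  labels <- classify_missingness(toy_matrix(v), design)
  expect_equal(unname(labels["pov", treated[c(2, 4)]]), c("MAR", "MAR"))
  expect_equal(unname(labels["mec", treated]), rep("MNAR", 4))
  expect_true(all(labels["full", ] == "observed"))
  expect_true(all(labels[, vehicle] == "observed"))
  expect_identical(labels == "observed", !is.na(v))
})

test_that("kNN imputation: forced neighbour and brute-force oracle", {
  design <- impute_design(2)
  # identical-profile neighbour fills the gap with its own value
  v <- matrix(c(1, 2, 3, NA,
                1, 2, 3, 4,
                9, 9, 9, 9), 3, 4, byrow = TRUE,
              dimnames = list(c("g", "twin", "far"), design$sample_id))
  out <- impute_knn(toy_matrix(v), k = 1)
  expect_equal(out$values["g", 4], 4)

  # 6x4 toy with several gaps vs exhaustive enumeration
  set.seed(6)
  v2 <- matrix(rnorm(24, 20, 2), 6, 4,
               dimnames = list(sprintf("f%d", 1:6), design$sample_id))
  v2[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  got <- suppressWarnings(impute_knn(toy_matrix(v2), k = 2))
  expect_equal(got$values, knn_oracle(v2, k = 2), tolerance = 1e-12)

  # no gaps: identity
  full <- toy_matrix(matrix(1:8 + 0, 2, 4,
                            dimnames = list(c("a", "b"), design$sample_id)))
  expect_identical(impute_knn(full)$values, full$values)
})

test_that("kNN falls back gracefully when neighbours are scarce", {
  design <- impute_design(2)
  v <- matrix(c(1, 2, 3, NA,
                1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("g", "only"), design$sample_id))
  expect_warning(out <- impute_knn(toy_matrix(v), k = 5), "neighbour")
  expect_equal(out$values["g", 4], 4)

  lonely <- matrix(c(1, 2, 3, NA,
                     NA, NA, 9, 9), 2, 4, byrow = TRUE,
                   dimnames = list(c("g", "thin"), design$sample_id))
  expect_warning(out <- impute_knn(toy_matrix(lonely), k = 1),
                 "no eligible neighbour")
  expect_true(is.na(out$values["g", 4]))
})

test_that("SLSA fills with replicate mean plus a sample offset", {
  design <- impute_design()
  treated <- design$sample_id[design$treatment != "vehicle"]
  # symmetric case: all replicates identical per feature -> offset 0
  v <- matrix(rep(c(10, 12, 14), each = 8), 3, 8, byrow = TRUE,
              dimnames = list(c("a", "b", "gap"), design$sample_id))
  v["gap", treated[2]] <- NA
  out <- impute_slsa(toy_matrix(v), design = design)
  expect_equal(out$values["gap", treated[2]], 14)

  # sample systematically 0.5 higher: offset recovered by brute force
  v2 <- matrix(20, 5, 8, dimnames = list(sprintf("f%d", 1:5), design$sample_id))
  v2[, treated[3]] <- 20.5
  v2["f5", treated[3]] <- NA
  # brute-force offset: median over fully observed features of
  # (value in j - mean of other replicates in the condition)
  offs <- sapply(sprintf("f%d", 1:4), function(f) {
    v2[f, treated[3]] - mean(v2[f, treated[-3]])
  })
  out2 <- impute_slsa(toy_matrix(v2), design = design)
  expect_equal(unname(out2$values["f5", treated[3]]),
               mean(v2["f5", treated[-3]]) + median(offs))
  expect_equal(unname(out2$values["f5", treated[3]]), 20.5)

  # no gaps: identity
  expect_identical(impute_slsa(toy_matrix(v2[1:4, ]), design = design)$values,
                   v2[1:4, ])
})

test_that("downshift sampling draws from the shifted column distribution", {
  design <- impute_design()
  set.seed(3)
  v <- matrix(rnorm(8 * 200, 20, 2), 200, 8,
              dimnames = list(sprintf("f%d", 1:200), design$sample_id))
  gaps <- matrix(runif(length(v)) < 0.1, 200, 8)
  v_gap <- v; v_gap[gaps] <- NA

  # width 0: every imputed value is exactly mu - 1.8 sigma of its column
  out0 <- impute_downshift(toy_matrix(v_gap), width = 0, seed = 1)
  j <- which(colSums(gaps) > 0)[1]
  mu <- mean(v_gap[!gaps[, j], j]); sigma <- sd(v_gap[!gaps[, j], j])
  expect_equal(unique(round(out0$values[gaps[, j], j], 10)),
               round(mu - 1.8 * sigma, 10))

  # determinism
  a <- impute_downshift(toy_matrix(v_gap), seed = 42)
  b <- impute_downshift(toy_matrix(v_gap), seed = 42)
  expect_identical(a$values, b$values)
  expect_no_change_observed(toy_matrix(v_gap), a)
})

test_that("downshift mean sits well below the observed mean (Monte Carlo)", {
  design <- toy_design(n_knockouts = 1, n_controls = 1, n_replicates = 4)
  set.seed(9)
  n <- 2500
  v <- matrix(rnorm(n * 16, 20, 2), n, 16,
              dimnames = list(sprintf("f%d", seq_len(n)), design$sample_id))
  gaps <- matrix(runif(length(v)) < 0.25, n, 16)   # ~10,000 gaps
  v_gap <- v; v_gap[gaps] <- NA
  out <- impute_downshift(toy_matrix(v_gap), seed = 11)
  imputed <- out$values[gaps]
  obs_mean <- mean(v_gap, na.rm = TRUE)
  obs_sd <- sd(as.vector(v_gap), na.rm = TRUE)
  se3 <- 3 * sd(imputed) / sqrt(length(imputed))
  expect_lt(mean(imputed), obs_mean - obs_sd + se3)
})

test_that("mixed imputation decomposes and completes the matrix", {
  design <- impute_design()
  treated <- design$sample_id[design$treatment != "vehicle"]
  # fully observed -> identity
  set.seed(2)
  v <- matrix(rnorm(40, 20, 1), 5, 8,
              dimnames = list(sprintf("f%d", 1:5), design$sample_id))
  out <- impute_mixed(toy_matrix(v), design, mode = "global", seed = 1)
  expect_identical(out$matrix$values, v)
  expect_true(all(out$labels == "observed"))

  # only whole-block (MNAR) gaps: mixed equals downshift alone
  v2 <- v
  v2[c(1, 2), treated] <- NA
  mixed <- impute_mixed(toy_matrix(v2), design, mode = "global", seed = 7)
  down <- impute_downshift(toy_matrix(v2), seed = 7)
  expect_identical(mixed$matrix$values, down$values)

  # mixed output is gap-free and preserves observed entries bit-for-bit
  sim <- simulate_toy(seed = 31, design = toy_design(n_replicates = 4,
                                                     assay = "phospho"),
                      n_features = 300)
  gap <- apply_missingness(sim$matrix, sim$truth, sim$design)
  m <- normalize_intensity(gap$matrix)
  for (mode in c("phospho", "global")) {
    out <- suppressWarnings(impute_mixed(m, sim$design, mode = mode, seed = 3))
    expect_false(anyNA(out$matrix$values))
    expect_no_change_observed(m, out$matrix)
  }
})

test_that("imputed data preserve the differential ranking of complete data", {
  design <- toy_design(n_knockouts = 0, n_controls = 1, n_replicates = 4,
                       timepoints = 240, assay = "phospho")
  sim <- simulate_toy(seed = 17, design = design, n_features = 500,
                      induced = sprintf("ISG%02d", 1:25))
  complete <- normalize_intensity(sim$matrix)
  gap <- apply_missingness(sim$matrix, sim$truth, design)
  filt <- filter_by_replicates(normalize_intensity(gap$matrix), design,
                               min_present = c(3L, 4L))
  imp <- suppressWarnings(impute_mixed(filt, design, mode = "phospho", seed = 5))
  d_complete <- differential_table(complete, design, engine = "moderated")
  d_imputed <- differential_table(imp$matrix, design, engine = "moderated")
  shared <- intersect(d_complete$feature_id, d_imputed$feature_id)
  rho <- cor(d_complete$t_statistic[match(shared, d_complete$feature_id)],
             d_imputed$t_statistic[match(shared, d_imputed$feature_id)],
             method = "spearman")
  expect_gt(rho, 0.9)
})
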