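test_that("donor centering removes donor offsets and preserves contrasts", {
  design <- toy_design(n_knockouts = 0, n_controls = 1, n_replicates = 4,
                       timepoints = 240, donors = c("d1", "d2"))
  set.seed(5)
  v <- matrix(rnorm(10 * 8, 20, 1), 10, 8,
              dimnames = list(sprintf("f%d", 1:10), design$sample_id))

  # single donor: identity
  one_donor <- design; one_donor$donor <- "d1"
  expect_identical(center_by_donor(toy_matrix(v), one_donor)$values, v)

  # constant donor offset is removed exactly; within-donor contrasts survive
  v_off <- v
  v_off[, design$donor == "d2"] <- v_off[, design$donor == "d2"] + 3
  cen <- center_by_donor(toy_matrix(v_off), design)$values
  base <- center_by_donor(toy_matrix(v), design)$values
  expect_equal(cen, base, tolerance = 1e-12)
  for (dn in c("d1", "d2")) {
    cols <- which(design$donor == dn)
    tr <- intersect(cols, which(design$treatment != "vehicle"))
    ve <- intersect(cols, which(design$treatment == "vehicle"))
    expect_equal(rowMeans(cen[, tr, drop = FALSE]) - rowMeans(cen[, ve, drop = FALSE]),
                 rowMeans(v_off[, tr, drop = FALSE]) - rowMeans(v_off[, ve, drop = FALSE]),
                 tolerance = 1e-12)
  }

  # simulated donor effects: post-centering donor means are ~0 per feature
  sim <- simulate_toy(seed = 19, design = design, n_features = 50, donor = 1)
  cen2 <- center_by_donor(to_log2(sim$matrix), design)$values
  for (dn in c("d1", "d2")) {
    expect_equal(unname(rowMeans(cen2[, design$donor == dn])),
                 rep(0, 50), tolerance = 1e-10)
  }
})

test_that("fold changes are time-matched means and antisymmetric", {
  design <- toy_design(n_knockouts = 0, n_controls = 1, n_replicates = 4,
                       timepoints = 240)
  treated <- design$treatment != "vehicle"
  v <- matrix(NA_real_, 2, 8, dimnames = list(c("up", "flat"), design$sample_id))
  v["up", ] <- ifelse(treated, 5, 4)
  v["flat", ] <- 7
  fc <- fold_change_vs_control(toy_matrix(v), design)
  expect_equal(fc$log2fc[fc$feature_id == "up"], 1)
  expect_equal(fc$log2fc[fc$feature_id == "flat"], 0)

  # swapping the roles of the arms negates the fold change exactly
  flipped <- design
  flipped$treatment <- ifelse(design$treatment == "vehicle", "IFN-b", "vehicle")
  fc2 <- fold_change_vs_control(toy_matrix(v), flipped)
  expect_equal(fc2$log2fc[order(fc2$feature_id)],
               -fc$log2fc[order(fc$feature_id)])

  # unmatched timepoint errors with the condition named
  broken <- design[!(design$treatment == "vehicle"), ]
  v_t <- v[, broken$sample_id]
  expect_error(fold_change_vs_control(toy_matrix(v_t), broken),
               "no time-matched vehicle")
})

test_that("Student's t matches the pooled formula and handles degeneracy", {
  expect_equal(student_t(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 4, degenerate = FALSE),
               tolerance = 1e-12)
  expect_equal(student_t(c(1, 2, 3), c(3, 1, 2))$t, 0, tolerance = 1e-12)

  oracle <- pooled_t_oracle(c(0, 1), c(2, 3))
  got <- student_t(c(0, 1), c(2, 3))
  expect_equal(got$t, oracle$t, tolerance = 1e-12)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)

  degen <- student_t(c(1, 1), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(student_t(1, c(1, 2)), "at least 2")
})

test_that("Student's t holds its nominal type-I error on null data", {
  set.seed(23)
  p <- replicate(10000, student_t(rnorm(4), rnorm(4))$p)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("moderated t has the right limits in the prior degrees of freedom", {
  set.seed(7)
  a <- matrix(rnorm(50 * 4, 1, 1), 50, 4)
  b <- matrix(rnorm(50 * 4, 0, 1), 50, 4)
  rownames(a) <- rownames(b) <- sprintf("f%d", 1:50)

  plain <- vapply(1:50, function(i) student_t(a[i, ], b[i, ])$t, numeric(1))
  mod0 <- moderated_t(a, b, prior_df = 0, prior_var = 1)
  expect_equal(mod0$t, plain, tolerance = 1e-10)

  modInf <- moderated_t(a, b, prior_df = Inf, prior_var = 2)
  se <- sqrt(2 * (1 / 4 + 1 / 4))
  expect_equal(modInf$t, unname(rowMeans(a) - rowMeans(b)) / se,
               tolerance = 1e-12)
})

test_that("variance prior is recovered by method of moments", {
  set.seed(29)
  d0_true <- 8; s0_true <- 0.25; dg <- 6
  rel_err <- replicate(20, {
    sigma2 <- s0_true * d0_true / rchisq(200, d0_true)
    s2 <- sigma2 * rchisq(200, dg) / dg
    fit <- estimate_variance_prior(s2, dg)
    c(abs(fit$d0 - d0_true) / d0_true, abs(fit$s0_2 - s0_true) / s0_true)
  })
  expect_lt(median(rel_err[1, ]), 0.25)
  expect_lt(median(rel_err[2, ]), 0.25)
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(41)
  a <- matrix(rnorm(120 * 4, 0, exp(rnorm(120, 0, 0.4))), 120, 4)
  b <- matrix(rnorm(120 * 4), 120, 4)
  rownames(a) <- rownames(b) <- sprintf("f%d", 1:120)
  ours <- moderated_t(a, b)

  design_mm <- cbind(intercept = 1, treated = rep(c(1, 0), each = 4))
  fit <- limma::lmFit(cbind(a, b), design_mm)
  fit <- limma::eBayes(fit)
  expect_equal(attr(ours, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(ours, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(ours$t, fit$t[, "treated"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ours$p, fit$p.value[, "treated"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("BH adjustment equals the brute-force step-up everywhere", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  set.seed(37)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p) == bh_stepup_oracle(p), rep(TRUE, length(p)))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 0)
  }
})

test_that("differential tables control false positives and find real effects", {
  design <- toy_design(n_knockouts = 0, n_controls = 1, n_replicates = 4,
                       timepoints = 240)
  # null: no effects -> FDR-controlled discoveries
  hits <- vapply(1:10, function(s) {
    sim <- simulate_toy(seed = 100 + s, design = design, n_features = 300,
                        noise = 0.3, donor = 0)
    d <- differential_table(normalize_intensity(sim$matrix), design,
                            engine = "moderated")
    sum(d$adj_p < 0.05 & d$log2fc > 0.75)
  }, numeric(1))
  expect_lte(mean(hits / 300), 0.05 + 3 * sqrt(0.05 * 0.95 / 3000))

  # a strong spiked feature is detected
  sim <- simulate_toy(seed = 55, design = design, n_features = 300,
                      induced = "ISG01", induced_effect = 3, noise = 0.3,
                      donor = 0)
  d <- differential_table(normalize_intensity(sim$matrix), design,
                          engine = "moderated")
  spike <- d[d$feature_id == "ISG01", ]
  expect_lt(spike$adj_p, 0.05)
  expect_gt(spike$log2fc, 0.75)

  # engines agree on variance-homogeneous data once the per-feature
  # variances are well estimated (deep replication)
  design10 <- toy_design(n_knockouts = 0, n_controls = 1, n_replicates = 10,
                         timepoints = 240)
  sim2 <- simulate_toy(seed = 56, design = design10, n_features = 500,
                       noise = 0.5, donor = 0)
  m <- normalize_intensity(sim2$matrix)
  ds <- differential_table(m, design10, engine = "student")
  dm <- differential_table(m, design10, engine = "moderated")
  expect_gt(cor(ds$t_statistic, dm$t_statistic, method = "spearman"), 0.99)
})

test_that("adjusted p-values dominate raw p-values within comparisons", {
  design <- toy_design(n_replicates = 3, assay = "phospho")
  sim <- simulate_toy(seed = 61, design = design, n_features = 80)
  d <- differential_table(normalize_intensity(sim$matrix), design)
  expect_true(all(d$adj_p >= d$p_value - 1e-15))
  expect_true(all(d$adj_p <= 1))
  # order preservation within each comparison
  for (cc in unique(d$comparison)) {
    dc <- d[d$comparison == cc, ]
    expect_true(all(diff(dc$adj_p[order(dc$p_value)]) >= -1e-15))
  }
})
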