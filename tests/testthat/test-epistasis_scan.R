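test_that("fit_pair_model recovers a noiseless interaction exactly", {
  set.seed(7)
  gi <- sample(0:2, 30, replace = TRUE)
  gj <- sample(0:2, 30, replace = TRUE)
  y <- 1 + 0 * gi + 0 * gj + 0.7 * gi * gj
  f <- fit_pair_model(gi, gj, y)
  expect_equal(f$status, "ok")
  expect_equal(f$beta3, 0.7, tolerance = 1e-10)
  expect_equal(f$mu, 1, tolerance = 1e-10)
  expect_lt(f$p3, 1e-10)
})

test_that("fit_pair_model flags degenerate designs without raising", {
  gi <- c(0, 1, 2, 0, 1, 2)
  expect_equal(fit_pair_model(gi, gi, rnorm(6))$status, "collinear")
  expect_equal(fit_pair_model(gi[1:4], gi[1:4], rnorm(4))$status,
               "insufficient")
})

test_that("fit_pair_model agrees with the normal-equations oracle", {
  set.seed(15)
  for (rep in 1:10) {
    gi <- sample(0:2, 40, replace = TRUE)
    gj <- sample(0:2, 40, replace = TRUE)
    y <- rnorm(40, sd = 2)
    f <- fit_pair_model(gi, gj, y)
    o <- ols_oracle(cbind(1, gi, gj, gi * gj), y)
    expect_equal(c(f$mu, f$beta1, f$beta2, f$beta3), o$beta,
                 tolerance = 1e-8)
    expect_equal(f$p3, o$p[4], tolerance = 1e-8)
  }
})

test_that("batched scan equals the per-pair fitter elementwise", {
  for (seed in 1:5) {
    cfg <- sim_config(n_samples = 50, n_snps = 12, n_chromosomes = 2,
                      missing_rate = 0.05, seed = seed)
    gm <- simulate_genotypes(cfg)$gm
    set.seed(seed)
    y <- rnorm(50)
    er <- scan_all_pairs(gm, y)
    expect_true(isSymmetric(er$beta3))
    expect_true(isSymmetric(er$p3))
    for (i in 1:11) for (j in (i + 1):12) {
      f <- fit_pair_model(gm$values[, i], gm$values[, j], y)
      expect_identical(er$status[i, j], f$status)
      if (f$status == "ok") {
        expect_equal(er$beta3[i, j], f$beta3, tolerance = 1e-8)
        expect_equal(er$se3[i, j], f$se3, tolerance = 1e-8)
        expect_equal(er$p3[i, j], f$p3, tolerance = 1e-8)
      }
    }
  }
})

test_that("scan matrices have the documented shape and diagonal", {
  gm <- toy_gm(cbind(c(0, 1, 2, 0, 1, 1), c(1, 0, 2, 1, 0, 2),
                     c(0, 0, 1, 2, 1, 0)))
  er <- scan_all_pairs(gm, c(1.2, 0.8, 2.5, 1.1, 0.9, 1.8))
  expect_equal(dim(er$beta3), c(3, 3))
  expect_equal(diag(er$beta3), setNames(rep(0, 3), er$snp_ids))
  expect_equal(diag(er$p3), setNames(rep(1, 3), er$snp_ids))
})

test_that("sample relabeling leaves the scan invariant", {
  cfg <- sim_config(n_samples = 40, n_snps = 8, missing_rate = 0,
                    seed = 23)
  gm <- simulate_genotypes(cfg)$gm
  set.seed(23)
  y <- rnorm(40)
  er1 <- scan_all_pairs(gm, y)
  perm <- sample(40)
  gm2 <- gm_subset(gm, samples = perm)
  er2 <- scan_all_pairs(gm2, y[perm])
  expect_equal(er1$beta3, er2$beta3, tolerance = 1e-10)
  expect_equal(er1$p3, er2$p3, tolerance = 1e-10)
})

test_that("chrom_pair_overview applies the type-7 quantile per cell", {
  # constant field: every populated cell = -log10(0.01) = 2
  gm <- toy_gm(matrix(rep(c(0, 1, 2, 0, 1, 2, 1, 0), 4), 8, 4),
               chrom = c("1", "1", "2", "2"))
  er <- scan_all_pairs(gm, rnorm(8))
  er$p3[] <- 0.01; diag(er$p3) <- 1
  er$status[] <- "ok"
  ov <- chrom_pair_overview(er, 0.9)
  expect_equal(unname(ov["1", "2"]), 2)
  expect_true(isSymmetric(ov))

  # hand quantile on a constructed cell {0.5, 0.5, 1e-6}
  vals <- -log10(c(0.5, 0.5, 1e-6))
  expect_equal(quantile(vals, 0.9, type = 7, names = FALSE),
               0.30103 + 0.8 * (6 - 0.30103), tolerance = 1e-4)
})

test_that("planted cross-chromosome interactions make the hotspot cell", {
  cfg <- sim_config(n_samples = 60, n_snps = 40, n_chromosomes = 4,
                    within_block_rho = 0, missing_rate = 0,
                    maf_range = c(0.3, 0.5),
                    planted_pairs = list(list(2, 12, 1.2), list(4, 14, 1.2),
                                         list(6, 16, 1.2), list(8, 18, 1.2)),
                    noise_sd = 0.5, seed = 12)
  sg <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sg$gm, cfg)$pheno
  er <- scan_all_pairs(sg$gm, ph$fc / ph$dw)
  ov <- chrom_pair_overview(er, 0.9)
  # SNPs 1-10 on chrom 1, 11-20 on chrom 2: all planted pairs are (1,2)
  expect_equal(unname(ov["1", "2"]), max(ov, na.rm = TRUE))
  expect_gt(unname(ov["1", "2"]), max(ov[!(rownames(ov) %in% c("1", "2")),
                                         !(colnames(ov) %in% c("1", "2"))],
                                      na.rm = TRUE))
})

test_that("beta3 estimates are unbiased over replicates", {
  set.seed(41)
  bias <- numeric(200)
  for (r in seq_len(200)) {
    gi <- sample(0:2, 60, replace = TRUE, prob = c(0.36, 0.48, 0.16))
    gj <- sample(0:2, 60, replace = TRUE, prob = c(0.36, 0.48, 0.16))
    y <- 0.5 + 0.2 * gi - 0.1 * gj + 0.6 * gi * gj + rnorm(60)
    bias[r] <- fit_pair_model(gi, gj, y)$beta3 - 0.6
  }
  mc_se <- sd(bias) / sqrt(length(bias))
  expect_lt(abs(mean(bias)), 2 * mc_se + 1e-12)
})
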