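test_that("code_genotypes codes minor-allele dosage with hand-counted MAF", {
  # {AA, AA, AG}: 1 G in 6 alleles -> minor G, dosage 0,0,1, maf 1/6
  cg <- code_genotypes(c("A", "A", "A"), c("A", "A", "G"))
  expect_equal(cg$minor_allele, "G")
  expect_equal(cg$code, c(0L, 0L, 1L))
  expect_equal(cg$maf, 1 / 6)

  # monomorphic
  cg <- code_genotypes(c("A", "A"), c("A", "A"))
  expect_equal(cg$maf, 0)
  expect_equal(cg$code, c(0L, 0L))

  # exact 0.5 tie -> lexicographically smaller allele is minor
  cg <- code_genotypes(c("A", "A", "G", "A"), c("A", "G", "G", "G"))
  expect_equal(cg$minor_allele, "A")
  expect_equal(cg$maf, 0.5)
  expect_equal(cg$code, c(2L, 1L, 0L, 1L))

  # missing calls excluded from the MAF denominator
  cg <- code_genotypes(c("A", "0", "A"), c("G", "0", "A"))
  expect_true(is.na(cg$code[2]))
  expect_equal(cg$maf, 1 / 4)

  expect_error(code_genotypes(c("A", "C"), c("G", "C")), "distinct alleles")
})

test_that("PED/MAP and TPED/TFAM parse to the same coded matrix", {
  d <- withr::local_tempdir()
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(d, "t.map"))
  writeLines(c("f1 i1 0 0 0 -9 A A A G",
               "f2 i2 0 0 0 -9 A G 0 0",
               "f3 i3 0 0 0 -9 A A G G"), file.path(d, "t.ped"))
  gm <- read_plink_text(ped = file.path(d, "t.ped"),
                        map = file.path(d, "t.map"))
  expect_equal(unname(gm$values[, 1]), c(0L, 1L, 0L))
  expect_equal(unname(gm$values[, 2]), c(1L, NA, 0L))
  expect_equal(gm$snps$maf, c(1 / 6, 1 / 4))  # rs2: G freq 3/4 -> minor A
  expect_equal(gm$sample_ids, c("i1", "i2", "i3"))

  # rs2: G has frequency 3/4 so A is minor; dosage counts A copies
  expect_equal(gm$snps$minor_allele[2], "A")

  writeLines(c("1 rs1 0 100 A A A G A A",
               "1 rs2 0 200 A G 0 0 G G"), file.path(d, "t.tped"))
  writeLines(c("f1 i1 0 0 0 -9", "f2 i2 0 0 0 -9", "f3 i3 0 0 0 -9"),
             file.path(d, "t.tfam"))
  gm2 <- read_plink_text(tped = file.path(d, "t.tped"),
                         tfam = file.path(d, "t.tfam"))
  expect_identical(gm$values, gm2$values)
  expect_identical(gm$snps, gm2$snps)
})

test_that("malformed PED lines and duplicate ids raise parse errors", {
  d <- withr::local_tempdir()
  writeLines("1 rs1 0 100", file.path(d, "t.map"))
  writeLines(c("f1 i1 0 0 0 -9 A A", "f2 i2 0 0 0 -9 A"),
             file.path(d, "t.ped"))
  expect_error(read_plink_text(ped = file.path(d, "t.ped"),
                               map = file.path(d, "t.map")), "line 2")
  writeLines(c("1 rs1 0 100", "1 rs1 0 200"), file.path(d, "d.map"))
  writeLines("f1 i1 0 0 0 -9 A A A G", file.path(d, "d.ped"))
  expect_error(read_plink_text(ped = file.path(d, "d.ped"),
                               map = file.path(d, "d.map")), "duplicate")
})

test_that("write/read round-trips genotype content in both dialects", {
  cfg <- sim_config(n_samples = 15, n_snps = 40, n_chromosomes = 2,
                    missing_rate = 0.05, seed = 21)
  gm <- simulate_genotypes(cfg)$gm
  d <- withr::local_tempdir()
  for (dialect in c("ped", "tped")) {
    write_plink_text(gm, file.path(d, dialect), dialect)
    back <- if (dialect == "ped")
      read_plink_text(ped = file.path(d, "ped.ped"),
                      map = file.path(d, "ped.map"))
    else
      read_plink_text(tped = file.path(d, "tped.tped"),
                      tfam = file.path(d, "tped.tfam"))
    expect_identical(back$values, gm$values)
    expect_equal(back$snps$maf, gm$snps$maf)
    expect_equal(back$sample_ids, gm$sample_ids)
  }
})

test_that("hwe_exact_p matches the enumeration oracle and handles edges", {
  expect_equal(hwe_exact_p(5, 0, 0), 1)
  # all-het case with 10 minor alleles in 10 samples
  expect_equal(hwe_exact_p(0, 10, 0), hwe_enum_oracle(0, 10, 0),
               tolerance = 1e-12)
  # sweep over moderate tables (the exhaustive <=100-sample sweep runs in
  # the acceptance suite)
  set.seed(4)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    nAa <- sample(0:n, 1)
    naa <- if (n - nAa > 0) sample(0:(n - nAa), 1) else 0
    nAA <- n - nAa - naa
    expect_equal(hwe_exact_p(nAA, nAa, naa),
                 hwe_enum_oracle(nAA, nAa, naa), tolerance = 1e-12)
  }
})

test_that("apply_qc filters in the documented order and reports removals", {
  # SNP1 healthy; SNP2 monomorphic (maf filter); SNP3 on X (non-autosomal)
  vals <- cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  gm <- toy_gm(vals, chrom = c("1", "1", "X"))
  qc <- apply_qc(gm)
  expect_equal(qc$report$n_snps_out, 1L)
  expect_equal(qc$gm$snps$snp_id, "s01")
  expect_equal(qc$report$removals[["maf"]], 1)
  expect_equal(qc$report$removals[["non_autosomal"]], 1)

  # sample with 2 of 3 SNPs missing (call rate 1/3 <= 0.9) removed first
  vals2 <- cbind(c(0L, 1L, 2L, 1L), c(NA, 0L, 1L, 0L), c(NA, 1L, 0L, 1L))
  qc2 <- apply_qc(toy_gm(vals2))
  expect_equal(qc2$report$n_samples_out, 3L)
  expect_equal(qc2$report$removals[["sample_call_rate"]], 1)
  # remaining SNPs have full call rate on the retained samples
  expect_equal(qc2$report$n_snps_out, 3L)

  # all SNPs removed -> explicit error
  mono <- toy_gm(matrix(0L, 4, 2))
  expect_error(apply_qc(mono), "empty after QC")
})

test_that("apply_qc is idempotent", {
  cfg <- sim_config(n_samples = 30, n_snps = 60, n_chromosomes = 3,
                    maf_range = c(0.05, 0.5), missing_rate = 0.02,
                    seed = 31)
  gm <- simulate_genotypes(cfg)$gm
  q1 <- apply_qc(gm)
  q2 <- apply_qc(q1$gm)
  expect_identical(q2$gm$values, q1$gm$values)
  expect_equal(q2$report$n_snps_out, q2$report$n_snps_in)
  expect_equal(q2$report$n_samples_out, q2$report$n_samples_in)
})

test_that("MAF after coding never exceeds 0.5", {
  cfg <- sim_config(n_samples = 25, n_snps = 80, maf_range = c(0.3, 0.5),
                    n_chromosomes = 2, missing_rate = 0.05, seed = 77)
  gm <- simulate_genotypes(cfg)$gm
  expect_true(all(gm$snps$maf <= 0.5 + 1e-12))
  # and under subsetting with recode
  sub <- gm_subset(gm, samples = 1:12, recode = TRUE)
  expect_true(all(sub$snps$maf <= 0.5 + 1e-12, na.rm = TRUE))
})
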