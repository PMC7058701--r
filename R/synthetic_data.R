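#' Simulation configuration
#'
#' States the world the generator emulates: a pig-breed-sized cohort
#' genotyped on tens of thousands of array SNPs arranged in LD blocks,
#' with a feed-conversion-ratio-like trait driven by a few planted
#' additive and pairwise-interaction effects. Defaults mirror the Duroc
#' scale of the motivating design: ~60 samples, trait mean 1.96, SD
#' 0.07, autosomes labelled from "1".
#'
#' @param n_samples cohort size (default 60).
#' @param n_snps number of biallelic SNPs (default 500).
#' @param n_chromosomes autosome count to spread SNPs over (default 5).
#' @param ld_block_size SNPs per LD block (default 10).
#' @param within_block_rho latent AR(1) correlation inside a block
#'   (default 0.975, genotype r2 ~ 0.95).
#' @param maf_range minor-allele-frequency range (default c(0.1, 0.5)).
#' @param planted_pairs list of `list(i, j, beta3)` interaction effects
#'   (SNP indices).
#' @param planted_mains list of `list(i, beta1)` additive effects.
#' @param mu trait model intercept before rescaling (default 0).
#' @param noise_sd residual SD before rescaling (default 1).
#' @param trait_target_mean,trait_target_sd scale of the emitted
#'   FCR-like trait (defaults 1.96 and 0.07).
#' @param missing_rate genotype missingness (default 0.01).
#' @param seed integer master seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 60, n_snps = 500, n_chromosomes = 5,
                       ld_block_size = 10, within_block_rho = 0.975,
                       maf_range = c(0.1, 0.5), planted_pairs = list(),
                       planted_mains = list(), mu = 0, noise_sd = 1,
                       trait_target_mean = 1.96, trait_target_sd = 0.07,
                       missing_rate = 0.01, seed = 1) {
  stopifnot(noise_sd >= 0, within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  for (pp in planted_pairs)
    stopifnot(pp[[1]] <= n_snps, pp[[2]] <= n_snps, pp[[1]] != pp[[2]])
  for (pm in planted_mains) stopifnot(pm[[1]] <= n_snps)
  structure(list(
    n_samples = n_samples, n_snps = n_snps, n_chromosomes = n_chromosomes,
    ld_block_size = ld_block_size, within_block_rho = within_block_rho,
    maf_range = maf_range, planted_pairs = planted_pairs,
    planted_mains = planted_mains, mu = mu, noise_sd = noise_sd,
    trait_target_mean = trait_target_mean,
    trait_target_sd = trait_target_sd, missing_rate = missing_rate,
    seed = seed), class = "sim_config")
}

## Deterministic sub-seeds: stream k of the master seed.
sub_seed <- function(seed, k) (seed * 101L + k * 7919L) %% 2147483647L

#' Simulate genotypes with LD blocks
#'
#' Gaussian-copula construction: per LD block a latent AR(1) normal is
#' drawn per sample and thresholded at the Hardy-Weinberg genotype
#' quantiles for each SNP's target MAF, producing 0/1/2 dosages with
#' controlled LD. Blocks are independent and never span chromosomes.
#' Missing calls are masked at `missing_rate`. Coding is re-oriented so
#' the stored dosage always counts the realized minor allele.
#'
#' @param config sim_config.
#' @return list with `gm` (genotype_matrix) and `truth` (target MAFs
#'   and block assignment).
#' @export
simulate_genotypes <- function(config) {
  cf <- config
  set.seed(sub_seed(cf$seed, 1L))
  n <- cf$n_samples; p <- cf$n_snps
  per_chrom <- ceiling(p / cf$n_chromosomes)
  chrom <- as.character(rep(seq_len(cf$n_chromosomes),
                            each = per_chrom)[seq_len(p)])
  idx_in_chrom <- unlist(lapply(rle(chrom)$lengths, seq_len))
  block <- paste0(chrom, "_", (idx_in_chrom - 1) %/% cf$ld_block_size)
  # alleles in strong LD co-segregate, so SNPs of one block share a base
  # MAF up to small jitter; without this, thresholding at different
  # quantiles caps the attainable genotype r2 well below the latent rho
  ublock <- unique(block)
  block_maf <- setNames(runif(length(ublock), cf$maf_range[1],
                              cf$maf_range[2]), ublock)
  maf <- pmin(pmax(block_maf[block] + rnorm(p, 0, 0.01),
                   cf$maf_range[1]), cf$maf_range[2])
  maf <- unname(maf)
  vals <- matrix(NA_integer_, n, p)
  rho <- cf$within_block_rho
  for (b in unique(block)) {
    js <- which(block == b)
    m <- length(js)
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho > 0)
      for (k in 2:m) z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * z[, k]
    for (k in seq_along(js)) {
      q <- maf[js[k]]
      t1 <- qnorm((1 - q)^2)      # below: homozygote major
      t2 <- qnorm(1 - q^2)        # above: homozygote minor
      vals[, js[k]] <- (z[, k] >= t1) + (z[, k] >= t2)
    }
  }
  if (cf$missing_rate > 0) {
    miss <- matrix(runif(n * p) < cf$missing_rate, n, p)
    vals[miss] <- NA_integer_
  }
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(p)), chrom = chrom,
    pos_bp = idx_in_chrom * 10000L,
    allele_a = "A", allele_b = "B", minor_allele = "B",
    maf = NA_real_, stringsAsFactors = FALSE)
  gm <- gm_recode(genotype_matrix(
    vals, snps, sprintf("S%03d", seq_len(cf$n_samples))))
  list(gm = gm, truth = list(target_maf = maf, block = block))
}

#' Simulate phenotypes with planted effects
#'
#' The raw trait follows the pairwise interaction model
#' y = mu + sum beta1 g + sum beta3 g_i g_j + N(0, noise_sd^2)
#' (missing dosages mean-imputed for the signal), then is affinely
#' rescaled to the FCR target mean/SD. Feed records are back-filled so
#' that fc / dw reproduces the trait exactly; daily feed intake is
#' linear in daily gain plus a trait-linked residual so RFI carries
#' signal.
#'
#' @param gm genotype_matrix from [simulate_genotypes()].
#' @param config sim_config.
#' @return list with `pheno` (phenotype data.frame) and `truth`
#'   (realized variance decomposition).
#' @export
simulate_phenotypes <- function(gm, config) {
  cf <- config
  set.seed(sub_seed(cf$seed, 2L))
  n <- nrow(gm$values)
  G <- gm$values
  for (j in seq_len(ncol(G))) {
    mj <- is.na(G[, j])
    if (any(mj)) G[mj, j] <- mean(G[, j], na.rm = TRUE)
  }
  signal <- rep(cf$mu, n)
  for (pm in cf$planted_mains)
    signal <- signal + pm[[2]] * G[, pm[[1]]]
  for (pp in cf$planted_pairs)
    signal <- signal + pp[[3]] * G[, pp[[1]]] * G[, pp[[2]]]
  eps <- rnorm(n, 0, cf$noise_sd)
  y_raw <- signal + eps
  s <- sd(y_raw)
  y <- if (s > 0) (y_raw - mean(y_raw)) / s * cf$trait_target_sd +
         cf$trait_target_mean
       else rep(cf$trait_target_mean, n)
  dw <- rnorm(n, 65, 8)
  test_days <- round(runif(n, 41, 70))
  fc <- y * dw
  dw_per_day <- dw / test_days
  initial_weight <- rnorm(n, 28, 1)
  z <- if (s > 0) (y_raw - mean(y_raw)) / s else rep(0, n)
  dfi <- 1.0 + 1.1 * dw_per_day + 0.08 * z + rnorm(n, 0, 0.04)
  pheno <- data.frame(
    sample_id = gm$sample_ids, fc = fc, dw = dw, dfi = dfi,
    initial_weight = initial_weight, test_days = test_days,
    dw_per_day = dw_per_day,
    age_days = round(rnorm(n, 125, 3)),
    stringsAsFactors = FALSE)
  var_sig <- var(signal); var_tot <- var(y_raw)
  list(pheno = pheno,
       truth = list(signal_variance_fraction =
                      if (var_tot > 0) var_sig / var_tot else NA_real_))
}

#' Planted two-module interaction-coefficient matrix
#'
#' Builds a symmetric coefficient matrix with dense within-module
#' entries drawn N(`within_mean`, `within_sd`) and background entries
#' N(0, `bg_sd`) — the planted-partition benchmark for the module
#' detection stage.
#'
#' @param n_snps matrix size.
#' @param module_sizes integer vector of planted module sizes.
#' @param within_mean,within_sd within-module coefficient distribution
#'   (defaults 0.8, 0.1).
#' @param bg_sd background SD (default 0.05).
#' @param seed integer seed.
#' @return list with `beta3` (symmetric, zero diagonal) and `truth`
#'   (integer labels; 0 = background).
#' @export
simulate_beta3_modules <- function(n_snps = 500, module_sizes = c(50, 50),
                                   within_mean = 0.8, within_sd = 0.1,
                                   bg_sd = 0.05, seed = 1) {
  stopifnot(sum(module_sizes) <= n_snps)
  set.seed(sub_seed(seed, 3L))
  b <- matrix(rnorm(n_snps^2, 0, bg_sd), n_snps, n_snps)
  labels <- rep(0L, n_snps)
  at <- 1L
  for (m in seq_along(module_sizes)) {
    ix <- at:(at + module_sizes[m] - 1L)
    labels[ix] <- m
    b[ix, ix] <- rnorm(module_sizes[m]^2, within_mean, within_sd)
    at <- at + module_sizes[m]
  }
  b <- (b + t(b)) / 2
  diag(b) <- 0
  ids <- sprintf("snp%04d", seq_len(n_snps))
  dimnames(b) <- list(ids, ids)
  list(beta3 = b, truth = setNames(labels, ids))
}

#' Write a complete simulated fixture to disk
#'
#' Profiles: `tiny` (20 x 50), `standard` (60 x 500), `breedlike`
#' (59 x 5000, Duroc-sized). Writes PED/MAP, TPED/TFAM, a phenotype
#' TSV, a toy GFF3 annotation covering part of each chromosome, and the
#' ground truth as JSON. Byte-identical across runs at a fixed seed.
#'
#' @param profile one of "tiny", "standard", "breedlike".
#' @param dir output directory (created).
#' @param seed master seed (default 1).
#' @param config optional sim_config overriding the profile.
#' @return invisibly, the named list of written paths.
#' @export
make_fixture <- function(profile = c("tiny", "standard", "breedlike"),
                         dir, seed = 1, config = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) {
    config <- switch(profile,
      tiny = sim_config(n_samples = 20, n_snps = 50, n_chromosomes = 2,
                        planted_pairs = list(list(1, 11, 0.8)),
                        seed = seed),
      standard = sim_config(planted_pairs = list(list(1, 11, 0.8),
                                                 list(3, 15, 0.8),
                                                 list(5, 18, 0.8)),
                            seed = seed),
      breedlike = sim_config(n_samples = 59, n_snps = 5000,
                             n_chromosomes = 18,
                             planted_pairs = list(list(1, 101, 0.8),
                                                  list(501, 1001, 0.8)),
                             seed = seed))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sg <- simulate_genotypes(config)
  sp <- simulate_phenotypes(sg$gm, config)
  paths <- list()
  write_plink_text(sg$gm, file.path(dir, "genotypes"), "ped")
  write_plink_text(sg$gm, file.path(dir, "genotypes"), "tped")
  paths$ped <- file.path(dir, "genotypes.ped")
  paths$map <- file.path(dir, "genotypes.map")
  paths$tped <- file.path(dir, "genotypes.tped")
  paths$tfam <- file.path(dir, "genotypes.tfam")
  paths$pheno <- file.path(dir, "phenotypes.tsv")
  write.table(sp$pheno, paths$pheno, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # toy annotation: 3 genes per chromosome tiling the low positions
  chroms <- unique(sg$gm$snps$chrom)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, start = c(5000L, 50000L, 120000L),
               end = c(30000L, 90000L, 150000L),
               gene_id = paste0("G", ch, "_", 1:3), stringsAsFactors = FALSE)
  }))
  paths$gff <- file.path(dir, "annotation_synthetic.gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       genes$chrom, genes$start, genes$end,
                       rep(c("+", "-", "+"), length(chroms)),
                       genes$gene_id, genes$gene_id)), paths$gff)
  paths$truth <- file.path(dir, "truth.json")
  truth <- list(
    profile = profile,
    config = unclass(config),
    realized_maf = sg$gm$snps$maf,
    block = sg$truth$block,
    signal_variance_fraction = sp$truth$signal_variance_fraction)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
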