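#' Single-SNP quantitative-trait association
#'
#' Ordinary least-squares regression of the trait on the minor-allele
#' dosage with an intercept; the reported p-value is the two-sided t-test
#' on the slope. Samples missing either the genotype or the trait are
#' dropped (per-SNP complete case). A genotype that is constant among the
#' usable samples is flagged untestable (p = 1, beta = NA) rather than
#' raising an error, so a scan over many SNPs never aborts.
#'
#' @param g coded genotype column (0/1/2, NA missing).
#' @param y trait vector.
#' @return list with `beta`, `se`, `t_stat`, `p`, `n_used`, `testable`.
#' @export
single_snp_assoc <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  n <- sum(ok)
  untestable <- list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                     p = 1, n_used = n, testable = FALSE)
  if (n < 3) return(untestable)
  g <- g[ok]; y <- y[ok]
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) return(untestable)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (g - mean(g))
  df <- n - 2
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  t_stat <- if (se == 0) sign(beta) * Inf else beta / se
  p <- 2 * pt(-abs(t_stat), df)
  list(beta = beta, se = se, t_stat = t_stat, p = max(p, .Machine$double.xmin),
       n_used = n, testable = TRUE)
}

#' Association scan over all SNPs
#'
#' @param gm genotype_matrix.
#' @param trait numeric trait vector aligned with `gm$sample_ids`.
#' @return data.frame with one row per SNP: `snp_id`, `chrom`, `pos_bp`,
#'   `beta`, `se`, `t_stat`, `p`, `n_used`, `testable`.
#' @export
assoc_scan <- function(gm, trait) {
  stopifnot(length(trait) == nrow(gm$values))
  res <- lapply(seq_len(ncol(gm$values)), function(j)
    single_snp_assoc(gm$values[, j], trait))
  out <- data.frame(
    snp_id = gm$snps$snp_id, chrom = gm$snps$chrom, pos_bp = gm$snps$pos_bp,
    beta = vapply(res, `[[`, 0, "beta"),
    se = vapply(res, `[[`, 0, "se"),
    t_stat = vapply(res, `[[`, 0, "t_stat"),
    p = vapply(res, `[[`, 0, "p"),
    n_used = vapply(res, `[[`, 0L, "n_used"),
    testable = vapply(res, `[[`, TRUE, "testable"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top-K associated SNPs
#'
#' SNPs are ranked by ascending p-value, ties broken by descending
#' absolute t statistic, then snp_id. Untestable SNPs rank after all
#' testable ones. The returned ids preserve genome order (the order of
#' `assoc` rows), so a matrix subset by them stays position-sorted.
#'
#' @param assoc data.frame from [assoc_scan()].
#' @param k number of SNPs to keep (default 7000).
#' @return character vector of snp_ids, in genome order.
#' @export
select_top_k <- function(assoc, k = 7000) {
  stopifnot(k >= 1)
  abs_t <- abs(assoc$t_stat)
  abs_t[is.na(abs_t)] <- -Inf
  ord <- order(!assoc$testable, assoc$p, -abs_t, assoc$snp_id)
  chosen <- ord[seq_len(min(k, nrow(assoc)))]
  assoc$snp_id[sort(chosen)]
}

#' Write association results as TSV
#' @param assoc data.frame from [assoc_scan()].
#' @param path output file.
#' @export
write_assoc <- function(assoc, path) {
  write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
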