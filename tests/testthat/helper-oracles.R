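# Shared independent oracles and small utilities for the test suite.

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

# HWE exact test by direct log-factorial enumeration of the conditional
# distribution of the heterozygote count given allele counts -- an
# independent route from the package's recurrence.
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * naa + nAa          # minor-allele count (either allele works)
  na <- min(na, 2 * n - na)
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  lp <- vapply(hets, function(h) {
    nr <- (na - h) / 2
    nc <- n - h - nr
    lfactorial(n) - lfactorial(nr) - lfactorial(nc) - lfactorial(h) +
      h * log(2)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(nAa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

# OLS by explicit normal equations (solve(t(X)X) t(X)y) with slope t-test:
# the brute-force route used against lm.fit/QR-based code.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  t <- b / se
  list(beta = unname(drop(b)), se = unname(se), t = unname(drop(t)),
       p = unname(2 * pt(-abs(drop(t)), df)))
}

# Small genotype matrix built directly from a dosage matrix.
toy_gm <- function(vals, chrom = NULL, pos = NULL) {
  vals <- as.matrix(vals)
  p <- ncol(vals)
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p) * 1000
  maf <- apply(vals, 2, function(g) sum(g, na.rm = TRUE) /
                                    (2 * sum(!is.na(g))))
  genotype_matrix(vals,
                  data.frame(snp_id = sprintf("s%02d", seq_len(p)),
                             chrom = chrom, pos_bp = pos,
                             allele_a = "A", allele_b = "B",
                             minor_allele = "B", maf = maf,
                             stringsAsFactors = FALSE),
                  sprintf("ind%02d", seq_len(nrow(vals))))
}
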