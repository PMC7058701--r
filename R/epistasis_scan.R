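#' Fit the pairwise interaction (heterogeneity) model for one SNP pair
#'
#' Ordinary least squares of the trait on
#' \deqn{y = \mu + \beta_1 g_i + \beta_2 g_j + \beta_3 (g_i g_j) + \epsilon}
#' with the genotypes coded as minor-allele dosage (0/1/2). The epistatic
#' effect is the product-term coefficient \eqn{\beta_3}, tested two-sided
#' with a t statistic on `n_used - 4` degrees of freedom. Samples missing
#' either genotype or the trait are dropped (complete case per pair).
#'
#' @param gi,gj coded genotype columns.
#' @param y trait vector.
#' @return list with `mu`, `beta1`, `beta2`, `beta3`, `se3`, `t3`, `p3`,
#'   `n_used`, `status` in `{"ok", "collinear", "insufficient"}`.
#' @export
fit_pair_model <- function(gi, gj, y) {
  ok <- !is.na(gi) & !is.na(gj) & !is.na(y)
  n <- sum(ok)
  base <- list(mu = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
               beta3 = NA_real_, se3 = NA_real_, t3 = NA_real_,
               p3 = NA_real_, n_used = n, status = "insufficient")
  if (n < 5) return(base)
  X <- cbind(1, gi[ok], gj[ok], gi[ok] * gj[ok])
  fit <- lm.fit(X, y[ok])
  if (fit$rank < 4) { base$status <- "collinear"; return(base) }
  b <- unname(fit$coefficients)
  df <- n - 4
  rss <- sum(fit$residuals^2)
  # (X'X)^-1 from the QR factor
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  se3 <- sqrt(rss / df * xtx_inv[4, 4])
  t3 <- if (se3 == 0) sign(b[4]) * Inf else b[4] / se3
  p3 <- max(2 * pt(-abs(t3), df), .Machine$double.xmin)
  list(mu = b[1], beta1 = b[2], beta2 = b[3], beta3 = b[4],
       se3 = se3, t3 = t3, p3 = p3, n_used = n, status = "ok")
}

#' Scan all SNP pairs for epistasis
#'
#' Fits the pairwise interaction model to every unordered SNP pair. The
#' computation is batched: all cross-product sums entering the 4x4 normal
#' equations are obtained from a handful of matrix products over the
#' missingness-masked genotype matrix, then each pair's system is solved
#' directly. Results agree elementwise with [fit_pair_model()].
#'
#' @param gm genotype_matrix (typically the LD-pruned top-K set).
#' @param trait numeric trait vector aligned with samples; samples with a
#'   missing trait are dropped up front.
#' @return an `epistasis_result`: list of symmetric matrices `beta3`,
#'   `se3`, `t3`, `p3`, `n_used`, character `status`, plus `snp_ids` and
#'   the SNP metadata `snps`. Diagonal convention: beta3 = 0, p3 = 1,
#'   status "ok".
#' @export
scan_all_pairs <- function(gm, trait) {
  stopifnot(length(trait) == nrow(gm$values))
  keep <- !is.na(trait)
  G <- gm$values[keep, , drop = FALSE]
  y <- trait[keep]
  p <- ncol(G)
  if (p < 2) stop("need at least 2 SNPs")
  M <- 1 * !is.na(G)
  G0 <- G; G0[is.na(G0)] <- 0L
  storage.mode(G0) <- "double"
  G2 <- G0 * G0

  N   <- crossprod(M)            # pair sample counts
  Si  <- crossprod(G0, M)        # sum g_i over j-present samples
  Sii <- crossprod(G2, M)
  Sij <- crossprod(G0)           # sum g_i g_j
  Siij <- crossprod(G2, G0)      # sum g_i^2 g_j
  Siijj <- crossprod(G2)         # sum g_i^2 g_j^2
  yM <- y * M
  Sy  <- crossprod(M, yM)        # sum y over pair-complete samples
  Syy <- crossprod(M, y * yM)
  Siy <- crossprod(G0, yM)       # sum g_i y
  Sijy <- crossprod(G0, y * G0)  # sum g_i g_j y

  beta3 <- se3 <- t3 <- matrix(NA_real_, p, p)
  p3 <- matrix(NA_real_, p, p)
  nmat <- matrix(0L, p, p)
  status <- matrix("insufficient", p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      n <- N[i, j]
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 5) next
      A <- matrix(c(n,        Si[i, j],  Si[j, i],   Sij[i, j],
                    Si[i, j], Sii[i, j], Sij[i, j],  Siij[i, j],
                    Si[j, i], Sij[i, j], Sii[j, i],  Siij[j, i],
                    Sij[i, j], Siij[i, j], Siij[j, i], Siijj[i, j]),
                  4, 4)
      xty <- c(Sy[i, j], Siy[i, j], Siy[j, i], Sijy[i, j])
      Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
      if (is.null(Ainv) || !all(is.finite(Ainv)) ||
          max(abs(Ainv)) > 1e12) {
        status[i, j] <- status[j, i] <- "collinear"
        next
      }
      b <- drop(Ainv %*% xty)
      rss <- max(Syy[i, j] - sum(b * xty), 0)
      df <- n - 4
      s3 <- sqrt(rss / df * Ainv[4, 4])
      tt <- if (s3 == 0) sign(b[4]) * Inf else b[4] / s3
      pv <- max(2 * pt(-abs(tt), df), .Machine$double.xmin)
      beta3[i, j] <- beta3[j, i] <- b[4]
      se3[i, j] <- se3[j, i] <- s3
      t3[i, j] <- t3[j, i] <- tt
      p3[i, j] <- p3[j, i] <- pv
      status[i, j] <- status[j, i] <- "ok"
    }
  }
  diag(beta3) <- 0; diag(p3) <- 1; diag(status) <- "ok"
  diag(nmat) <- as.integer(diag(N))
  ids <- gm$snps$snp_id
  dimnames(beta3) <- dimnames(se3) <- dimnames(t3) <- dimnames(p3) <-
    dimnames(status) <- dimnames(nmat) <- list(ids, ids)
  structure(list(snp_ids = ids, snps = gm$snps, beta3 = beta3, se3 = se3,
                 t3 = t3, p3 = p3, n_used = nmat, status = status),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  nok <- sum(x$status[upper.tri(x$status)] == "ok")
  cat(sprintf("epistasis_result: %d SNPs, %d pairs (%d ok)\n",
              length(x$snp_ids), choose(length(x$snp_ids), 2), nok))
  invisible(x)
}

#' Chromosome-pair interaction overview
#'
#' For every chromosome pair (a, b), the q-quantile (type-7, linear
#' interpolation) of -log10(p3) over all ok pairs with one SNP on a and
#' the other on b (a = b allowed). High cells mark interaction hotspots.
#'
#' @param er epistasis_result from [scan_all_pairs()].
#' @param q quantile in (0, 1), default 0.9.
#' @return symmetric chromosome x chromosome matrix; cells with no
#'   eligible pair are NA.
#' @export
chrom_pair_overview <- function(er, q = 0.9) {
  stopifnot(q > 0, q < 1)
  chroms <- unique(er$snps$chrom)
  k <- length(chroms)
  out <- matrix(NA_real_, k, k, dimnames = list(chroms, chroms))
  ci <- match(er$snps$chrom, chroms)
  ut <- which(upper.tri(er$p3), arr.ind = TRUE)
  ok <- er$status[ut] == "ok"
  ut <- ut[ok, , drop = FALSE]
  mlp <- -log10(er$p3[ut])
  ca <- pmin(ci[ut[, 1]], ci[ut[, 2]])
  cb <- pmax(ci[ut[, 1]], ci[ut[, 2]])
  for (grp in split(seq_along(mlp), paste(ca, cb))) {
    a <- ca[grp[1]]; b <- cb[grp[1]]
    val <- quantile(mlp[grp], probs = q, type = 7, names = FALSE)
    out[a, b] <- out[b, a] <- val
  }
  out
}

#' Write an epistasis result as a pair-list TSV
#' @param er epistasis_result.
#' @param path output file.
#' @param p_max optional: only write pairs with p3 <= p_max.
#' @export
write_epistasis <- function(er, path, p_max = 1) {
  ut <- which(upper.tri(er$beta3), arr.ind = TRUE)
  df <- data.frame(snp_i = er$snp_ids[ut[, 1]], snp_j = er$snp_ids[ut[, 2]],
                   beta3 = er$beta3[ut], se3 = er$se3[ut], p3 = er$p3[ut],
                   status = er$status[ut], stringsAsFactors = FALSE)
  df <- df[is.na(df$p3) | df$p3 <= p_max, ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
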