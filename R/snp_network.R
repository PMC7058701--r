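## WGCNA-style module color sequence, largest module first.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white")

#' Signed weighted adjacency from an interaction-coefficient matrix
#'
#' The pairwise epistatic coefficients are normalized into \[-1, 1\] by the
#' maximum absolute off-diagonal value (or a high quantile, to resist
#' outliers) and passed through the signed soft-threshold transform
#' a = ((1 + s) / 2)^beta. Cells whose pair fit failed get s = 0
#' (a = 0.5^beta, the neutral weight). Diagonal is forced to 0.
#'
#' @param beta3 symmetric coefficient matrix (NAs allowed for failed fits).
#' @param power_beta soft-threshold power (>= 1).
#' @param status optional status matrix; non-"ok" cells are neutralized.
#' @param normalization `"max"` or `"quantile"` (clips at the 99.5th
#'   percentile of |beta3| before scaling).
#' @return list with `adjacency` (in \[0,1\]), `power_beta` and
#'   `normalization_constant`.
#' @export
signed_adjacency <- function(beta3, power_beta, status = NULL,
                             normalization = c("max", "quantile")) {
  normalization <- match.arg(normalization)
  stopifnot(power_beta >= 1, nrow(beta3) == ncol(beta3))
  b <- beta3
  if (!is.null(status)) b[status != "ok"] <- NA
  off <- abs(b[upper.tri(b)])
  off <- off[!is.na(off)]
  if (length(off) == 0 || max(off) == 0)
    stop("no interaction signal: all coefficients zero or failed")
  norm_c <- if (normalization == "max") max(off)
            else quantile(off, 0.995, names = FALSE)
  s <- b / norm_c
  s[is.na(s)] <- 0
  s <- pmin(pmax(s, -1), 1)
  a <- ((1 + s) / 2)^power_beta
  diag(a) <- 0
  dimnames(a) <- dimnames(beta3)
  list(adjacency = a, power_beta = power_beta,
       normalization_constant = norm_c)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity vector into equal-width bins and regresses
#' log10 frequency on log10 mean connectivity. The returned `r2` is
#' signed as in the usual soft-threshold diagnostics: positive slope
#' (anti-scale-free) yields a negative value.
#'
#' @param k connectivity vector.
#' @param n_bins number of bins (default 10).
#' @return list with `r2` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins || diff(range(k)) == 0)
    return(list(r2 = 0, slope = NA_real_))
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mk <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = NA_real_))
  x <- log10(mk[keep]); yv <- log10(freq[keep] / sum(freq[keep]))
  fit <- lm(yv ~ x)
  sl <- coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(r2 = unname(-sign(sl) * r2), slope = unname(sl))
}

#' Pick the soft-threshold power
#'
#' Returns the smallest candidate power whose signed scale-free fit R2
#' reaches `target_r2`; if none qualifies, falls back to 12 with a
#' warning (a conventional default for signed networks).
#'
#' @param beta3 coefficient matrix (see [signed_adjacency()]).
#' @param candidates candidate powers.
#' @param target_r2 required fit (default 0.8).
#' @param status optional status matrix.
#' @return list with `power_beta`, `fit_table` (power, r2, slope).
#' @export
pick_power <- function(beta3, candidates = seq(2, 20, by = 2),
                       target_r2 = 0.8, status = NULL) {
  fits <- lapply(candidates, function(pw) {
    adj <- signed_adjacency(beta3, pw, status = status)$adjacency
    scale_free_fit(rowSums(adj))
  })
  tab <- data.frame(power = candidates,
                    r2 = vapply(fits, `[[`, 0, "r2"),
                    slope = vapply(fits, `[[`, 0, "slope"))
  ok <- which(tab$r2 >= target_r2)
  if (length(ok) == 0) {
    warning("no candidate power reaches scale-free fit R2 >= ", target_r2,
            "; falling back to 12")
    return(list(power_beta = 12, fit_table = tab))
  }
  list(power_beta = candidates[ok[1]], fit_table = tab)
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' unit diagonal. The clustering dissimilarity is 1 - TOM.
#'
#' @param adjacency symmetric matrix in \[0,1\] with zero diagonal.
#' @return TOM matrix in \[0,1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  stopifnot(isSymmetric(unname(a)), all(a >= 0), all(a <= 1))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2   # guard against round-off asymmetry
  pmin(pmax(tom, 0), 1)
}

#' Detect SNP modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering followed by a deterministic
#' adaptive cut. The tree is cut at the mean off-diagonal dissimilarity
#' (so a module is a branch that coheres more tightly than the average
#' SNP pair), and each resulting cluster is kept only if it has at least
#' `min_module_size` members and passes a cohesion gate: mean
#' within-cluster dissimilarity <= `tightness` times the overall mean.
#' The default gate of 0.99 is calibrated to the near-1 TOM
#' dissimilarities that estimated interaction matrices produce: genuine
#' modules sit a few percent below the background mean, while the large
#' loose clusters that average linkage forms on pure noise stay within
#' a fraction of a percent of it.
#' The gate discards the large, loose clusters that average linkage
#' produces on structureless input, so pure-noise networks come out
#' almost entirely "grey". Everything rejected is labelled "grey";
#' modules get the conventional color labels in decreasing size order.
#'
#' @param dissim symmetric dissimilarity matrix (1 - TOM).
#' @param min_module_size smallest admissible module (default 30).
#' @param cut_height explicit cut height; default NULL = mean
#'   off-diagonal dissimilarity.
#' @param tightness cohesion gate relative to the background (default
#'   0.99).
#' @return a `module_partition`: list with `assignment` (named character
#'   vector, snp -> color), `hclust`, and the parameters.
#' @export
cluster_and_cut <- function(dissim, min_module_size = 30,
                            cut_height = NULL, tightness = 0.99) {
  stopifnot(min_module_size >= 3)
  n <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- paste0("snp", seq_len(n))
  if (n < min_module_size) {
    warning("fewer SNPs than min_module_size; all grey")
    return(new_partition(setNames(rep("grey", n), ids), NULL,
                         min_module_size))
  }
  hc <- hclust(as.dist(dissim), method = "average")
  overall <- mean(dissim[upper.tri(dissim)])
  h <- if (is.null(cut_height)) overall else cut_height
  cl <- cutree(hc, h = h)
  sizes <- table(cl)
  keep <- character(0)
  for (cid in names(sizes)) {
    if (sizes[[cid]] < min_module_size) next
    ix <- which(cl == as.integer(cid))
    within <- mean(dissim[ix, ix][upper.tri(diag(length(ix)))])
    if (within <= tightness * overall) keep <- c(keep, cid)
  }
  assignment <- setNames(rep("grey", n), ids)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (m in seq_along(keep)) {
      lab <- if (m <= length(MODULE_COLORS)) MODULE_COLORS[m]
             else paste0("module", m)
      assignment[cl == as.integer(keep[m])] <- lab
    }
  }
  new_partition(assignment, hc, min_module_size)
}

new_partition <- function(assignment, hc, min_module_size) {
  structure(list(assignment = assignment, hclust = hc,
                 min_module_size = min_module_size),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(x$assignment), decreasing = TRUE)
  cat(sprintf("module_partition: %d SNPs, %d modules (+grey)\n",
              length(x$assignment),
              sum(names(tab) != "grey")))
  print(tab)
  invisible(x)
}

#' Module eigenSNP
#'
#' First principal component of the module's standardized genotype
#' submatrix across samples: missing dosages are mean-imputed, each SNP
#' column is z-scored, and the first left singular vector is scaled to
#' unit standard deviation. The sign is anchored so the eigenSNP
#' correlates non-negatively with the mean standardized genotype.
#'
#' @param X samples x SNPs dosage matrix for one module.
#' @return list with `eigensnp` (length n_samples, mean 0, SD 1) and
#'   `variance_explained`.
#' @export
eigen_snp <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  for (j in seq_len(ncol(X))) {
    mj <- is.na(X[, j])
    if (any(mj)) X[mj, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance column(s) in module")
    X <- X[, v > 0, drop = FALSE]
    if (ncol(X) < 2) stop("module degenerate after dropping constant SNPs")
  }
  Z <- scale(X)
  sv <- svd(Z, nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (cor(e, rowMeans(Z)) < 0) e <- -e
  e <- e / sd(e)
  list(eigensnp = e, variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' EigenSNPs for every module of a partition
#'
#' @param gm genotype_matrix covering the partitioned SNPs.
#' @param partition module_partition.
#' @return list with `me` (samples x modules matrix, columns named
#'   `ME<color>`) and `variance_explained` (named vector). "grey" is
#'   skipped.
#' @export
eigen_snp_set <- function(gm, partition) {
  mods <- setdiff(unique(partition$assignment), "grey")
  mods <- names(sort(table(partition$assignment)[mods], decreasing = TRUE))
  if (length(mods) == 0)
    return(list(me = matrix(numeric(0), nrow(gm$values), 0),
                variance_explained = numeric(0)))
  me <- matrix(NA_real_, nrow(gm$values), length(mods),
               dimnames = list(gm$sample_ids, paste0("ME", mods)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in seq_along(mods)) {
    ids <- names(partition$assignment)[partition$assignment == mods[m]]
    es <- eigen_snp(gm$values[, ids, drop = FALSE])
    me[, m] <- es$eigensnp
    ve[m] <- es$variance_explained
  }
  list(me = me, variance_explained = ve)
}

#' Merge modules with strongly correlated eigenSNPs
#'
#' Iteratively merges the module pair whose eigenSNP correlation is
#' highest, while it is >= 1 - `cut_height`; eigenSNPs are recomputed
#' after each merge until a fixed point. The merged module keeps the
#' label of the larger member.
#'
#' @param partition module_partition.
#' @param gm genotype_matrix covering the partitioned SNPs.
#' @param cut_height merge threshold on 1 - correlation (default 0.25).
#' @return updated module_partition.
#' @export
merge_close_modules <- function(partition, gm, cut_height = 0.25) {
  repeat {
    mods <- setdiff(unique(partition$assignment), "grey")
    if (length(mods) < 2) break
    es <- eigen_snp_set(gm, partition)
    cc <- cor(es$me)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] < 1 - cut_height) break
    a <- sub("^ME", "", colnames(cc)[mx[1]])
    b <- sub("^ME", "", colnames(cc)[mx[2]])
    sizes <- table(partition$assignment)
    from <- if (sizes[[a]] >= sizes[[b]]) b else a
    into <- if (from == a) b else a
    partition$assignment[partition$assignment == from] <- into
  }
  partition
}

#' Soft connectivity
#'
#' Per-SNP sum of adjacency weights to all other SNPs; high values mark
#' hub SNPs.
#'
#' @param adjacency adjacency matrix (zero diagonal).
#' @param partition optional module_partition for module labels.
#' @return data.frame `snp_id`, `connectivity`, `module`, sorted by
#'   module then descending connectivity.
#' @export
soft_connectivity <- function(adjacency, partition = NULL) {
  k <- rowSums(adjacency)
  ids <- rownames(adjacency)
  if (is.null(ids)) ids <- paste0("snp", seq_along(k))
  mod <- if (is.null(partition)) rep(NA_character_, length(k))
         else unname(partition$assignment[ids])
  out <- data.frame(snp_id = ids, connectivity = unname(k), module = mod,
                    stringsAsFactors = FALSE)
  out[order(out$module, -out$connectivity, out$snp_id), , drop = FALSE]
}
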