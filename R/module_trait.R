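#' Module eigenSNP - trait correlation
#'
#' Pearson correlation between each module eigenSNP and each trait, with
#' a two-sided t-test on n - 2 degrees of freedom and a Bonferroni
#' adjustment across all module x trait cells.
#'
#' @param me samples x modules eigenSNP matrix (columns `ME<color>`).
#' @param pheno phenotype table with `sample_id` rows aligned to `me`
#'   and the trait columns.
#' @param traits trait column names (default `c("fcr", "rfi")`).
#' @return data.frame `module`, `trait`, `r`, `p`, `p_adj`, `n`.
#' @export
module_trait_correlation <- function(me, pheno, traits = c("fcr", "rfi")) {
  stopifnot(nrow(me) == nrow(pheno))
  traits <- intersect(traits, names(pheno))
  if (length(traits) == 0) stop("no requested trait column present")
  empty <- data.frame(module = character(0), trait = character(0),
                      r = numeric(0), p = numeric(0), p_adj = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (ncol(me) == 0) return(empty)
  rows <- list()
  for (m in colnames(me)) {
    for (tr in traits) {
      y <- pheno[[tr]]
      ok <- !is.na(me[, m]) & !is.na(y)
      n <- sum(ok)
      if (n < 4) stop("fewer than 4 complete samples for ", m, " x ", tr)
      if (sd(y[ok]) == 0) stop("zero-variance trait: ", tr)
      r <- cor(me[ok, m], y[ok])
      tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
      p <- max(2 * pt(-abs(tt), n - 2), .Machine$double.xmin)
      rows[[length(rows) + 1]] <- data.frame(
        module = sub("^ME", "", m), trait = tr, r = r, p = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out[, c("module", "trait", "r", "p", "p_adj", "n")]
}

#' Select significant modules
#'
#' A module qualifies when, for at least one trait, |r| > `r_min` and
#' p <= `p_max` (raw p; the Bonferroni-adjusted value is reported
#' alongside but does not gate). "grey" is never selectable. When
#' `top_n` is set, the qualifying modules with the smallest p are kept.
#'
#' @param mt data.frame from [module_trait_correlation()].
#' @param r_min absolute-correlation gate (default 0.4).
#' @param p_max p-value gate (default 0.05).
#' @param top_n keep at most this many modules (default 3; NULL = all).
#' @return character vector of module names.
#' @export
select_significant_modules <- function(mt, r_min = 0.4, p_max = 0.05,
                                       top_n = 3) {
  hit <- mt[abs(mt$r) > r_min & mt$p <= p_max & mt$module != "grey", ,
            drop = FALSE]
  if (nrow(hit) == 0) return(character(0))
  best <- tapply(hit$p, hit$module, min)
  mods <- names(sort(best))
  if (!is.null(top_n)) mods <- head(mods, top_n)
  mods
}

#' Extract hub SNPs from the selected modules
#'
#' All member SNPs of the selected modules, annotated with their soft
#' connectivity and the trait(s) for which the module passed the gate,
#' sorted by descending connectivity within module. The row count equals
#' the sum of the selected module sizes.
#'
#' @param selected character vector from [select_significant_modules()].
#' @param partition module_partition.
#' @param connectivity data.frame from [soft_connectivity()].
#' @param snps SNP metadata (`snp_id`, `chrom`, `pos_bp`).
#' @param mt optional module-trait table, used to fill the `traits`
#'   column; its gate hits define the per-module trait list.
#' @param r_min,p_max gates used when `mt` is given.
#' @return data.frame `snp_id`, `module`, `traits`, `connectivity`,
#'   `chrom`, `pos_bp`.
#' @export
extract_hub_snps <- function(selected, partition, connectivity, snps,
                             mt = NULL, r_min = 0.4, p_max = 0.05) {
  if (length(selected) == 0) {
    warning("no selected modules; empty hub table")
    return(data.frame(snp_id = character(0), module = character(0),
                      traits = character(0), connectivity = numeric(0),
                      chrom = character(0), pos_bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  trait_of <- function(mod) {
    if (is.null(mt)) return(NA_character_)
    h <- mt[mt$module == mod & abs(mt$r) > r_min & mt$p <= p_max, ]
    paste(sort(unique(h$trait)), collapse = "/")
  }
  rows <- lapply(selected, function(mod) {
    ids <- names(partition$assignment)[partition$assignment == mod]
    k <- connectivity$connectivity[match(ids, connectivity$snp_id)]
    mi <- match(ids, snps$snp_id)
    df <- data.frame(snp_id = ids, module = mod, traits = trait_of(mod),
                     connectivity = k, chrom = snps$chrom[mi],
                     pos_bp = snps$pos_bp[mi], stringsAsFactors = FALSE)
    df[order(-df$connectivity, df$snp_id), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
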