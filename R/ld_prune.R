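#' Squared genotype correlation (composite LD)
#'
#' Squared Pearson correlation of two coded genotype columns over their
#' pairwise-complete samples. A column that is constant on the shared
#' samples gives r2 = 0 with a degenerate flag.
#'
#' @param gi,gj coded genotype columns.
#' @return list with `r2` in \[0, 1\] and `degenerate` logical.
#' @export
genotype_r2 <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2) return(list(r2 = 0, degenerate = TRUE))
  x <- gi[ok]; y <- gj[ok]
  if (sd(x) == 0 || sd(y) == 0) return(list(r2 = 0, degenerate = TRUE))
  r <- cor(x, y)
  list(r2 = min(1, r * r), degenerate = FALSE)
}

#' Build LD blocks by greedy chaining
#'
#' SNPs must be sorted by (chrom, pos). Within each chromosome, scan left
#' to right: the current block is extended while the candidate SNP has
#' r2 >= `threshold` with the block's representative (its first member)
#' and the block holds fewer than `max_block_size` SNPs; otherwise a new
#' block starts at the candidate.
#'
#' @param gm genotype_matrix of the SNPs to block (position-sorted).
#' @param threshold r2 threshold (default 0.9).
#' @param max_block_size maximum members per block (default 1000).
#' @return data.frame with `block_id`, `chrom`, `snp_id`,
#'   `representative` (the anchor SNP the block was chained from) and
#'   `r2_to_rep`.
#' @export
build_blocks <- function(gm, threshold = 0.9, max_block_size = 1000) {
  sn <- gm$snps
  r <- rle(sn$chrom)
  if (anyDuplicated(r$values))
    stop("SNPs of one chromosome must be contiguous")
  if (any(unlist(tapply(sn$pos_bp, factor(sn$chrom, unique(sn$chrom)),
                        is.unsorted, simplify = FALSE))))
    stop("SNPs must be position-sorted within chromosome")
  out <- vector("list", nrow(sn))
  block_id <- 0L
  anchor <- NA_integer_
  block_n <- 0L
  prev_chrom <- NULL
  for (j in seq_len(nrow(sn))) {
    new_block <- TRUE
    r2 <- NA_real_
    if (!is.null(prev_chrom) && sn$chrom[j] == prev_chrom &&
        block_n < max_block_size) {
      lr <- genotype_r2(gm$values[, anchor], gm$values[, j])
      r2 <- lr$r2
      if (!lr$degenerate && lr$r2 >= threshold) new_block <- FALSE
    }
    if (new_block) {
      block_id <- block_id + 1L
      anchor <- j
      block_n <- 1L
      r2 <- 1
    } else {
      block_n <- block_n + 1L
    }
    prev_chrom <- sn$chrom[j]
    out[[j]] <- data.frame(block_id = block_id, chrom = sn$chrom[j],
                           snp_id = sn$snp_id[j],
                           representative = sn$snp_id[anchor],
                           r2_to_rep = r2, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Prune LD blocks to one SNP each
#'
#' Keeps, per block, the member with the smallest single-SNP association
#' p-value (genome order breaks ties). Output preserves genome order.
#'
#' @param blocks data.frame from [build_blocks()].
#' @param assoc data.frame from [assoc_scan()]; must cover all members.
#' @return character vector of retained snp_ids in genome order.
#' @export
prune_blocks <- function(blocks, assoc) {
  p <- assoc$p[match(blocks$snp_id, assoc$snp_id)]
  if (anyNA(p)) stop("block member without association record: ",
                     blocks$snp_id[is.na(p)][1])
  keep <- vapply(split(seq_len(nrow(blocks)), blocks$block_id), function(ix) {
    ix[which.min(p[ix])]      # which.min takes the first = genome order
  }, 0L)
  blocks$snp_id[sort(keep)]
}
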