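#' Read a gene annotation from GFF3 or BED
#'
#' GFF3: rows with feature type "gene" are used (all rows if none are
#' typed "gene"); `gene_id` comes from the `ID`/`gene_id` attribute and
#' `name` from `Name`. BED6: name column is both id and name.
#' Coordinates are returned 1-based inclusive.
#'
#' @param path annotation file (.gff/.gff3 or .bed).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `name`.
#' @export
read_gene_annotation <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED needs at least 4 columns")
    out <- data.frame(gene_id = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      start = df[[2]] + 1L, end = df[[3]],
                      strand = if (ncol(df) >= 6) df[[6]] else "+",
                      name = as.character(df[[4]]),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 9)
    if (length(bad)) stop("malformed GFF3 line ", bad[1])
    df <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
    if (any(df$V3 == "gene")) df <- df[df$V3 == "gene", ]
    attr_get <- function(s, key) {
      m <- regmatches(s, regexec(paste0("(^|;)", key, "=([^;]+)"), s))
      vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    }
    gid <- attr_get(df$V9, "ID")
    gid2 <- attr_get(df$V9, "gene_id")
    gid[is.na(gid)] <- gid2[is.na(gid)]
    gid[is.na(gid)] <- paste0("gene", seq_len(nrow(df)))[is.na(gid)]
    nm <- attr_get(df$V9, "Name")
    nm[is.na(nm)] <- gid[is.na(nm)]
    out <- data.frame(gene_id = gid, chrom = df$V1,
                      start = as.integer(df$V4), end = as.integer(df$V5),
                      strand = ifelse(df$V7 %in% c("+", "-"), df$V7, "+"),
                      name = nm, stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("gene with start > end")
  out
}

#' Classify SNPs against gene ranges
#'
#' Each SNP gets exactly one primary class: `genic` when its position
#' falls inside a gene (the smallest-span gene when several overlap; all
#' overlapping genes are also reported), otherwise `upstream` or
#' `downstream` of the nearest gene within `flank_bp` (respecting the
#' gene's strand), otherwise `intergenic`. SNPs on chromosomes absent
#' from the annotation are intergenic with a warning.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos_bp`.
#' @param genes data.frame from [read_gene_annotation()].
#' @param flank_bp flank width (default 5000).
#' @return data.frame `snp_id`, `class`, `gene_id`, `gene_name`,
#'   `all_genes` (comma list of overlapping gene ids, genic only).
#' @export
classify_snps <- function(snps, genes, flank_bp = 5000) {
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr_snps <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos_bp, snps$pos_bp))
  missing_chr <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(missing_chr))
    warning("chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "), "; SNPs set intergenic")
  n <- nrow(snps)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  allg <- rep(NA_character_, n)

  ov <- GenomicRanges::findOverlaps(gr_snps, gr_genes, ignore.strand = TRUE)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    span <- genes$end - genes$start
    for (i in unique(qh)) {
      hits <- sh[qh == i]
      primary <- hits[order(span[hits], genes$gene_id[hits])][1]
      cls[i] <- "genic"
      gid[i] <- genes$gene_id[primary]
      allg[i] <- paste(genes$gene_id[hits][order(span[hits])],
                       collapse = ",")
    }
  }
  ng <- which(cls != "genic" & snps$chrom %in% genes$chrom)
  if (length(ng)) {
    nr <- GenomicRanges::distanceToNearest(gr_snps[ng], gr_genes,
                                           ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(nr); sh <- S4Vectors::subjectHits(nr)
    d <- S4Vectors::mcols(nr)$distance
    for (t in seq_along(qh)) {
      if (d[t] > flank_bp) next
      i <- ng[qh[t]]; g <- sh[t]
      before <- snps$pos_bp[i] < genes$start[g]
      plus <- genes$strand[g] != "-"
      cls[i] <- if (before == plus) "upstream" else "downstream"
      gid[i] <- genes$gene_id[g]
    }
  }
  data.frame(snp_id = snps$snp_id, class = cls, gene_id = gid,
             gene_name = genes$name[match(gid, genes$gene_id)],
             all_genes = allg, stringsAsFactors = FALSE)
}

#' Annotate a hub-SNP table
#'
#' @param hubs data.frame from [extract_hub_snps()].
#' @param genes data.frame from [read_gene_annotation()].
#' @param flank_bp flank width (default 5000).
#' @return `hubs` with `class`, `gene_id`, `gene_name` appended.
#' @export
annotate_hubs <- function(hubs, genes, flank_bp = 5000) {
  cl <- classify_snps(hubs[, c("snp_id", "chrom", "pos_bp")], genes,
                      flank_bp)
  cbind(hubs, cl[, c("class", "gene_id", "gene_name")])
}
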