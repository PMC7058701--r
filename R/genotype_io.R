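#' @importFrom stats lm lm.fit pt cor quantile sd var rnorm runif qnorm
#'   hclust as.dist cutree dist complete.cases coef setNames
#' @importFrom utils write.table read.table head
NULL

GENO_MISSING <- NA_integer_

#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds a samples x SNPs integer matrix coded as the
#' number of minor-allele copies (0 = homozygote major, 1 = heterozygote,
#' 2 = homozygote minor, `NA` = missing call) plus per-SNP metadata.
#'
#' @param values integer matrix, samples in rows, SNPs in columns.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`, `minor_allele`, `maf`.
#' @param sample_ids character vector of row identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snps, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(ncol(values) == nrow(snps), nrow(values) == length(sample_ids))
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id: ", snps$snp_id[duplicated(snps$snp_id)][1])
  rownames(values) <- sample_ids
  colnames(values) <- snps$snp_id
  structure(list(values = values, snps = snps,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d chromosome(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

## Subset samples and/or SNPs, keeping metadata in step.
#' Subset a genotype matrix
#' @param gm genotype_matrix.
#' @param samples sample index or id vector (NULL = all).
#' @param snps SNP index or id vector (NULL = all).
#' @param recode recompute minor allele and MAF on the retained samples.
#' @return genotype_matrix.
#' @export
gm_subset <- function(gm, samples = NULL, snps = NULL, recode = FALSE) {
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else {
    if (is.character(samples)) match(samples, gm$sample_ids) else samples
  }
  ci <- if (is.null(snps)) seq_len(ncol(gm$values)) else {
    if (is.character(snps)) match(snps, gm$snps$snp_id) else snps
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(ci)) stop("unknown snp id(s)")
  out <- genotype_matrix(gm$values[si, ci, drop = FALSE],
                         gm$snps[ci, , drop = FALSE],
                         gm$sample_ids[si])
  if (recode) out <- gm_recode(out)
  out
}

## Re-orient coding so that the stored dosage counts the minor allele on the
## current sample set; flips 0<->2 where the minor allele switched.
gm_recode <- function(gm) {
  v <- gm$values
  sn <- gm$snps
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    nm <- !is.na(col)
    n2 <- sum(nm)
    if (n2 == 0L) { sn$maf[j] <- NA_real_; next }
    f_minor <- sum(col[nm]) / (2 * n2)     # freq of currently-coded allele
    if (f_minor > 0.5 ||
        (f_minor == 0.5 && !is.na(sn$allele_a[j]) &&
         tie_break_minor(sn$minor_allele[j],
                         other_allele(sn, j)) != sn$minor_allele[j])) {
      v[, j] <- 2L - col
      sn$minor_allele[j] <- other_allele(sn, j)
      f_minor <- 1 - f_minor
    }
    sn$maf[j] <- f_minor
  }
  gm$values <- v
  gm$snps <- sn
  gm
}

other_allele <- function(sn, j) {
  a <- c(sn$allele_a[j], sn$allele_b[j])
  a <- a[a != sn$minor_allele[j] & a != "0" & !is.na(a)]
  if (length(a) == 0) sn$minor_allele[j] else a[1]
}

## Tie at frequency 0.5: lexicographically smaller allele is minor.
tie_break_minor <- function(a, b) sort(c(a, b))[1]

#' Code one SNP's allele calls as minor-allele dosage
#'
#' Alleles are single characters with `"0"` meaning a missing call. The
#' minor allele is the allele with frequency <= 0.5 among non-missing
#' calls; at an exact 0.5 tie the lexicographically smaller allele is
#' taken as minor so that the coding is deterministic.
#'
#' @param a1,a2 character vectors, the two allele calls per sample.
#' @return list with `code` (integer 0/1/2/NA dosage), `minor_allele`,
#'   `major_allele`, `maf`.
#' @export
code_genotypes <- function(a1, a2) {
  stopifnot(length(a1) == length(a2))
  miss <- a1 == "0" | a2 == "0"
  if (all(miss)) stop("no non-missing genotype calls")
  alleles <- sort(unique(c(a1[!miss], a2[!miss])))
  if (length(alleles) > 2)
    stop("more than 2 distinct alleles: ", paste(alleles, collapse = ","))
  if (length(alleles) == 1) {
    code <- ifelse(miss, NA_integer_, 0L)
    return(list(code = as.integer(code), minor_allele = alleles[1],
                major_allele = alleles[1], maf = 0))
  }
  n1 <- sum(a1[!miss] == alleles[1]) + sum(a2[!miss] == alleles[1])
  tot <- 2 * sum(!miss)
  f1 <- n1 / tot
  minor <- if (f1 < 0.5) alleles[1]
           else if (f1 > 0.5) alleles[2]
           else tie_break_minor(alleles[1], alleles[2])
  major <- setdiff(alleles, minor)
  code <- (a1 == minor) + (a2 == minor)
  code[miss] <- NA_integer_
  maf <- sum(code, na.rm = TRUE) / (2 * sum(!miss))
  list(code = as.integer(code), minor_allele = minor, major_allele = major,
       maf = maf)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Uses the stable recurrence over heterozygote counts.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (>= 0, sum >= 1).
#' @return p-value in (0, 1]. Monomorphic input returns 1.
#' @export
hwe_exact_p <- function(n_hom_major, n_het, n_hom_minor) {
  stopifnot(n_hom_major >= 0, n_het >= 0, n_hom_minor >= 0)
  n <- n_hom_major + n_het + n_hom_minor
  if (n < 1) stop("empty genotype table")
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n_hom_major + n_het
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)
  # possible het counts share parity with the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized log-probabilities by recurrence:
  # P(h+2)/P(h) = 4*nr(h)*nc(h) / ((h+2)*(h+1)), nr/nc = rare/common homs
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    nr <- (rare - h) / 2
    nc <- n - h - nr
    lp[k] <- lp[k - 1] + log(4) + log(nr) + log(nc) -
      log(h + 2) - log(h + 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count parity inconsistent with alleles")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

parse_map_line <- function(fields, path, i) {
  if (length(fields) < 4)
    stop(sprintf("%s line %d: expected >= 4 fields, got %d",
                 path, i, length(fields)))
  list(chrom = fields[1], snp_id = fields[2], pos_bp = as.numeric(fields[4]))
}

#' Read PLINK-style text genotypes
#'
#' Supports both the sample-major PED/MAP dialect and the SNP-major
#' TPED/TFAM dialect (whitespace-delimited, allele `"0"` = missing call).
#' Positions are 1-based bp. Genotypes are coded to minor-allele dosage
#' via [code_genotypes()]; sample and SNP order follow the files.
#'
#' @param ped,map paths for the PED/MAP dialect.
#' @param tped,tfam paths for the TPED/TFAM dialect.
#' @return genotype_matrix.
#' @export
read_plink_text <- function(ped = NULL, map = NULL,
                            tped = NULL, tfam = NULL) {
  if (!is.null(ped)) {
    stopifnot(!is.null(map), file.exists(ped), file.exists(map))
    map_l <- strsplit(trimws(readLines(map)), "[ \t]+")
    map_l <- map_l[lengths(map_l) > 0]
    meta <- do.call(rbind, lapply(seq_along(map_l), function(i) {
      m <- parse_map_line(map_l[[i]], map, i)
      data.frame(snp_id = m$snp_id, chrom = m$chrom, pos_bp = m$pos_bp,
                 stringsAsFactors = FALSE)
    }))
    n_snps <- nrow(meta)
    ped_l <- strsplit(trimws(readLines(ped)), "[ \t]+")
    ped_l <- ped_l[lengths(ped_l) > 0]
    n_samp <- length(ped_l)
    a1 <- matrix("0", n_samp, n_snps)
    a2 <- matrix("0", n_samp, n_snps)
    ids <- character(n_samp)
    for (i in seq_len(n_samp)) {
      f <- ped_l[[i]]
      if (length(f) != 6 + 2 * n_snps)
        stop(sprintf("%s line %d: expected %d fields (6 + 2 x %d SNPs), got %d",
                     ped, i, 6 + 2 * n_snps, n_snps, length(f)))
      ids[i] <- f[2]
      g <- f[-(1:6)]
      a1[i, ] <- g[seq(1, length(g), by = 2)]
      a2[i, ] <- g[seq(2, length(g), by = 2)]
    }
  } else {
    stopifnot(!is.null(tped), !is.null(tfam),
              file.exists(tped), file.exists(tfam))
    fam_l <- strsplit(trimws(readLines(tfam)), "[ \t]+")
    fam_l <- fam_l[lengths(fam_l) > 0]
    ids <- vapply(fam_l, function(f) f[2], "")
    n_samp <- length(ids)
    tped_l <- strsplit(trimws(readLines(tped)), "[ \t]+")
    tped_l <- tped_l[lengths(tped_l) > 0]
    n_snps <- length(tped_l)
    a1 <- matrix("0", n_samp, n_snps)
    a2 <- matrix("0", n_samp, n_snps)
    meta <- data.frame(snp_id = character(n_snps), chrom = character(n_snps),
                       pos_bp = numeric(n_snps), stringsAsFactors = FALSE)
    for (j in seq_len(n_snps)) {
      f <- tped_l[[j]]
      if (length(f) != 4 + 2 * n_samp)
        stop(sprintf("%s line %d: expected %d fields (4 + 2 x %d samples), got %d",
                     tped, j, 4 + 2 * n_samp, n_samp, length(f)))
      m <- parse_map_line(f[1:4], tped, j)
      meta$snp_id[j] <- m$snp_id; meta$chrom[j] <- m$chrom
      meta$pos_bp[j] <- m$pos_bp
      g <- f[-(1:4)]
      a1[, j] <- g[seq(1, length(g), by = 2)]
      a2[, j] <- g[seq(2, length(g), by = 2)]
    }
  }
  if (anyDuplicated(meta$snp_id))
    stop("duplicate snp_id: ", meta$snp_id[duplicated(meta$snp_id)][1])
  vals <- matrix(NA_integer_, n_samp, n_snps)
  snps <- data.frame(meta,
                     allele_a = NA_character_, allele_b = NA_character_,
                     minor_allele = NA_character_, maf = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(n_snps)) {
    if (all(a1[, j] == "0" & a2[, j] == "0")) next   # all-missing SNP
    cg <- code_genotypes(a1[, j], a2[, j])
    vals[, j] <- cg$code
    snps$allele_a[j] <- cg$major_allele
    snps$allele_b[j] <- cg$minor_allele
    snps$minor_allele[j] <- cg$minor_allele
    snps$maf[j] <- cg$maf
  }
  genotype_matrix(vals, snps, ids)
}

#' Write PLINK-style text genotypes
#'
#' Inverse of [read_plink_text()]; allele labels are reconstructed from the
#' stored major/minor alleles and missing calls written as `0 0`.
#'
#' @param gm genotype_matrix.
#' @param prefix output path prefix; writes `prefix.ped` + `prefix.map`
#'   or `prefix.tped` + `prefix.tfam`.
#' @param dialect `"ped"` or `"tped"`.
#' @return invisibly, the written file paths.
#' @export
write_plink_text <- function(gm, prefix, dialect = c("ped", "tped")) {
  dialect <- match.arg(dialect)
  v <- gm$values
  n_samp <- nrow(v); n_snps <- ncol(v)
  gstr <- matrix("0 0", n_samp, n_snps)
  for (j in seq_len(n_snps)) {
    mino <- gm$snps$minor_allele[j]
    both <- c(gm$snps$allele_a[j], gm$snps$allele_b[j])
    maj <- setdiff(both[!is.na(both)], mino)
    if (length(maj) == 0) maj <- mino   # monomorphic
    maj <- maj[1]
    if (is.na(mino)) mino <- "0"
    if (is.na(maj)) maj <- "0"
    gj <- v[, j]
    gstr[, j] <- ifelse(is.na(gj), "0 0",
                 ifelse(gj == 0L, paste(maj, maj),
                 ifelse(gj == 1L, paste(maj, mino), paste(mino, mino))))
  }
  if (dialect == "ped") {
    ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
    lines <- vapply(seq_len(n_samp), function(i)
      paste(c(gm$sample_ids[i], gm$sample_ids[i], 0, 0, 0, -9,
              gstr[i, ]), collapse = " "), "")
    writeLines(lines, ped)
    writeLines(sprintf("%s %s 0 %d", gm$snps$chrom, gm$snps$snp_id,
                       as.integer(gm$snps$pos_bp)), map)
    invisible(c(ped, map))
  } else {
    tped <- paste0(prefix, ".tped"); tfam <- paste0(prefix, ".tfam")
    lines <- vapply(seq_len(n_snps), function(j)
      paste(c(gm$snps$chrom[j], gm$snps$snp_id[j], 0,
              as.integer(gm$snps$pos_bp[j]), gstr[, j]), collapse = " "), "")
    writeLines(lines, tped)
    writeLines(sprintf("%s %s 0 0 0 -9", gm$sample_ids, gm$sample_ids), tfam)
    invisible(c(tped, tfam))
  }
}

#' Default genotype QC parameters
#'
#' Thresholds follow common array-QC practice for this kind of study:
#' samples with call rate <= 90% removed; SNPs removed when call rate
#' < 90%, MAF < 0.01, HWE exact p < 1e-7, non-autosomal, or lacking a
#' position. Note the asymmetric operators (samples `<=`, SNPs `<`).
#'
#' @param sample_call_rate sample threshold (removed when `<=`).
#' @param snp_call_rate SNP threshold (removed when `<`).
#' @param maf_min minimum MAF (removed when `<`).
#' @param hwe_p HWE p threshold (removed when `<`).
#' @param autosomes chromosome labels counted as autosomal.
#' @return named list of parameters.
#' @export
qc_params <- function(sample_call_rate = 0.90, snp_call_rate = 0.90,
                      maf_min = 0.01, hwe_p = 1e-7,
                      autosomes = as.character(1:18)) {
  list(sample_call_rate = sample_call_rate, snp_call_rate = snp_call_rate,
       maf_min = maf_min, hwe_p = hwe_p, autosomes = autosomes)
}

#' Apply genotype quality control
#'
#' Filter order: (1) samples by call rate; per-SNP statistics (minor
#' allele, MAF, HWE) are then recomputed on the retained samples;
#' (2) non-autosomal SNPs; (3) SNPs without position; (4) SNP call rate;
#' (5) MAF; (6) HWE exact test. Each removed SNP is attributed to the
#' first filter that removes it.
#'
#' @param gm genotype_matrix.
#' @param params list from [qc_params()].
#' @return list with `gm` (filtered genotype_matrix) and `report`
#'   (a `qc_report` list of input/output sizes and per-filter counts).
#' @export
apply_qc <- function(gm, params = qc_params()) {
  n_samples_in <- nrow(gm$values); n_snps_in <- ncol(gm$values)
  cr_samp <- rowMeans(!is.na(gm$values))
  keep_s <- cr_samp > params$sample_call_rate
  n_rm_samp <- sum(!keep_s)
  if (!any(keep_s)) stop("empty after QC: all samples removed")
  gm <- gm_subset(gm, samples = which(keep_s), recode = TRUE)

  v <- gm$values; sn <- gm$snps
  removed <- rep(NA_character_, ncol(v))
  is_auto <- sn$chrom %in% params$autosomes
  removed[!is_auto] <- "non_autosomal"
  no_pos <- is.na(sn$pos_bp) | sn$pos_bp <= 0
  removed[is.na(removed) & no_pos] <- "no_position"
  cr_snp <- colMeans(!is.na(v))
  removed[is.na(removed) & cr_snp < params$snp_call_rate] <- "snp_call_rate"
  removed[is.na(removed) &
          (is.na(sn$maf) | sn$maf < params$maf_min)] <- "maf"
  idx <- which(is.na(removed))
  for (j in idx) {
    col <- v[, j]
    n0 <- sum(col == 0L, na.rm = TRUE)
    n1 <- sum(col == 1L, na.rm = TRUE)
    n2 <- sum(col == 2L, na.rm = TRUE)
    if (hwe_exact_p(n0, n1, n2) < params$hwe_p) removed[j] <- "hwe"
  }
  keep <- is.na(removed)
  if (!any(keep)) stop("empty after QC: all SNPs removed")
  counts <- table(factor(removed[!keep],
                         levels = c("non_autosomal", "no_position",
                                    "snp_call_rate", "maf", "hwe")))
  report <- structure(list(
    n_samples_in = n_samples_in, n_samples_out = sum(keep_s),
    n_snps_in = n_snps_in, n_snps_out = sum(keep),
    removals = c(sample_call_rate = n_rm_samp, unclass(counts))),
    class = "qc_report")
  list(gm = gm_subset(gm, snps = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d samples, %d -> %d SNPs\n",
              x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out))
  r <- x$removals
  for (nm in names(r)) cat(sprintf("  removed by %-17s %d\n", nm, r[[nm]]))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report qc_report from [apply_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_samples_in", "n_samples_out", "n_snps_in", "n_snps_out",
               paste0("removed_", names(report$removals))),
    value = c(report$n_samples_in, report$n_samples_out,
              report$n_snps_in, report$n_snps_out,
              unlist(report$removals)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
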