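#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter, with the
#' conventional defaults of the analysis: top_k = 7000, LD threshold
#' 0.9, max block 1000, overview quantile 0.9, module gates r > 0.4 and
#' p <= 0.05, top 3 modules. Unknown keys are rejected.
#'
#' @param ped,map,tped,tfam genotype input paths (one dialect required).
#' @param pheno phenotype TSV path.
#' @param gff optional gene annotation (GFF3 or BED).
#' @param trait trait column to analyze ("fcr", "rfi", or custom).
#' @param subset "all", "LFE" or "HFE".
#' @param ... overrides for stage parameters: `top_k`, `ld_threshold`,
#'   `max_block_size`, `quantile`, `min_module_size`, `merge_cut_height`,
#'   `power_beta` (12 by default, the signed-network convention; NULL =
#'   pick by scale-free fit), `r_min`, `p_max`,
#'   `top_n_modules`, `n_per_group`, `flank_bp`, `qc` (list for
#'   [qc_params()]), `seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ped = NULL, map = NULL, tped = NULL,
                            tfam = NULL, pheno, gff = NULL,
                            trait = "fcr", subset = "all", ...) {
  defaults <- list(top_k = 7000, ld_threshold = 0.9, max_block_size = 1000,
                   quantile = 0.9, min_module_size = 30,
                   merge_cut_height = 0.25, power_beta = 12,
                   r_min = 0.4, p_max = 0.05, top_n_modules = 3,
                   n_per_group = 15, flank_bp = 5000, qc = list(),
                   seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  stopifnot(subset %in% c("all", "LFE", "HFE"))
  c(list(ped = ped, map = map, tped = tped, tfam = tfam, pheno = pheno,
         gff = gff, trait = trait, subset = subset), defaults) |>
    structure(class = "pipeline_config")
}

stamp_hash <- function(obj, files = character(0)) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  paste(c(unname(tools::md5sum(tf)),
          unname(tools::md5sum(files[file.exists(files)]))),
        collapse = "-")
}

write_stamp <- function(dir, stage, hash, counts) {
  jsonlite::write_json(list(stage = stage, hash = hash, counts = counts),
                       file.path(dir, paste0(stage, ".stamp.json")),
                       auto_unbox = TRUE)
}

stamp_matches <- function(dir, stage, hash) {
  f <- file.path(dir, paste0(stage, ".stamp.json"))
  if (!file.exists(f)) return(FALSE)
  identical(jsonlite::read_json(f)$hash, hash)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg))
}

#' Run the full epistatic-network pipeline
#'
#' Stages: QC -> phenotype derivation -> single-SNP association -> top-K
#' selection -> LD-block pruning -> pairwise epistasis scan -> signed
#' network + modules -> module-trait association -> hub extraction ->
#' (optional) gene annotation. Each stage writes a TSV artifact and a
#' JSON stamp (parameter + input hash chain, output counts) into
#' `out_dir`. The hash chain makes invalidation observable: changing a
#' stage parameter changes that stage's stamp and every downstream one,
#' never an upstream one. All stages are deterministic, so a rerun
#' reproduces identical artifacts.
#'
#' @param config pipeline_config.
#' @param out_dir run directory (created).
#' @return invisibly, a summary list with per-stage counts and the key
#'   result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  geno_files <- unlist(cfg[c("ped", "map", "tped", "tfam")])
  # per-stage hash chain: a stamp changes iff its own parameters, its
  # inputs, or any upstream stamp changed
  qc_hash <- stamp_hash(cfg["qc"], geno_files)
  assoc_hash <- stamp_hash(c(cfg[c("trait", "subset", "top_k",
                                   "n_per_group")], up = qc_hash),
                           cfg$pheno)
  prune_hash <- stamp_hash(c(cfg[c("ld_threshold", "max_block_size")],
                             up = assoc_hash))
  epi_hash <- stamp_hash(c(cfg["quantile"], up = prune_hash))
  network_hash <- stamp_hash(c(cfg[c("power_beta", "min_module_size",
                                     "merge_cut_height")],
                               up = epi_hash))
  modules_hash <- stamp_hash(c(cfg[c("r_min", "p_max", "top_n_modules")],
                               up = network_hash))

  log_stage("qc", "reading genotypes")
  gm <- if (!is.null(cfg$ped))
    read_plink_text(ped = cfg$ped, map = cfg$map)
  else read_plink_text(tped = cfg$tped, tfam = cfg$tfam)
  qc <- apply_qc(gm, do.call(qc_params, cfg$qc))
  gm <- qc$gm
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  write_stamp(out_dir, "qc", qc_hash,
              list(samples = qc$report$n_samples_out,
                   snps = qc$report$n_snps_out))
  log_stage("qc", sprintf("%d samples, %d SNPs retained",
                          qc$report$n_samples_out, qc$report$n_snps_out))

  pheno <- read_phenotypes(cfg$pheno)
  pheno <- pheno[match(gm$sample_ids, pheno$sample_id), ]
  if (anyNA(pheno$sample_id)) stop("phenotype rows missing for genotyped samples")
  pheno <- phenotype_table(pheno, n_per_group = cfg$n_per_group)
  write_groups(pheno, file.path(out_dir, "groups.tsv"))

  if (cfg$subset != "all") {
    keep <- pheno$group == cfg$subset
    gm <- gm_subset(gm, samples = which(keep), recode = TRUE)
    pheno <- pheno[keep, ]
    log_stage("subset", sprintf("%s group: %d samples", cfg$subset,
                                sum(keep)))
  }
  trait <- pheno[[cfg$trait]]
  if (is.null(trait)) stop("trait column not found: ", cfg$trait)

  log_stage("assoc", "single-SNP association")
  assoc <- assoc_scan(gm, trait)
  write_assoc(assoc, file.path(out_dir, "assoc.tsv"))
  top_ids <- select_top_k(assoc, cfg$top_k)
  gm_top <- gm_subset(gm, snps = top_ids)
  write_stamp(out_dir, "assoc", assoc_hash, list(top_k = length(top_ids)))

  log_stage("prune", "LD-block pruning")
  blocks <- build_blocks(gm_top, cfg$ld_threshold, cfg$max_block_size)
  pruned_ids <- prune_blocks(blocks, assoc)
  gm_pruned <- gm_subset(gm_top, snps = pruned_ids)
  write.table(blocks, file.path(out_dir, "blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_stamp(out_dir, "prune", prune_hash,
              list(blocks = length(unique(blocks$block_id)),
                   pruned = length(pruned_ids)))
  log_stage("prune", sprintf("%d SNPs after pruning", length(pruned_ids)))

  log_stage("epistasis", sprintf("scanning %d pairs",
                                 choose(length(pruned_ids), 2)))
  er <- scan_all_pairs(gm_pruned, trait)
  write_epistasis(er, file.path(out_dir, "epistasis_pairs.tsv"),
                  p_max = 0.05)
  overview <- chrom_pair_overview(er, cfg$quantile)
  write.table(overview, file.path(out_dir, "chrom_interaction.tsv"),
              sep = "\t", quote = FALSE)
  write_stamp(out_dir, "epistasis", epi_hash,
              list(ok_pairs = sum(er$status[upper.tri(er$status)] == "ok")))

  log_stage("network", "signed network and modules")
  pw <- if (is.null(cfg$power_beta))
    pick_power(er$beta3, status = er$status)$power_beta
  else cfg$power_beta
  adj <- signed_adjacency(er$beta3, pw, status = er$status)
  tom <- tom_similarity(adj$adjacency)
  part <- cluster_and_cut(1 - tom, cfg$min_module_size)
  part <- merge_close_modules(part, gm_pruned, cfg$merge_cut_height)
  conn <- soft_connectivity(adj$adjacency, part)
  mod_df <- data.frame(snp_id = names(part$assignment),
                       module = unname(part$assignment),
                       stringsAsFactors = FALSE)
  mod_df <- merge(mod_df, conn[, c("snp_id", "connectivity")], by = "snp_id")
  write.table(mod_df, file.path(out_dir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  n_modules <- length(setdiff(unique(part$assignment), "grey"))
  write_stamp(out_dir, "network", network_hash,
              list(power = pw, modules = n_modules))
  log_stage("network", sprintf("power %s, %d modules", pw, n_modules))

  log_stage("modules", "module-trait association")
  es <- eigen_snp_set(gm_pruned, part)
  traits_avail <- intersect(c("fcr", "rfi"), names(pheno))
  mt <- module_trait_correlation(es$me, pheno, traits_avail)
  write.table(mt, file.path(out_dir, "module_trait.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sel <- select_significant_modules(mt, cfg$r_min, cfg$p_max,
                                    cfg$top_n_modules)
  hubs <- extract_hub_snps(sel, part, conn, gm_pruned$snps, mt,
                           cfg$r_min, cfg$p_max)
  write.table(hubs, file.path(out_dir, "hub_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_stamp(out_dir, "modules", modules_hash,
              list(selected = length(sel), hubs = nrow(hubs)))

  if (!is.null(cfg$gff) && nrow(hubs) > 0) {
    log_stage("annotate", "SNP-to-gene classification")
    genes <- read_gene_annotation(cfg$gff)
    hubs <- annotate_hubs(hubs, genes, cfg$flank_bp)
    write.table(hubs, file.path(out_dir, "hub_snps_annotated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_samples = nrow(gm$values),
    n_snps_post_qc = qc$report$n_snps_out,
    n_top_k = length(top_ids),
    n_pruned = length(pruned_ids),
    power_beta = pw,
    n_modules = n_modules,
    selected_modules = sel,
    n_hub_snps = nrow(hubs))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(summary,
              list(module_trait = mt, hubs = hubs, partition = part,
                   epistasis = er, overview = overview, pheno = pheno)))
}
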