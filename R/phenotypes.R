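#' Feed conversion ratio
#'
#' FCR = feed consumed over the test period divided by body-weight gain
#' (delta weight). Lower values mean a more efficient animal.
#'
#' @param fc feed consumed (kg), vectorized.
#' @param dw delta weight (kg), must be > 0.
#' @return fc / dw.
#' @export
compute_fcr <- function(fc, dw) {
  if (any(dw <= 0)) stop("delta weight must be > 0")
  fc / dw
}

#' Residual feed intake
#'
#' RFI is the residual of an ordinary least-squares regression of observed
#' daily feed intake (DFI) on production-trait predictors (with intercept):
#' observed minus predicted intake. Residuals sum to zero by construction.
#' The predictor set is configurable; the default uses daily weight gain
#' and initial weight.
#'
#' @param pheno data.frame with columns `dfi` plus the predictor columns.
#' @param predictors character vector of predictor column names.
#' @return numeric vector of RFI values (same order as `pheno`).
#' @export
compute_rfi <- function(pheno, predictors = c("dw_per_day", "initial_weight")) {
  predictors <- intersect(predictors, names(pheno))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(pheno[, predictors, drop = FALSE]))
  if (nrow(X) < ncol(X) + 1)
    stop("need at least p + 2 samples to fit the intake regression")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear intake predictors (rank deficient): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, pheno$dfi)
  as.numeric(fit$residuals)
}

#' Assign feed-efficiency groups from FCR
#'
#' Animals at least one standard deviation above the mean FCR seed the
#' low-feed-efficiency (LFE) group (high FCR = inefficient); one SD below
#' seeds HFE. Each group is then filled to exactly `n_per_group` by taking
#' the next most extreme animals; ties are resolved by sample id so the
#' assignment is deterministic.
#'
#' @param fcr numeric FCR vector.
#' @param sample_ids ids aligned with `fcr`.
#' @param n_per_group target size of each group.
#' @return character vector of labels in `{LFE, HFE, MID}`.
#' @export
assign_efficiency_groups <- function(fcr, sample_ids = as.character(seq_along(fcr)),
                                     n_per_group = 15) {
  n <- length(fcr)
  stopifnot(length(sample_ids) == n)
  if (n_per_group > floor(n / 2))
    stop("n_per_group exceeds floor(n/2)")
  if (sd(fcr) == 0)
    warning("all FCR values equal; groups assigned by sample id order")
  # most to least extreme per side; sample_id breaks ties, from opposite
  # ends so full degeneracy still yields disjoint groups
  ord_desc <- order(-fcr, xtfrm(sample_ids))           # high FCR -> LFE
  ord_asc <- order(fcr, -xtfrm(sample_ids))            # low FCR -> HFE
  lfe <- ord_desc[seq_len(n_per_group)]
  hfe <- ord_asc[seq_len(n_per_group)]
  if (length(intersect(lfe, hfe)) > 0)
    stop("groups overlap; n too small for n_per_group")
  grp <- rep("MID", n)
  grp[lfe] <- "LFE"
  grp[hfe] <- "HFE"
  grp
}

#' Build a phenotype table
#'
#' Derives FCR and RFI from raw feed records and assigns efficiency
#' groups. The one-SD rule seeds the groups; ranks fill them to
#' `n_per_group` (see [assign_efficiency_groups()]).
#'
#' @param pheno data.frame with `sample_id`, `fc`, `dw`, `dfi`,
#'   `initial_weight`, `age_days`, and optionally `test_days`.
#' @param n_per_group group size (default 15).
#' @param rfi_predictors predictor columns for [compute_rfi()].
#' @return the input with `fcr`, `rfi`, `group` columns appended.
#' @export
phenotype_table <- function(pheno, n_per_group = 15,
                            rfi_predictors = c("dw_per_day", "initial_weight")) {
  req <- c("sample_id", "fc", "dw", "dfi")
  miss <- setdiff(req, names(pheno))
  if (length(miss)) stop("missing phenotype columns: ",
                         paste(miss, collapse = ", "))
  if (!"dw_per_day" %in% names(pheno) && "test_days" %in% names(pheno))
    pheno$dw_per_day <- pheno$dw / pheno$test_days
  pheno$fcr <- compute_fcr(pheno$fc, pheno$dw)
  pheno$rfi <- compute_rfi(pheno, rfi_predictors)
  pheno$group <- assign_efficiency_groups(pheno$fcr, pheno$sample_id,
                                          n_per_group)
  pheno
}

#' Read a phenotype TSV
#' @param path file with header columns `sample_id`, `fc`, `dw`, `dfi`,
#'   `initial_weight`, `age_days` (extra columns kept).
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write group assignments as a two-column TSV
#' @param pheno phenotype table with `sample_id` and `group`.
#' @param path output file.
#' @export
write_groups <- function(pheno, path) {
  write.table(pheno[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
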