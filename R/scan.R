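#' Single-locus association scan
#'
#' Runs every SNP x outcome x genetic-model combination and applies
#' Benjamini-Hochberg FDR control across the whole scan (one block p-value
#' per combination, the codominant block counting once). A scan over
#' `outcomes = "status"` is the case-control family (m = 12 for 3 SNPs x 4
#' models); a scan over the four sub-phenotypes is the within-case family
#' (m = 48).
#'
#' Two estimators are available: `"crude"` computes cross-product odds
#' ratios with Woolf CIs from the genotype count tables (the estimator that
#' reproduces printed within-case tables), `"adjusted"` fits
#' covariate-adjusted logistic models via [logistic_association()]. Cells
#' that cannot be estimated (e.g. an outcome level absent in a stratum)
#' become flagged rows rather than aborting the scan.
#'
#' @param cohort A [join_cohort()] result.
#' @param outcomes Character vector: `"status"` and/or sub-phenotype names.
#' @param models Genetic models (default: the four study models).
#' @param covariates Covariates for the adjusted estimator.
#' @param estimator `"crude"` or `"adjusted"`.
#' @param level Confidence level.
#' @return A tibble with columns `snp`, `outcome`, `model`, `genotype`,
#'   `n0`, `n1`, `or`, `ci_low`, `ci_high`, `p`, `p_fdr`, `ref`, `note`.
#' @export
run_single_locus_scan <- function(cohort, outcomes = "status",
                                  models = c("codominant", "dominant",
                                             "recessive", "overdominant"),
                                  covariates = character(),
                                  estimator = c("crude", "adjusted"),
                                  level = 0.95) {
  estimator <- match.arg(estimator)
  models <- vapply(models, match.arg, "", choices = GENETIC_MODELS)
  snps <- cohort$genotypes$snps$id
  blocks <- list()
  for (snp in snps) {
    j <- match(snp, snps)
    gl <- genotype_labels_for(cohort$genotypes$snps, j)
    for (outcome in outcomes) {
      counts <- tryCatch(genotype_counts(cohort, snp, outcome),
                         error = function(e) e)
      for (model in models) {
        key <- paste(snp, outcome, model, sep = ".")
        blocks[[key]] <- scan_cell(cohort, snp, outcome, model, counts, gl,
                                   covariates, estimator, level)
        blocks[[key]]$snp <- snp
        blocks[[key]]$outcome <- outcome
      }
    }
  }
  out <- dplyr::bind_rows(blocks)
  # one p per block; BH across blocks, mapped back to every member row
  block_id <- paste(out$snp, out$outcome, out$model, sep = ".")
  block_p <- tapply(out$p, block_id, function(p) {
    p <- p[!is.na(p)]
    if (length(p)) p[1] else NA_real_
  })
  adj <- rep(NA_real_, length(block_p))
  ok <- !is.na(block_p)
  adj[ok] <- bh_adjust(block_p[ok])
  names(adj) <- names(block_p)
  out$p_fdr <- ifelse(is.na(out$p), NA_real_, adj[block_id])
  dplyr::select(out, "snp", "outcome", dplyr::everything())
}

scan_cell <- function(cohort, snp, outcome, model, counts, gl, covariates,
                      estimator, level) {
  flagged_row <- function(msg) {
    tibble::tibble(model = model, genotype = NA_character_,
                   n0 = NA_integer_, n1 = NA_integer_, or = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   ref = FALSE, note = msg)
  }
  if (inherits(counts, "error")) return(flagged_row(conditionMessage(counts)))
  if (any(rowSums(counts) == 0))
    return(flagged_row("empty outcome level in stratum"))
  res <- tryCatch({
    if (estimator == "crude")
      assoc_from_counts(counts, model, genotype_labels = gl, level = level)
    else
      logistic_association(cohort, snp, outcome, model, covariates, level)
  }, error = function(e) flagged_row(conditionMessage(e)))
  if (!"note" %in% names(res)) res$note <- NA_character_
  if ("flagged" %in% names(res)) res$flagged <- NULL
  res
}
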