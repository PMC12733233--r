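#' Join genotypes and phenotypes into an analysis cohort
#'
#' Inner join on sample id. Samples present on only one side are dropped and
#' counted; an empty intersection is an error. The result is invariant to
#' the row order of either input (samples are sorted by id).
#'
#' @param gt A [genotype_table()].
#' @param pt A [phenotype_table()].
#' @return An object of class `cohort` with elements `genotypes`,
#'   `phenotypes` (sample-aligned) and `dropped` (per-side counts).
#' @export
join_cohort <- function(gt, pt) {
  stopifnot(inherits(gt, "genotype_table"), inherits(pt, "phenotype_table"))
  common <- sort(intersect(gt$samples, pt$sample))
  if (length(common) == 0) stop("no overlapping sample ids")
  dropped <- c(genotypes_only = length(setdiff(gt$samples, common)),
               phenotypes_only = length(setdiff(pt$sample, common)))
  gt2 <- genotype_table(gt$codes[common, , drop = FALSE], gt$snps,
                        samples = common)
  pt2 <- pt[match(common, pt$sample), , drop = FALSE]
  structure(list(genotypes = gt2, phenotypes = pt2, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  st <- x$phenotypes$status
  cat("<cohort> ", length(st), " samples (", sum(st == 1), " cases, ",
      sum(st == 0), " controls), ", nrow(x$genotypes$snps), " SNPs\n",
      sep = "")
  if (any(x$dropped > 0))
    cat("dropped at join:", x$dropped["genotypes_only"], "genotype-only,",
        x$dropped["phenotypes_only"], "phenotype-only\n")
  invisible(x)
}

cohort_outcome <- function(cohort, outcome) {
  outcome <- tolower(outcome)
  if (outcome == "status") return(cohort$phenotypes$status)
  if (!outcome %in% names(cohort$phenotypes))
    stop("outcome '", outcome, "' not present in cohort")
  cohort$phenotypes[[outcome]]
}

#' Genotype counts by outcome level
#'
#' Cross-tabulates the three genotype codes against a binary outcome.
#' Missing genotypes are excluded per SNP (complete cases per locus), so
#' table totals can differ between SNPs, as in per-locus genotyping studies.
#'
#' @param cohort A [join_cohort()] result.
#' @param snp SNP id.
#' @param stratum Outcome defining the two rows: `"status"` or a
#'   sub-phenotype column (`"aclf"`, `"acls"`, ...). Sub-phenotypes restrict
#'   the table to cases.
#' @return A 2x3 integer matrix, rows = outcome levels `0`/`1`, columns =
#'   genotype codes `1`/`2`/`3`.
#' @export
genotype_counts <- function(cohort, snp, stratum = "status") {
  stopifnot(inherits(cohort, "cohort"))
  j <- match(snp, cohort$genotypes$snps$id)
  if (is.na(j)) stop("unknown SNP: ", snp)
  y <- cohort_outcome(cohort, stratum)
  g <- cohort$genotypes$codes[, j]
  keep <- !is.na(y) & !is.na(g)
  if (!any(keep)) stop("no non-missing genotypes for ", snp, " in stratum ",
                       stratum)
  tab <- table(factor(y[keep], levels = 0:1),
               factor(g[keep], levels = 1:3))
  out <- matrix(as.integer(tab), nrow = 2, dimnames = dimnames(tab))
  names(dimnames(out)) <- c(stratum, snp)
  out
}

#' Compare demographics between cases and controls
#'
#' Continuous variables are compared with the Wilcoxon rank-sum test and
#' summarised as mean (SD) per group; categorical variables (factor or
#' character columns) with Fisher's exact test. A variable constant across
#' the cohort gets `p = 1` with a warning.
#'
#' @param cohort A [join_cohort()] result.
#' @param variables Columns of the phenotype table to compare; defaults to
#'   every covariate column (everything except `sample`, `status` and the
#'   sub-phenotypes).
#' @return A tibble with one row per variable: group means (SD) or counts,
#'   the test used, the statistic and the p-value.
#' @export
demographics_compare <- function(cohort, variables = NULL) {
  pt <- cohort$phenotypes
  if (is.null(variables))
    variables <- setdiff(names(pt), c("sample", "status", SUBTYPE_COLS))
  if (length(variables) == 0) stop("no covariate columns to compare")
  y <- pt$status
  if (min(table(factor(y, levels = 0:1))) < 2)
    stop("need at least 2 samples per group")
  rows <- lapply(variables, function(v) {
    x <- pt[[v]]
    keep <- !is.na(x)
    xv <- x[keep]; yv <- y[keep]
    if (length(unique(xv)) < 2) {
      warning("variable '", v, "' is constant; p set to 1")
      return(tibble::tibble(variable = v, test = "none",
                            control_summary = summarise_group(xv, yv, 0),
                            case_summary = summarise_group(xv, yv, 1),
                            statistic = NA_real_, p = 1))
    }
    if (is.numeric(xv)) {
      wt <- suppressWarnings(wilcox.test(xv[yv == 0], xv[yv == 1],
                                         exact = FALSE))
      tibble::tibble(variable = v, test = "wilcoxon",
                     control_summary = summarise_group(xv, yv, 0),
                     case_summary = summarise_group(xv, yv, 1),
                     statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      ft <- fisher.test(table(xv, yv))
      tibble::tibble(variable = v, test = "fisher",
                     control_summary = summarise_group(xv, yv, 0),
                     case_summary = summarise_group(xv, yv, 1),
                     statistic = NA_real_, p = ft$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

summarise_group <- function(x, y, level) {
  xg <- x[y == level]
  if (is.numeric(xg))
    sprintf("%.1f (%.1f)", mean(xg), stats::sd(xg))
  else
    paste(names(table(xg)), as.integer(table(xg)), sep = ":", collapse = ", ")
}
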