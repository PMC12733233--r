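#' Logistic association test for one SNP
#'
#' Maximum-likelihood logistic regression of a binary outcome on the
#' model-encoded genotype, optionally adjusting for covariates (the study
#' design adjusts for age and body mass). Per-contrast odds ratios are
#' `exp(coefficient)` with Wald confidence intervals; the reported p-value
#' is the likelihood-ratio test of the whole genotype term (2 df under the
#' codominant model, 1 df otherwise).
#'
#' Quasi-complete separation does not abort the fit: the affected estimates
#' are returned with `flagged = TRUE` and a diagnostic note.
#'
#' @param cohort A [join_cohort()] result.
#' @param snp SNP id.
#' @param outcome `"status"` or a sub-phenotype column name.
#' @param model Genetic model name (see [encode_model()]).
#' @param covariates Character vector of phenotype columns to adjust for,
#'   e.g. `c("age", "body_mass")`.
#' @param level Confidence level for the Wald intervals.
#' @return A tibble with one row per genotype contrast: `model`, `genotype`,
#'   `n0`, `n1`, `or`, `ci_low`, `ci_high`, `p` (block LRT), `ref`,
#'   `flagged`, `note`.
#' @export
logistic_association <- function(cohort, snp, outcome = "status",
                                 model = "codominant",
                                 covariates = character(), level = 0.95) {
  model <- match.arg(model, GENETIC_MODELS)
  j <- match(snp, cohort$genotypes$snps$id)
  if (is.na(j)) stop("unknown SNP: ", snp)
  y <- cohort_outcome(cohort, outcome)
  g <- cohort$genotypes$codes[, j]
  df <- data.frame(y = y, x = encode_model(g, model))
  for (cv in covariates) {
    if (!cv %in% names(cohort$phenotypes))
      stop("covariate '", cv, "' not present in cohort")
    df[[cv]] <- cohort$phenotypes[[cv]]
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2)
    stop("outcome '", outcome, "' does not have both levels present")
  if (model == "codominant") df$x <- droplevels(df$x)

  rhs <- paste(c("x", covariates), collapse = " + ")
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  mm <- stats::model.matrix(stats::as.formula(paste("y ~", rhs)), df)
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design matrix")

  separated <- FALSE
  handler <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      separated <<- TRUE
    invokeRestart("muffleWarning")
  }
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste("y ~", rhs)), family = binomial(), data = df),
    warning = handler)
  fit0 <- withCallingHandlers(
    glm(stats::as.formula(paste("y ~", rhs0)), family = binomial(), data = df),
    warning = handler)
  p_block <- anova(fit0, fit, test = "LRT")[2, "Pr(>Chi)"]
  if (any(abs(coef(fit)[grep("^x", names(coef(fit)))]) > 12, na.rm = TRUE))
    separated <- TRUE

  z <- qnorm(1 - (1 - level) / 2)
  terms <- grep("^x", names(coef(fit)), value = TRUE)
  gl <- genotype_labels_for(cohort$genotypes$snps, j)
  labs <- if (model == "codominant") model_group_labels(model, gl)
          else if (model == "log_additive") list(ref = "0 alleles",
                                                 contrasts = "per-allele")
          else model_group_labels(model, gl)
  n_by <- table(factor(df$y, levels = 0:1))
  ref_row <- tibble::tibble(model = model, genotype = labs$ref,
                            n0 = NA_integer_, n1 = NA_integer_, or = 1,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, ref = TRUE, flagged = FALSE,
                            note = NA_character_)
  rows <- lapply(seq_along(terms), function(k) {
    b <- coef(fit)[[terms[k]]]
    se <- sqrt(vcov(fit)[terms[k], terms[k]])
    tibble::tibble(model = model,
                   genotype = labs$contrasts[min(k, length(labs$contrasts))],
                   n0 = as.integer(n_by[["0"]]), n1 = as.integer(n_by[["1"]]),
                   or = exp(b), ci_low = exp(b - z * se),
                   ci_high = exp(b + z * se), p = p_block, ref = FALSE,
                   flagged = separated,
                   note = if (separated) "possible separation" else NA_character_)
  })
  out <- dplyr::bind_rows(c(list(ref_row), rows))
  if (model == "log_additive") out <- out[-1, , drop = FALSE]
  out
}

genotype_labels_for <- function(panel, j) {
  maj <- panel$major_allele[j]; mnr <- panel$minor_allele[j]
  c(paste0(maj, "/", maj), paste0(mnr, "/", maj), paste0(mnr, "/", mnr))
}
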