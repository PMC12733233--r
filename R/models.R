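GENETIC_MODELS <- c("codominant", "dominant", "recessive", "overdominant",
                    "log_additive")

#' Encode genotype codes under a genetic model
#'
#' Collapses the three genotype codes into the exposure contrast of a
#' genetic inheritance model, treating the minor allele as the risk factor:
#' * `codominant`: 3-level factor, homozygous major (code 1) as reference;
#' * `dominant`: carriers of any minor allele (`{2,3}`) vs. `{1}`;
#' * `recessive`: homozygous minor (`{3}`) vs. `{1,2}`;
#' * `overdominant`: heterozygotes (`{2}`) vs. homozygotes (`{1,3}`);
#' * `log_additive`: minor-allele dose `code - 1` (0/1/2).
#'
#' @param codes Integer genotype codes in `{1, 2, 3, NA}`.
#' @param model One of `r paste0('"', GENETIC_MODELS, '"', collapse = ", ")`.
#' @return A factor (codominant) or numeric vector; `NA` propagates.
#' @export
encode_model <- function(codes, model) {
  model <- match.arg(model, GENETIC_MODELS)
  if (any(!is.na(codes) & !(codes %in% 1:3)))
    stop("genotype codes must be 1, 2, 3 or NA")
  switch(model,
    codominant  = factor(codes, levels = 1:3),
    dominant    = as.numeric(codes >= 2),
    recessive   = as.numeric(codes == 3),
    overdominant = as.numeric(codes == 2),
    log_additive = as.numeric(codes - 1))
}

# genotype-group labels per model from the three genotype strings
model_group_labels <- function(model, gl) {
  switch(model,
    codominant  = list(ref = gl[1], contrasts = gl[2:3]),
    dominant    = list(ref = gl[1], contrasts = paste0(gl[2], "-", gl[3])),
    recessive   = list(ref = paste0(gl[1], "-", gl[2]), contrasts = gl[3]),
    overdominant = list(ref = paste0(gl[1], "-", gl[3]), contrasts = gl[2]))
}

# collapse a 2x3 genotype count table into the model's 2x2 (or keep 2x3)
collapse_counts <- function(counts, model) {
  stopifnot(is.matrix(counts), nrow(counts) == 2, ncol(counts) == 3)
  switch(model,
    dominant    = cbind(counts[, 1], counts[, 2] + counts[, 3]),
    recessive   = cbind(counts[, 1] + counts[, 2], counts[, 3]),
    overdominant = cbind(counts[, 1] + counts[, 3], counts[, 2]),
    codominant  = counts)
}

#' Model-wise association estimates from a genotype count table
#'
#' Computes the crude (cross-product) odds ratios with Woolf 95% CIs and the
#' likelihood-ratio block p-value for one SNP/outcome from its 2x3 genotype
#' counts, under one genetic model. This is the estimator whose output
#' matches published within-case association tables computed from printed
#' counts. The codominant model yields one reference row plus two contrast
#' rows sharing a single 2-df block p-value; the collapsed models yield a
#' reference and one contrast row.
#'
#' @param counts 2x3 matrix as returned by [genotype_counts()] (rows:
#'   outcome 0/1; columns: genotype codes 1/2/3).
#' @param model Genetic model name (`"log_additive"` is fitted as a logistic
#'   dose model on the expanded counts).
#' @param genotype_labels Character length-3 genotype display labels, e.g.
#'   `c("D/D", "I/D", "I/I")`.
#' @param level Confidence level.
#' @return A tibble: `model`, `genotype`, `n0`, `n1`, `or`, `ci_low`,
#'   `ci_high`, `p` (block p, `NA` on the reference row), `ref`.
#' @export
assoc_from_counts <- function(counts, model,
                              genotype_labels = c("A/A", "A/B", "B/B"),
                              level = 0.95) {
  model <- match.arg(model, GENETIC_MODELS)
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (model == "log_additive") return(log_additive_from_counts(counts, level))
  cc <- collapse_counts(counts, model)
  labs <- model_group_labels(model, genotype_labels)
  p_block <- g_test(cc)
  ref_row <- tibble::tibble(model = model, genotype = labs$ref,
                            n0 = cc[1, 1], n1 = cc[2, 1],
                            or = 1, ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, ref = TRUE)
  contrast_rows <- lapply(seq_along(labs$contrasts), function(k) {
    est <- crude_odds_ratio(a = cc[2, k + 1], b = cc[1, k + 1],
                            c = cc[2, 1], d = cc[1, 1], level = level)
    tibble::tibble(model = model, genotype = labs$contrasts[k],
                   n0 = cc[1, k + 1], n1 = cc[2, k + 1],
                   or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
                   p = p_block, ref = FALSE)
  })
  dplyr::bind_rows(c(list(ref_row), contrast_rows))
}

log_additive_from_counts <- function(counts, level = 0.95) {
  dose <- rep(c(0, 1, 2, 0, 1, 2), times = c(counts[1, ], counts[2, ]))
  y <- rep(c(0, 1), times = c(sum(counts[1, ]), sum(counts[2, ])))
  fit <- glm(y ~ dose, family = binomial())
  null <- glm(y ~ 1, family = binomial())
  p <- anova(null, fit, test = "LRT")[2, "Pr(>Chi)"]
  z <- qnorm(1 - (1 - level) / 2)
  b <- coef(fit)[["dose"]]
  se <- sqrt(vcov(fit)["dose", "dose"])
  tibble::tibble(model = "log_additive", genotype = "per-allele",
                 n0 = sum(counts[1, ]), n1 = sum(counts[2, ]),
                 or = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se), p = p, ref = FALSE)
}
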