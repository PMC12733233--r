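# Bundled result tables of the MMP-ACL case-control study that this
# package's defaults emulate (three MMP SNPs, 160 injured football players /
# 136 controls). Individual-level data are not public; the printed genotype
# count tables and test summaries below are the reproducible surface.

#' Within-case genotype counts by sub-phenotype
#'
#' Genotype counts (codes 1/2/3 = hom. major / het / hom. minor) for each
#' SNP and injury sub-phenotype within the case group, as published.
#' Totals differ slightly between SNPs because missing genotypes are
#' excluded per locus.
#'
#' @return A tibble: `snp`, `outcome`, `n0_1`, `n0_2`, `n0_3` (outcome level
#'   0) and `n1_1`, `n1_2`, `n1_3` (outcome level 1).
#' @export
acl_within_case_counts <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~snp,        ~outcome, ~n0_1, ~n0_2, ~n0_3, ~n1_1, ~n1_2, ~n1_3,
    "rs1799750", "aclf",      33,    58,    10,    15,    23,    20,
    "rs1799750", "acls",      12,    13,     6,    36,    68,    24,
    "rs1799750", "aclrp",     28,    69,    23,    20,    12,     7,
    "rs1799750", "aclrc",     37,    73,    30,    11,     8,     0,
    "rs486055",  "aclf",      62,    35,     4,    42,    15,     2,
    "rs486055",  "acls",      19,    11,     1,    85,    39,     5,
    "rs486055",  "aclrp",     86,    29,     5,    18,    21,     1,
    "rs486055",  "aclrc",     94,    42,     5,    10,     8,     1,
    "rs2276109", "aclf",      89,    11,     1,    39,    17,     3,
    "rs2276109", "acls",      27,     4,     0,   101,    24,     4,
    "rs2276109", "aclrp",     94,    23,     3,    34,     5,     1,
    "rs2276109", "aclrc",    111,    26,     4,    17,     2,     0)
}

#' Published within-case association results
#'
#' Odds ratios, Woolf 95% CIs, block p-values and FDR-adjusted p-values as
#' published for the within-case analyses (one row per genotype contrast;
#' the two codominant contrasts share a block p). Zero-cell rows carry
#' `or = 0` with the CI omitted (`NA`). The within-case FDR family has
#' m = 48 members (3 SNPs x 4 outcomes x 4 models).
#'
#' @return A tibble: `snp`, `outcome`, `model`, `contrast` (2 = het vs ref,
#'   3 = hom. minor vs ref, 1 = the collapsed model's single contrast),
#'   `or`, `ci_low`, `ci_high`, `p`, `p_fdr`.
#' @export
acl_within_case_results <- function() {
  tibble::tribble(
    ~snp, ~outcome, ~model, ~contrast, ~or, ~ci_low, ~ci_high, ~p, ~p_fdr,
    "rs1799750", "aclf",  "codominant",   2, 0.87, 0.40,  1.90, 0.001,  0.0096,
    "rs1799750", "aclf",  "codominant",   3, 4.40, 1.66, 11.65, 0.001,  0.0096,
    "rs1799750", "aclf",  "dominant",     1, 1.39, 0.68,  2.86, 0.365,  0.631,
    "rs1799750", "aclf",  "recessive",    1, 4.79, 2.05, 11.19, 0.0002, 0.0096,
    "rs1799750", "aclf",  "overdominant", 1, 0.49, 0.25,  0.94, 0.031,  0.099,
    "rs1799750", "acls",  "codominant",   2, 1.74, 0.72,  4.21, 0.468,  0.702,
    "rs1799750", "acls",  "codominant",   3, 1.33, 0.44,  4.04, 0.468,  0.702,
    "rs1799750", "acls",  "dominant",     1, 1.61, 0.71,  3.66, 0.257,  0.549,
    "rs1799750", "acls",  "recessive",    1, 0.96, 0.36,  2.60, 0.939,  1.0,
    "rs1799750", "acls",  "overdominant", 1, 1.57, 0.71,  3.47, 0.263,  0.549,
    "rs1799750", "aclrp", "codominant",   2, 0.24, 0.11,  0.56, 0.003,  0.018,
    "rs1799750", "aclrp", "codominant",   3, 0.43, 0.15,  1.18, 0.003,  0.018,
    "rs1799750", "aclrp", "dominant",     1, 0.29, 0.14,  0.62, 0.001,  0.0096,
    "rs1799750", "aclrp", "recessive",    1, 0.92, 0.36,  2.35, 0.865,  0.944,
    "rs1799750", "aclrp", "overdominant", 1, 0.33, 0.15,  0.71, 0.003,  0.018,
    "rs1799750", "aclrc", "codominant",   2, 0.37, 0.14,  0.99, 0.006,  0.024,
    "rs1799750", "aclrc", "codominant",   3, 0.00,   NA,    NA, 0.006,  0.024,
    "rs1799750", "aclrc", "dominant",     1, 0.26, 0.10,  0.70, 0.007,  0.026,
    "rs1799750", "aclrc", "recessive",    1, 0.00,   NA,    NA, 0.025,  0.086,
    "rs1799750", "aclrc", "overdominant", 1, 0.67, 0.25,  1.76, 0.411,  0.680,
    "rs486055",  "aclf",  "codominant",   2, 0.63, 0.31,  1.30, 0.444,  0.687,
    "rs486055",  "aclf",  "codominant",   3, 0.74, 0.13,  4.21, 0.444,  0.687,
    "rs486055",  "aclf",  "dominant",     1, 0.64, 0.32,  1.28, 0.207,  0.549,
    "rs486055",  "aclf",  "recessive",    1, 0.85, 0.15,  4.79, 0.854,  0.944,
    "rs486055",  "aclf",  "overdominant", 1, 0.64, 0.31,  1.31, 0.220,  0.549,
    "rs486055",  "acls",  "codominant",   2, 0.79, 0.34,  1.82, 0.850,  0.944,
    "rs486055",  "acls",  "codominant",   3, 1.12, 0.12, 10.13, 0.850,  0.944,
    "rs486055",  "acls",  "dominant",     1, 0.82, 0.36,  1.84, 0.632,  0.798,
    "rs486055",  "acls",  "recessive",    1, 1.21, 0.14, 10.74, 0.862,  0.944,
    "rs486055",  "acls",  "overdominant", 1, 0.79, 0.34,  1.80, 0.574,  0.798,
    "rs486055",  "aclrp", "codominant",   2, 3.46, 1.62,  7.38, 0.005,  0.022,
    "rs486055",  "aclrp", "codominant",   3, 0.96, 0.11,  8.68, 0.005,  0.022,
    "rs486055",  "aclrp", "dominant",     1, 3.09, 1.48,  6.47, 0.003,  0.018,
    "rs486055",  "aclrp", "recessive",    1, 0.59, 0.07,  5.20, 0.616,  0.798,
    "rs486055",  "aclrp", "overdominant", 1, 3.47, 1.64,  7.33, 0.001,  0.0096,
    "rs486055",  "aclrc", "codominant",   2, 1.79, 0.66,  4.86, 0.496,  0.721,
    "rs486055",  "aclrc", "codominant",   3, 1.88, 0.20, 17.73, 0.496,  0.721,
    "rs486055",  "aclrc", "dominant",     1, 1.80, 0.68,  4.73, 0.237,  0.549,
    "rs486055",  "aclrc", "recessive",    1, 1.51, 0.17, 13.67, 0.725,  0.870,
    "rs486055",  "aclrc", "overdominant", 1, 1.71, 0.64,  4.57, 0.287,  0.574,
    "rs2276109", "aclf",  "codominant",   2, 3.53, 1.51,  8.22, 0.004,  0.021,
    "rs2276109", "aclf",  "codominant",   3, 6.85, 0.69, 67.89, 0.004,  0.021,
    "rs2276109", "aclf",  "dominant",     1, 3.80, 1.69,  8.54, 0.0009, 0.0096,
    "rs2276109", "aclf",  "recessive",    1, 5.36, 0.54, 52.73, 0.116,  0.348,
    "rs2276109", "aclf",  "overdominant", 1, 3.31, 1.43,  7.69, 0.005,  0.022,
    "rs2276109", "acls",  "codominant",   2, 1.60, 0.51,  5.02, 0.598,  0.798,
    "rs2276109", "acls",  "codominant",   3, 0.00,   NA,    NA, 0.598,  0.798,
    "rs2276109", "acls",  "dominant",     1, 1.87, 0.60,  5.80, 0.252,  0.549,
    "rs2276109", "acls",  "recessive",    1, 0.00,   NA,    NA, 1.0,    1.0,
    "rs2276109", "acls",  "overdominant", 1, 1.54, 0.49,  4.82, 0.440,  0.687,
    "rs2276109", "aclrp", "codominant",   2, 0.60, 0.21,  1.71, 0.611,  0.798,
    "rs2276109", "aclrp", "codominant",   3, 0.92, 0.09,  9.16, 0.611,  0.798,
    "rs2276109", "aclrp", "dominant",     1, 0.64, 0.24,  1.68, 0.340,  0.628,
    "rs2276109", "aclrp", "recessive",    1, 1.00, 0.10,  9.89, 1.0,    1.0,
    "rs2276109", "aclrp", "overdominant", 1, 0.60, 0.21,  1.71, 0.322,  0.618,
    "rs2276109", "aclrc", "codominant",   2, 0.50, 0.11,  2.31, 0.718,  0.870,
    "rs2276109", "aclrc", "codominant",   3, 0.00,   NA,    NA, 0.718,  0.870,
    "rs2276109", "aclrc", "dominant",     1, 0.44, 0.10,  1.99, 0.240,  0.549,
    "rs2276109", "aclrc", "recessive",    1, 0.00,   NA,    NA, 1.0,    1.0,
    "rs2276109", "aclrc", "overdominant", 1, 0.52, 0.11,  2.39, 0.368,  0.631)
}

#' Published case-control genotype counts and test summaries
#'
#' Genotype counts of the case-control comparison as printed, together with
#' the published (covariate-adjusted) per-model p-values and their FDR
#' adjustments (family m = 12). The two count columns are kept under
#' neutral names because the published column headers are internally
#' inconsistent with the stated group sizes: `n_groupA_*` sums to 136
#' (the control group size) and `n_groupB_*` to ~158. Downstream defaults
#' treat group A as the controls; see `maf_source` of [study_control_mafs()].
#' The published adjusted odds ratios are included for reference but are not
#' reproducible from counts alone (they condition on unavailable
#' individual-level covariates).
#'
#' @return A list with tibbles `counts` (per SNP: `n_groupA_1..3`,
#'   `n_groupB_1..3`) and `tests` (per SNP and model: `or` — adjusted,
#'   non-reference contrast; codominant rows give the heterozygote contrast
#'   — `p`, `p_fdr`).
#' @export
acl_case_control_tables <- function() {
  counts <- tibble::tribble(
    ~snp,        ~n_groupA_1, ~n_groupA_2, ~n_groupA_3,
                 ~n_groupB_1, ~n_groupB_2, ~n_groupB_3,
    "rs1799750",  34, 57, 45,  48, 80, 30,
    "rs486055",   98, 35,  3, 103, 50,  6,
    "rs2276109", 106, 30,  0, 128, 27,  4)
  tests <- tibble::tribble(
    ~snp,        ~model,         ~or,  ~p,    ~p_fdr,
    "rs1799750", "codominant",   1.70, 0.018, 0.072,
    "rs1799750", "dominant",     1.13, 0.728, 0.728,
    "rs1799750", "recessive",    0.42, 0.014, 0.072,
    "rs1799750", "overdominant", 2.23, 0.011, 0.072,
    "rs486055",  "codominant",   1.21, 0.674, 0.728,
    "rs486055",  "dominant",     1.13, 0.718, 0.728,
    "rs486055",  "recessive",    0.51, 0.486, 0.716,
    "rs486055",  "overdominant", 1.24, 0.537, 0.716,
    "rs2276109", "codominant",   1.50, 0.209, 0.418,
    "rs2276109", "dominant",     1.62, 0.206, 0.418,
    "rs2276109", "recessive",    0.00, 0.152, 0.418,
    "rs2276109", "overdominant", 1.46, 0.324, 0.555)
  list(counts = counts, tests = tests)
}

#' Case-group genotype counts and published HWE p-values
#'
#' Genotype counts implied by the published case-group genotype frequencies
#' (percentages of n = 160, or 159 for rs1799750 which has one missing
#' genotype), with the published exact HWE p-values.
#'
#' @return A tibble: `snp`, `n1`, `n2`, `n3`, `hwe_p_published`.
#' @export
acl_case_genotype_counts <- function() {
  tibble::tribble(
    ~snp,        ~n1, ~n2, ~n3, ~hwe_p_published,
    "rs1799750",  48,  81,  30, 0.749,
    "rs486055",  104,  50,   6, 1.00,
    "rs2276109", 128,  28,   4, 0.115)
}

#' Published group characteristics
#'
#' Mean (SD) of the demographic covariates per group and the published
#' Wilcoxon rank-sum p-values.
#'
#' @return A tibble: `variable`, `control_mean`, `control_sd`, `case_mean`,
#'   `case_sd`, `p_published` (0.001 stands for the printed "<0.001").
#' @export
acl_demographics <- function() {
  tibble::tribble(
    ~variable,   ~control_mean, ~control_sd, ~case_mean, ~case_sd, ~p_published,
    "age",                  27,           4,         36,        7,        0.001,
    "height",              178,           7,        178,        6,        0.284,
    "body_mass",            73,          16,         78,       10,        0.001)
}

#' Study control-group minor allele frequencies
#'
#' MAFs computed from the case-control genotype counts, used as the default
#' MAFs of the power module and the cohort simulator ("MAFs estimated in
#' controls"). The published column headers conflict with the stated group
#' sizes, so which column holds the controls is configurable: `"groupA"`
#' (sums to 136, the stated control N; the default — its rs486055 MAF of
#' 0.15 matches the published recessive-model power remark) or `"groupB"`.
#'
#' @param maf_source `"groupA"` or `"groupB"`.
#' @return Named numeric vector of per-SNP MAFs.
#' @export
study_control_mafs <- function(maf_source = c("groupA", "groupB")) {
  maf_source <- match.arg(maf_source)
  cc <- acl_case_control_tables()$counts
  pre <- if (maf_source == "groupA") "n_groupA_" else "n_groupB_"
  n1 <- cc[[paste0(pre, 1)]]; n2 <- cc[[paste0(pre, 2)]]
  n3 <- cc[[paste0(pre, 3)]]
  maf <- (2 * n3 + n2) / (2 * (n1 + n2 + n3))
  maf <- pmin(maf, 1 - maf)
  setNames(maf, cc$snp)
}

#' Within-case sub-phenotype group sizes
#'
#' Sizes of the 0/1 groups for each injury sub-phenotype among the 160
#' cases, as printed (modal values across the per-SNP tables, which differ
#' by at most one missing genotype).
#'
#' @return A tibble: `outcome`, `n0`, `n1`.
#' @export
acl_subtype_sizes <- function() {
  tibble::tribble(
    ~outcome, ~n0, ~n1,
    "aclf",   101,  59,
    "acls",    31, 129,
    "aclrp",  120,  40,
    "aclrc",  141,  19)
}
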