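# shared fixtures: tiny panels and cohorts built in code

toy_panel <- function(L = 2) {
  snp_panel(paste0("snp", seq_len(L)),
            major_allele = rep("A", L), minor_allele = rep("B", L))
}

# cohort holding one SNP whose genotype x outcome table equals `counts`
# (2x3 matrix: rows outcome 0/1, columns codes 1/2/3); outcome stored both
# as case status and, when all are cases, as a sub-phenotype column
cohort_from_counts <- function(counts, snp = "snp1", major = "A",
                               minor = "B", subtype = NULL) {
  codes <- c(rep(1:3, counts[1, ]), rep(1:3, counts[2, ]))
  y <- rep(0:1, rowSums(counts))
  n <- length(y)
  gt <- genotype_table(matrix(codes, ncol = 1), snp_panel(snp, major, minor),
                       samples = sprintf("s%03d", seq_len(n)))
  ph <- data.frame(sample = sprintf("s%03d", seq_len(n)))
  if (is.null(subtype)) {
    ph$status <- y
  } else {
    ph$status <- 1L
    ph[[subtype]] <- y
  }
  join_cohort(gt, phenotype_table(ph))
}

# within-case 2x3 count matrix for one SNP/outcome from the bundled tables
study_counts_matrix <- function(snp, outcome) {
  k <- acl_within_case_counts()
  k <- k[k$snp == snp & k$outcome == outcome, ]
  matrix(c(k$n0_1, k$n0_2, k$n0_3, k$n1_1, k$n1_2, k$n1_3),
         nrow = 2, byrow = TRUE, dimnames = list(0:1, 1:3))
}

# genotype labels (hom-major, het, hom-minor) for a panel SNP
study_genotype_labels <- function(snp) {
  p <- mmp_panel()
  j <- match(snp, p$id)
  c(paste0(p$major_allele[j], "/", p$major_allele[j]),
    paste0(p$minor_allele[j], "/", p$major_allele[j]),
    paste0(p$minor_allele[j], "/", p$minor_allele[j]))
}

# fast annealing settings for tests
test_logic_control <- function(...) {
  logic_control(moves_per_temp = 50, max_moves = 2500,
                stop_no_improve = 1500, ...)
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
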