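test_that("delimited genotype round-trip is the identity, missing included", {
  withr::with_seed(42, {
    codes <- matrix(sample(c(1:3, NA), 30, replace = TRUE), 10, 3)
  })
  gt <- genotype_table(codes, mmp_panel())
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gt, path)
  gt2 <- read_genotypes(path, mmp_panel())
  expect_identical(gt2$codes, gt$codes)
  expect_identical(gt2$samples, gt$samples)
})

test_that("allele strings map to codes relative to the declared minor allele", {
  p <- mmp_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,rs1799750,rs486055,rs2276109",
               "s1,I/I,C/T,A/A",
               "s2,D/I,C/C,A/G",
               "s3,D/D,,G/G"), path)
  gt <- read_genotypes(path, p)
  expect_equal(unname(gt$codes[, "rs1799750"]), c(3L, 2L, 1L))
  expect_equal(unname(gt$codes[, "rs486055"]), c(2L, 1L, NA))
  expect_equal(unname(gt$codes[, "rs2276109"]), c(1L, 2L, 3L))
})

test_that("malformed or out-of-panel alleles are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,rs1799750", "s1,I/X"), path)
  expect_error(read_genotypes(path, mmp_panel()[1, ]), "rs1799750")
  writeLines(c("sample,rs1799750", "s1,IDI"), path)
  expect_error(read_genotypes(path, mmp_panel()[1, ]), "malformed")
})

test_that("VCF genotypes map through REF/ALT onto the panel coding", {
  # rs2276109 has REF = panel major; rs1799750 is swapped (REF = minor I)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "11\t100\trs1799750\tI\tD\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "11\t200\trs2276109\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t./."),
    path)
  panel <- snp_panel(c("rs1799750", "rs2276109"), c("D", "A"), c("I", "G"))
  gt <- read_genotypes(path, panel, format = "vcf")
  # REF=I is the minor allele: 0/0 -> hom minor -> 3
  expect_equal(unname(gt$codes[, "rs1799750"]), c(3L, 2L, 1L))
  expect_equal(unname(gt$codes[, "rs2276109"]), c(2L, 3L, NA))
})

test_that("allele relabelling is involutive and maps codes 1<->3", {
  withr::with_seed(7, {
    codes <- matrix(sample(c(1:3, NA), 45, replace = TRUE), 15, 3)
  })
  gt <- genotype_table(codes, mmp_panel())
  sw <- swap_alleles(gt, "rs486055")
  expect_equal(unname(sw$codes[, "rs486055"]),
               unname(4L - gt$codes[, "rs486055"]))
  expect_equal(unname(sw$codes[, "rs1799750"]),
               unname(gt$codes[, "rs1799750"]))
  expect_identical(swap_alleles(sw, "rs486055")$codes, gt$codes)
})

test_that("phenotype validation enforces the case-only sub-phenotype rule", {
  base <- data.frame(sample = c("a", "b"), status = c(0, 1))
  expect_s3_class(phenotype_table(base), "phenotype_table")
  expect_error(phenotype_table(transform(base, status = c(2, 1))), "status")
  bad <- transform(base, aclf = c(1, NA))
  expect_error(phenotype_table(bad), "control")
  ok <- transform(base, aclf = c(NA, 1))
  expect_equal(phenotype_table(ok)$aclf, c(NA, 1L))
  empty <- transform(base, aclrp = c(NA, NA))
  expect_false("aclrp" %in% names(phenotype_table(empty)))
})

test_that("study-sized phenotype file reads back with the printed group sizes", {
  df <- data.frame(sample = sprintf("s%03d", 1:296),
                   status = rep(c(1, 0), c(160, 136)))
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  pt <- read_phenotypes(path)
  expect_equal(sum(pt$status == 1), 160)
  expect_equal(sum(pt$status == 0), 136)
})

test_that("join is an inner join with per-side dropped counts", {
  gt <- genotype_table(matrix(1L, 3, 2), toy_panel(),
                       samples = c("a", "b", "extra"))
  pt <- phenotype_table(data.frame(sample = c("b", "a"), status = c(1, 0)))
  cc <- join_cohort(gt, pt)
  expect_equal(length(cc$phenotypes$sample), 2)
  expect_equal(unname(cc$dropped["genotypes_only"]), 1)
  expect_equal(unname(cc$dropped["phenotypes_only"]), 0)
  expect_error(join_cohort(gt, phenotype_table(
    data.frame(sample = "zzz", status = 1))), "overlap")
})

test_that("join is invariant to input row order", {
  withr::with_seed(11, {
    codes <- matrix(sample(1:3, 20, replace = TRUE), 10, 2)
    ids <- sprintf("s%02d", 1:10)
    gt1 <- genotype_table(codes, toy_panel(), samples = ids)
    perm <- sample(10)
    gt2 <- genotype_table(codes[perm, ], toy_panel(), samples = ids[perm])
    pt <- phenotype_table(data.frame(sample = rev(ids),
                                     status = rep(c(0, 1), 5)))
    c1 <- join_cohort(gt1, pt)
    c2 <- join_cohort(gt2, pt)
    expect_identical(c1$genotypes$codes, c2$genotypes$codes)
    expect_identical(c1$phenotypes, c2$phenotypes)
  })
})

test_that("genotype_counts reproduces a published within-case block", {
  counts <- study_counts_matrix("rs1799750", "aclf")
  cc <- cohort_from_counts(counts, snp = "rs1799750", major = "D",
                           minor = "I", subtype = "aclf")
  tab <- genotype_counts(cc, "rs1799750", stratum = "aclf")
  expect_equal(unname(tab), unname(counts))
  # printed Table values: single {33, 58, 10}, multiple {15, 23, 20}
  expect_equal(unname(tab[1, ]), c(33, 58, 10))
  expect_equal(unname(tab[2, ]), c(15, 23, 20))
})

test_that("genotype_counts excludes missing per locus and conserves totals", {
  codes <- matrix(c(1, 2, 3, NA, 2, rep(1, 5)), ncol = 2)
  gt <- genotype_table(codes, toy_panel(), samples = letters[1:5])
  pt <- phenotype_table(data.frame(sample = letters[1:5],
                                   status = c(0, 0, 1, 1, 1)))
  cc <- join_cohort(gt, pt)
  tab <- genotype_counts(cc, "snp1")
  expect_equal(sum(tab), 4)  # one missing genotype dropped
  gt_allna <- genotype_table(matrix(NA_integer_, 5, 2), toy_panel(),
                             samples = letters[1:5])
  cc2 <- join_cohort(gt_allna, pt)
  expect_error(genotype_counts(cc2, "snp1"), "non-missing")
})

test_that("demographics: rank-sum matches direct rank computation on a toy", {
  x0 <- c(1.2, 3.4, 2.2, 5.0)
  x1 <- c(2.8, 4.1, 6.3, 0.7)
  gt <- genotype_table(matrix(1L, 8, 1), toy_panel(1),
                       samples = sprintf("s%d", 1:8))
  pt <- phenotype_table(data.frame(sample = sprintf("s%d", 1:8),
                                   status = rep(0:1, each = 4),
                                   age = c(x0, x1)))
  out <- demographics_compare(join_cohort(gt, pt))
  r <- rank(c(x0, x1))
  W_oracle <- sum(r[1:4]) - 4 * 5 / 2  # Mann-Whitney U of group 0
  expect_equal(out$statistic[out$variable == "age"], W_oracle)
})

test_that("demographics: identical groups give p = 1, constants warn", {
  gt <- genotype_table(matrix(1L, 8, 1), toy_panel(1),
                       samples = sprintf("s%d", 1:8))
  pt <- phenotype_table(data.frame(sample = sprintf("s%d", 1:8),
                                   status = rep(0:1, each = 4),
                                   age = rep(c(20, 30, 40, 50), 2),
                                   site = rep("x", 8)))
  expect_warning(out <- demographics_compare(join_cohort(gt, pt)), "constant")
  expect_equal(out$p[out$variable == "age"], 1)
  expect_equal(out$p[out$variable == "site"], 1)
})

test_that("demographics: categorical covariates go through Fisher's test", {
  gt <- genotype_table(matrix(1L, 8, 1), toy_panel(1),
                       samples = sprintf("s%d", 1:8))
  pt <- phenotype_table(data.frame(sample = sprintf("s%d", 1:8),
                                   status = rep(0:1, each = 4),
                                   side = c("L", "L", "R", "L",
                                            "R", "R", "L", "R")))
  out <- demographics_compare(join_cohort(gt, pt))
  expect_equal(out$test, "fisher")
  tab <- table(c("L", "L", "R", "L", "R", "R", "L", "R"), rep(0:1, each = 4))
  expect_equal(out$p, fisher.test(tab)$p.value)
})
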