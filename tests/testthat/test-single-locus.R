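test_that("model encodings follow the inheritance definitions", {
  expect_equal(encode_model(c(1, 2, 3), "dominant"), c(0, 1, 1))
  expect_equal(encode_model(c(1, 2, 3), "recessive"), c(0, 0, 1))
  expect_equal(encode_model(c(1, 2, 3), "overdominant"), c(0, 1, 0))
  expect_equal(encode_model(c(1, 2, 3), "log_additive"), c(0, 1, 2))
  cod <- encode_model(c(1, 2, 3, NA), "codominant")
  expect_s3_class(cod, "factor")
  expect_equal(levels(cod), c("1", "2", "3"))
  expect_true(is.na(cod[4]))
  expect_error(encode_model(1:3, "multiplicative"), "arg")
  expect_error(encode_model(c(1, 5), "dominant"), "codes")
})

test_that("counts-based estimates mirror published blocks per model", {
  counts <- study_counts_matrix("rs2276109", "aclf")
  gl <- study_genotype_labels("rs2276109")
  dom <- assoc_from_counts(counts, "dominant", gl)
  expect_equal(dom$or[dom$ref], 1)
  expect_equal(round(dom$or[!dom$ref], 2), 3.80)
  expect_equal(round(dom$ci_low[!dom$ref], 2), 1.69)
  expect_equal(round(dom$ci_high[!dom$ref], 2), 8.54)
  cod <- assoc_from_counts(counts, "codominant", gl)
  expect_equal(nrow(cod), 3)
  expect_equal(round(cod$or[2], 2), 3.53)  # heterozygote contrast
  expect_equal(length(unique(cod$p[!cod$ref])), 1)  # one 2-df block p
  over <- assoc_from_counts(counts, "overdominant", gl)
  expect_equal(round(over$or[!over$ref], 2), 3.31)
})

test_that("unadjusted logistic OR equals the crude cross-product ratio", {
  counts <- study_counts_matrix("rs486055", "aclrp")
  cc <- cohort_from_counts(counts, snp = "rs486055", major = "C", minor = "T",
                           subtype = "aclrp")
  for (model in c("dominant", "recessive", "overdominant")) {
    fit <- logistic_association(cc, "rs486055", outcome = "aclrp",
                                model = model)
    crude <- assoc_from_counts(counts, model)
    expect_equal(fit$or[!fit$ref], crude$or[!crude$ref], tolerance = 1e-6)
    expect_equal(fit$p[!fit$ref], crude$p[!crude$ref], tolerance = 1e-6)
  }
})

test_that("logistic LRT is calibrated under the null", {
  withr::with_seed(808, {
    rej <- 0
    nsim <- 300
    for (i in 1:nsim) {
      g <- simulate_genotypes(400, 0.3)
      y <- rbinom(400, 1, 0.5)
      p <- assoc_from_counts(table(factor(y, 0:1), factor(g, 1:3)),
                             "dominant")$p[2]
      rej <- rej + (p < 0.05)
    }
    expect_within(rej / nsim, 0.02, 0.09)
  })
})

test_that("separation is flagged, not fatal; rank deficiency errors", {
  withr::with_seed(3, {
    n <- 60
    g <- simulate_genotypes(n, 0.3)
    y <- as.integer(g >= 2)  # outcome identical to the dominant encoding
    gt <- genotype_table(matrix(g, ncol = 1), toy_panel(1),
                         samples = sprintf("s%d", 1:n))
    pt <- phenotype_table(data.frame(sample = sprintf("s%d", 1:n),
                                     status = y, age = rnorm(n, 30, 5)))
    cc <- join_cohort(gt, pt)
    fit <- logistic_association(cc, "snp1", model = "dominant")
    expect_true(all(fit$flagged[!fit$ref]))
    pt2 <- pt
    pt2$age2 <- pt2$age  # duplicated covariate column
    cc2 <- join_cohort(gt, phenotype_table(pt2))
    expect_error(logistic_association(cc2, "snp1", model = "dominant",
                                      covariates = c("age", "age2")),
                 "rank")
  })
})

test_that("adjusted estimator shifts the OR when a confounder is present", {
  withr::with_seed(21, {
    n <- 1200
    g <- simulate_genotypes(n, 0.4)
    age <- rnorm(n, 30, 5) + 2 * (g - 1)       # age depends on genotype
    y <- rbinom(n, 1, plogis(-3 + 0.1 * age))  # outcome depends on age only
    gt <- genotype_table(matrix(g, ncol = 1), toy_panel(1),
                         samples = sprintf("s%04d", 1:n))
    pt <- phenotype_table(data.frame(sample = sprintf("s%04d", 1:n),
                                     status = y, age = age))
    cc <- join_cohort(gt, pt)
    crude <- logistic_association(cc, "snp1", model = "log_additive")
    adj <- logistic_association(cc, "snp1", model = "log_additive",
                                covariates = "age")
    expect_gt(crude$or, adj$or)  # adjustment removes the confounded excess
    expect_lt(abs(log(adj$or)), abs(log(crude$or)))
  })
})

test_that("scan yields one block p per SNP x outcome x model with family FDR", {
  cc <- simulate_cohort(sim_config(seed = 61))
  sc <- run_single_locus_scan(cc, outcomes = c("aclf", "acls", "aclrp",
                                               "aclrc"))
  blocks <- unique(paste(sc$snp, sc$outcome, sc$model))
  expect_equal(length(blocks), 48)
  one_p <- tapply(sc$p[!sc$ref], paste(sc$snp, sc$outcome, sc$model)[!sc$ref],
                  function(v) length(unique(v)))
  expect_true(all(one_p == 1))
  nr <- sc[!sc$ref & !is.na(sc$p), ]
  block_tbl <- nr[!duplicated(paste(nr$snp, nr$outcome, nr$model)), ]
  expect_equal(block_tbl$p_fdr, bh_adjust(block_tbl$p))
  expect_true(all(sc$p_fdr >= sc$p, na.rm = TRUE))
})

test_that("scan flags empty strata instead of aborting", {
  counts <- study_counts_matrix("rs1799750", "aclf")
  cc <- cohort_from_counts(counts, snp = "rs1799750", major = "D",
                           minor = "I", subtype = "aclf")
  sc <- run_single_locus_scan(cc, outcomes = c("aclf", "aclrc"))
  aclrc_rows <- sc[sc$outcome == "aclrc", ]
  expect_true(all(!is.na(aclrc_rows$note)))  # no aclrc labels in fixture
  aclf_rows <- sc[sc$outcome == "aclf" & !sc$ref, ]
  expect_true(all(is.na(aclf_rows$note)))
})
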