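test_that("single-SNP haplotype frequencies equal allele frequencies", {
  codes <- matrix(c(1L, 2L, 2L, 3L, 1L, 2L), ncol = 1)
  gt <- genotype_table(codes, toy_panel(1))
  hs <- em_haplotype_frequencies(gt)
  maf <- sum(codes - 1) / (2 * nrow(codes))
  expect_equal(hs$haplotypes$freq[hs$haplotypes$label == "B"], maf,
               tolerance = 1e-9)
  expect_true(hs$converged)
})

test_that("fully phased individuals give direct-count frequencies", {
  # doubly homozygous: no ambiguity, frequencies are haplotype counts / 2n
  codes <- rbind(c(1L, 1L), c(3L, 3L), c(1L, 3L), c(3L, 3L))
  gt <- genotype_table(codes, toy_panel(2))
  hs <- em_haplotype_frequencies(gt)
  f <- setNames(hs$haplotypes$freq, hs$haplotypes$label)
  expect_equal(unname(f["A-A"]), 2 / 8)
  expect_equal(unname(f["B-B"]), 4 / 8)
  expect_equal(unname(f["A-B"]), 2 / 8)
})

test_that("EM matches the brute-force likelihood grid maximiser to 1e-4", {
  true_f <- c(0.5, 0.3, 0.15, 0.05)  # (A-A, A-B, B-A, B-B)
  for (seed in c(101, 202, 303)) {
    codes <- sim_hap2(50, true_f, seed)
    gt <- genotype_table(codes, toy_panel(2))
    hs <- em_haplotype_frequencies(gt, tol = 1e-12, max_iter = 5000)
    oracle <- hap2_grid_mle(codes)  # order: (0,0),(0,1),(1,0),(1,1)
    em_f <- setNames(hs$haplotypes$freq, hs$haplotypes$label)
    full <- setNames(rep(0, 4), c("A-A", "A-B", "B-A", "B-B"))
    full[names(em_f)] <- em_f
    expect_lt(max(abs(unname(full) - oracle)), 1e-4)
  }
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  codes <- sim_hap2(80, c(0.4, 0.3, 0.2, 0.1), 77)
  hs <- em_haplotype_frequencies(genotype_table(codes, toy_panel(2)))
  expect_true(all(diff(hs$loglik_trace) >= -1e-9))
})

test_that("frequencies are invariant to sample order and SNP order", {
  codes <- sim_hap2(60, c(0.45, 0.25, 0.2, 0.1), 13)
  gt <- genotype_table(codes, toy_panel(2))
  hs1 <- em_haplotype_frequencies(gt)
  perm <- withr::with_seed(1, sample(60))
  gt2 <- genotype_table(codes[perm, ], toy_panel(2),
                        samples = paste0("S", perm))
  hs2 <- em_haplotype_frequencies(gt2)
  expect_equal(hs1$haplotypes, hs2$haplotypes, tolerance = 1e-9)
  # swapping SNP columns relabels haplotypes but keeps the frequency set
  codes_swapped <- codes[, 2:1]
  colnames(codes_swapped) <- NULL  # defeat the by-name column realignment
  gt3 <- genotype_table(codes_swapped, toy_panel(2))
  hs3 <- em_haplotype_frequencies(gt3)
  relabel <- vapply(strsplit(hs3$haplotypes$label, "-"), function(a)
    paste(rev(a), collapse = "-"), "")
  f3 <- setNames(hs3$haplotypes$freq, relabel)
  f1 <- setNames(hs1$haplotypes$freq, hs1$haplotypes$label)
  expect_equal(f3[names(f1)], f1, tolerance = 1e-9)
})

test_that("listwise deletion drops individuals missing any panel SNP", {
  codes <- rbind(c(1L, 2L), c(NA, 2L), c(3L, 3L))
  hs <- em_haplotype_frequencies(genotype_table(codes, toy_panel(2)))
  expect_equal(length(hs$samples), 2)
})

test_that("haplotype GLM reduces to the log-additive single-locus fit", {
  withr::with_seed(404, {
    n <- 300
    g <- simulate_genotypes(n, 0.3)
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * (g - 1)))
    gt <- genotype_table(matrix(g, ncol = 1), toy_panel(1),
                         samples = sprintf("s%03d", 1:n))
    pt <- phenotype_table(data.frame(sample = sprintf("s%03d", 1:n),
                                     status = y))
    cc <- join_cohort(gt, pt)
    hg <- haplo_glm(cc, rare_threshold = 0)
    la <- logistic_association(cc, "snp1", model = "log_additive")
    expect_equal(hg$estimates$or, la$or, tolerance = 1e-6)
    expect_equal(hg$estimates$coef, log(la$or), tolerance = 1e-6)
  })
})

test_that("zero-ambiguity cohorts reproduce the known-dose logistic fit", {
  withr::with_seed(505, {
    n <- 200
    # individuals heterozygous at no more than one SNP: phase is known
    g1 <- simulate_genotypes(n, 0.4)
    g2 <- ifelse(g1 == 2, sample(c(1L, 3L), n, TRUE), simulate_genotypes(n, 0.3))
    codes <- cbind(g1, g2)
    colnames(codes) <- c("snp1", "snp2")
    y <- rbinom(n, 1, plogis(-0.3 + 0.5 * (g1 == 3)))
    gt <- genotype_table(codes, toy_panel(2), samples = sprintf("s%03d", 1:n))
    cc <- join_cohort(gt, phenotype_table(
      data.frame(sample = sprintf("s%03d", 1:n), status = y)))
    hs <- em_haplotype_frequencies(cc$genotypes)
    expect_true(all(vapply(hs$posteriors, nrow, 1L) == 1))
    hg <- haplo_glm(cc, rare_threshold = 0, hs = hs)
    # oracle: ordinary logistic on the true haplotype dose columns
    doses <- sapply(sort(setdiff(hs$haplotypes$label,
                                 hg$reference)), function(h) {
      al <- strsplit(h, "-")[[1]]
      # count copies per SNP: minor copies = code-1; major copies = 3-code
      c1 <- if (al[1] == "B") codes[, 1] - 1 else 3 - codes[, 1]
      c2 <- if (al[2] == "B") codes[, 2] - 1 else 3 - codes[, 2]
      pmin(c1, c2)
    })
    fit <- glm(y ~ doses, family = binomial())
    expect_equal(unname(hg$estimates$coef),
                 unname(coef(fit)[-1]), tolerance = 1e-6)
  })
})

test_that("planted haplotype effect is recovered within 15%", {
  true_f <- c("A-A" = 0.45, "A-B" = 0.15, "B-A" = 0.25, "B-B" = 0.15)
  target <- "B-B"; or_true <- 2
  ors <- vapply(1:8, function(seed) {
    withr::with_seed(7000 + seed, {
      n <- 1500
      # retrospective draw: controls from f, cases tilted by target dose
      draw <- function(m, tilt) {
        pair_w <- outer(true_f, true_f)
        dose <- outer(names(true_f) == target, names(true_f) == target, "+")
        w <- pair_w * or_true^(dose * tilt)
        idx <- sample.int(16, m, TRUE, prob = as.numeric(w / sum(w)))
        cbind((idx - 1) %% 4 + 1, (idx - 1) %/% 4 + 1)
      }
      hp <- rbind(draw(n / 2, 0), draw(n / 2, 1))
      bit <- function(h, k) (h - 1) %/% c(2, 1)[k] %% 2
      codes <- cbind(1L + bit(hp[, 1], 1) + bit(hp[, 2], 1),
                     1L + bit(hp[, 1], 2) + bit(hp[, 2], 2))
      colnames(codes) <- c("snp1", "snp2")
      gt <- genotype_table(codes, toy_panel(2),
                           samples = sprintf("s%04d", 1:n))
      cc <- join_cohort(gt, phenotype_table(
        data.frame(sample = sprintf("s%04d", 1:n),
                   status = rep(0:1, each = n / 2))))
      hg <- haplo_glm(cc, rare_threshold = 0.01)
      hg$estimates$or[hg$estimates$haplotype == target]
    })
  }, 0)
  expect_within(median(ors), or_true * 0.85, or_true * 1.15)
})
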