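#' Hardy-Weinberg equilibrium test
#'
#' Exact test by full enumeration of the heterozygote count conditional on
#' the observed allele counts: the two-sided p-value sums the conditional
#' probabilities of all tables no more probable than the observed one
#' (the standard exact HWE construction). A 1-df Pearson chi-square p-value
#' against the HWE expectations is reported alongside.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts,
#'   major homozygote first.
#' @return A list of class `hwe_result`: `counts`, `maf`, `p_exact`,
#'   `p_chisq`. A monomorphic locus returns `p = 1` for both tests.
#' @examples
#' hwe_test(c(104, 50, 6))   # p_exact ~ 1.00
#' hwe_test(c(128, 28, 4))   # p_exact ~ 0.115
#' @export
hwe_test <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0))
    stop("counts must be three non-negative integers (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n == 0) stop("total count must be positive")
  n_minor <- 2L * counts[3] + counts[2]
  n_major <- 2L * counts[1] + counts[2]
  maf <- n_minor / (2 * n)
  if (n_minor == 0 || n_major == 0) {
    out <- list(counts = counts, maf = maf, p_exact = 1, p_chisq = 1)
    class(out) <- "hwe_result"
    return(out)
  }
  rare <- min(n_minor, n_major)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log conditional probability of each heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2L * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(counts[2], hets)]
  p_exact <- min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))

  p <- n_major / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((counts - expected)^2 / expected)
  p_chisq <- pchisq(x2, df = 1, lower.tail = FALSE)

  out <- list(counts = counts, maf = maf, p_exact = p_exact,
              p_chisq = p_chisq)
  class(out) <- "hwe_result"
  out
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("HWE test: counts", paste(x$counts, collapse = "/"),
      sprintf(" MAF %.3f  exact p %.4g  chi-square p %.4g\n",
              x$maf, x$p_exact, x$p_chisq))
  invisible(x)
}

#' HWE tests for every SNP of a cohort stratum
#'
#' @param cohort A [join_cohort()] result.
#' @param group `"cases"`, `"controls"` or `"all"`.
#' @return A tibble with one row per SNP: genotype counts, MAF and both
#'   p-values.
#' @export
hwe_scan <- function(cohort, group = c("cases", "controls", "all")) {
  group <- match.arg(group)
  st <- cohort$phenotypes$status
  keep <- switch(group, cases = st == 1, controls = st == 0,
                 all = rep(TRUE, length(st)))
  rows <- lapply(seq_len(nrow(cohort$genotypes$snps)), function(j) {
    g <- cohort$genotypes$codes[keep, j]
    cnt <- as.integer(table(factor(g, levels = 1:3)))
    h <- hwe_test(cnt)
    tibble::tibble(snp = cohort$genotypes$snps$id[j],
                   n_hom_major = cnt[1], n_het = cnt[2], n_hom_minor = cnt[3],
                   maf = h$maf, p_exact = h$p_exact, p_chisq = h$p_chisq)
  })
  dplyr::bind_rows(rows)
}
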