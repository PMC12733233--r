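#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Expectation-maximisation over the unobserved phase assignments of a
#' multi-SNP panel. The E-step assigns each individual's compatible ordered
#' haplotype pairs posterior weights proportional to `f_a * f_b` (doubled
#' for heterogeneous pairs); the M-step re-estimates frequencies from the
#' expected haplotype counts. The log-likelihood is non-decreasing across
#' iterations (asserted) and iteration stops when the gain falls below
#' `tol`. Individuals missing any panel genotype are dropped listwise.
#'
#' Haplotypes are labelled by their allele symbols in panel order (e.g.
#' `"D-C-A"`) and kept in lexicographic label order; initialisation is
#' uniform over the haplotypes compatible with the sample, so the result is
#' deterministic (no random restarts by default).
#'
#' @param gt A [genotype_table()] (or a cohort, whose genotypes are used).
#' @param tol Convergence threshold on the log-likelihood gain.
#' @param max_iter Maximum EM iterations; non-convergence returns the best
#'   iterate flagged with `converged = FALSE`.
#' @return An object of class `haplotype_set`: `haplotypes` (tibble `label`,
#'   `freq`), `posteriors` (per kept individual, tibble `h1`, `h2`, `prob`
#'   over unordered compatible pairs), `loglik`, `loglik_trace`,
#'   `converged`, `n_iter`, `samples`.
#' @export
em_haplotype_frequencies <- function(gt, tol = 1e-8, max_iter = 1000) {
  if (inherits(gt, "cohort")) gt <- gt$genotypes
  stopifnot(inherits(gt, "genotype_table"))
  L <- nrow(gt$snps)
  if (L < 1) stop("need at least one SNP")
  keep <- complete.cases(gt$codes)
  codes <- gt$codes[keep, , drop = FALSE]
  n <- nrow(codes)
  if (n == 0) stop("no complete-case individuals")

  hap_label <- function(mask) {
    alleles <- ifelse(bitwAnd(mask, 2^(seq_len(L) - 1)) > 0,
                      gt$snps$minor_allele, gt$snps$major_allele)
    paste(alleles, collapse = "-")
  }

  # unordered compatible haplotype pairs (as bitmasks) per individual
  pairs_of <- function(g) {
    base <- sum(2^(which(g == 3) - 1))
    hets <- which(g == 2)
    h <- length(hets)
    if (h == 0) return(matrix(c(base, base), ncol = 2))
    first <- hets[1]
    rest <- hets[-1]
    subsets <- list(integer(0))
    for (r in rest)
      subsets <- c(subsets, lapply(subsets, function(s) c(s, r)))
    t(vapply(subsets, function(s) {
      h1 <- base + 2^(first - 1) + sum(2^(s - 1))
      h2 <- base + sum(2^(setdiff(rest, s) - 1))
      c(h1, h2)
    }, numeric(2)))
  }
  pair_list <- lapply(seq_len(n), function(i) pairs_of(codes[i, ]))

  masks <- sort(unique(unlist(pair_list)))
  labels <- vapply(masks, hap_label, "")
  ord <- order(labels)
  masks <- masks[ord]; labels <- labels[ord]
  K <- length(masks)
  idx_of <- setNames(seq_len(K), masks)
  pair_idx <- lapply(pair_list, function(m)
    cbind(idx_of[as.character(m[, 1])], idx_of[as.character(m[, 2])]))

  f <- rep(1 / K, K)
  loglik_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(max_iter)) {
    expected <- numeric(K)
    ll <- 0
    post <- vector("list", n)
    for (i in seq_len(n)) {
      pi <- pair_idx[[i]]
      w <- f[pi[, 1]] * f[pi[, 2]] * ifelse(pi[, 1] == pi[, 2], 1, 2)
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / nrow(pi), nrow(pi)); tot <- 1e-300 }
      ll <- ll + log(tot)
      w <- w / sum(w)
      post[[i]] <- w
      for (k in seq_len(nrow(pi))) {
        expected[pi[k, 1]] <- expected[pi[k, 1]] + w[k]
        expected[pi[k, 2]] <- expected[pi[k, 2]] + w[k]
      }
    }
    if (length(loglik_trace) && ll < loglik_trace[length(loglik_trace)] - 1e-9)
      stop("EM log-likelihood decreased; this is a bug")
    gain <- if (length(loglik_trace))
      ll - loglik_trace[length(loglik_trace)] else Inf
    loglik_trace <- c(loglik_trace, ll)
    f_new <- expected / (2 * n)
    if (gain < tol) { converged <- TRUE; break }
    f <- f_new
  }
  posteriors <- lapply(seq_len(n), function(i) {
    pi <- pair_idx[[i]]
    tibble::tibble(h1 = labels[pi[, 1]], h2 = labels[pi[, 2]],
                   prob = post[[i]])
  })
  structure(list(
    haplotypes = tibble::tibble(label = labels, freq = f),
    posteriors = posteriors,
    loglik = loglik_trace[length(loglik_trace)],
    loglik_trace = loglik_trace,
    converged = converged, n_iter = length(loglik_trace),
    samples = gt$samples[keep], snps = gt$snps),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$haplotypes), " haplotypes over ",
      nrow(x$snps), " SNPs, ", length(x$samples), " individuals\n",
      "log-likelihood ", sprintf("%.4f", x$loglik),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  print(as.data.frame(x$haplotypes), digits = 4)
  invisible(x)
}

#' Haplotype-outcome GLM with phase-uncertainty weighting
#'
#' Logistic regression of a binary outcome on additive haplotype doses under
#' phase ambiguity: each individual's design rows are expanded over their
#' compatible haplotype pairs, weighted by the phase posteriors, and the
#' weighted fit and posterior update are iterated to convergence (weights
#' are updated with each pair's likelihood under the current outcome
#' model). The most frequent haplotype is the reference; haplotypes rarer
#' than `rare_threshold` are pooled into a `"rare"` term.
#'
#' @param cohort A [join_cohort()] result.
#' @param outcome `"status"` or a sub-phenotype name.
#' @param covariates Phenotype columns to adjust for.
#' @param rare_threshold Pooling threshold on the EM frequency.
#' @param hs Optionally a precomputed [em_haplotype_frequencies()] result.
#' @param tol,max_iter Convergence control for the fit/reweight iteration.
#' @param level Confidence level for Wald intervals.
#' @return An object of class `haplo_glm_result`: tibble `estimates`
#'   (`haplotype`, `freq`, `coef`, `or`, `ci_low`, `ci_high`, `p`),
#'   `reference`, `converged`.
#' @export
haplo_glm <- function(cohort, outcome = "status", covariates = character(),
                      rare_threshold = 0.01, hs = NULL, tol = 1e-8,
                      max_iter = 100, level = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(hs)) hs <- em_haplotype_frequencies(cohort$genotypes)
  y_all <- cohort_outcome(cohort, outcome)
  names(y_all) <- cohort$genotypes$samples
  y <- y_all[hs$samples]
  keep <- !is.na(y)
  if (length(unique(y[keep])) < 2) stop("outcome does not have both levels")

  freqs <- hs$haplotypes
  ref <- freqs$label[which.max(freqs$freq)]
  pooled <- freqs$label[freqs$freq < rare_threshold & freqs$label != ref]
  term_of <- function(h) ifelse(h %in% pooled, "rare", h)
  terms <- setdiff(unique(term_of(freqs$label)), ref)
  if (length(terms) == 0) stop("all individuals carry only the reference haplotype")

  # expanded rows over compatible pairs
  rows <- list()
  for (i in seq_along(hs$samples)) {
    if (!keep[i]) next
    po <- hs$posteriors[[i]]
    dose <- matrix(0, nrow = nrow(po), ncol = length(terms),
                   dimnames = list(NULL, terms))
    for (k in seq_len(nrow(po))) {
      for (h in c(po$h1[k], po$h2[k])) {
        tm <- term_of(h)
        if (tm != ref && tm %in% terms)
          dose[k, tm] <- dose[k, tm] + 1
      }
    }
    rows[[length(rows) + 1]] <-
      list(id = i, y = unname(y[i]), prior = po$prob, dose = dose)
  }
  id <- unlist(lapply(rows, function(r) rep(r$id, length(r$prior))))
  yy <- unlist(lapply(rows, function(r) rep(r$y, length(r$prior))))
  prior <- unlist(lapply(rows, function(r) r$prior))
  D <- do.call(rbind, lapply(rows, function(r) r$dose))
  df <- as.data.frame(D)
  names(df) <- make.names(terms)
  df$y <- yy
  for (cv in covariates) {
    v <- cohort$phenotypes[[cv]][match(hs$samples, cohort$phenotypes$sample)]
    df[[cv]] <- unlist(lapply(rows, function(r) rep(v[r$id], length(r$prior))))
  }
  rhs <- paste(c(make.names(terms), covariates), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))

  w <- prior
  fit <- NULL
  converged <- FALSE
  old_coef <- NULL
  for (it in seq_len(max_iter)) {
    fit <- suppressWarnings(glm(form, family = binomial(), data = df,
                                weights = w))
    p_hat <- fit$fitted.values
    lik <- ifelse(df$y == 1, p_hat, 1 - p_hat)
    w_new <- prior * lik
    w_new <- w_new / stats::ave(w_new, id, FUN = sum)
    w <- w_new
    if (!is.null(old_coef) &&
        max(abs(coef(fit) - old_coef), na.rm = TRUE) < tol) {
      converged <- TRUE
      break
    }
    old_coef <- coef(fit)
  }
  z <- qnorm(1 - (1 - level) / 2)
  est <- lapply(seq_along(terms), function(k) {
    nm <- make.names(terms)[k]
    b <- coef(fit)[[nm]]
    se <- sqrt(vcov(fit)[nm, nm])
    fr <- if (terms[k] == "rare") sum(freqs$freq[freqs$label %in% pooled])
          else freqs$freq[freqs$label == terms[k]]
    tibble::tibble(haplotype = terms[k], freq = fr, coef = b, or = exp(b),
                   ci_low = exp(b - z * se), ci_high = exp(b + z * se),
                   p = 2 * stats::pnorm(-abs(b / se)))
  })
  structure(list(estimates = dplyr::bind_rows(est), reference = ref,
                 ref_freq = freqs$freq[freqs$label == ref],
                 converged = converged, outcome = outcome),
            class = "haplo_glm_result")
}

#' @export
print.haplo_glm_result <- function(x, ...) {
  cat("<haplo_glm_result> outcome ", x$outcome, "; reference haplotype ",
      x$reference, sprintf(" (freq %.3f)\n", x$ref_freq), sep = "")
  print(as.data.frame(x$estimates), digits = 3)
  invisible(x)
}
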