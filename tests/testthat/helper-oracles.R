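# independent oracles shared by the unit and acceptance suites

# conditional distribution of the heterozygote count given allele counts via
# the ratio recurrence (a different route than the log-factorial enumeration
# used by the implementation)
hwe_exact_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n_minor <- 2 * naa + nAa
  n_major <- 2 * nAA + nAa
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    # P(h+2)/P(h) = 4 * hom_r * hom_c / ((h+2)(h+1))
    probs[k] <- probs[k - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(nAa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# multinomial log-likelihood of 2-SNP genotype patterns under haplotype
# frequencies (f_AB, f_Ab, f_aB, f_ab); haplotypes 1=00, 2=01, 3=10, 4=11
hap2_loglik <- function(f, pattern_counts) {
  pair_prob <- function(h1, h2) if (h1 == h2) f[h1]^2 else 2 * f[h1] * f[h2]
  opts <- list(`1` = list(c(0, 0)), `2` = list(c(0, 1), c(1, 0)),
               `3` = list(c(1, 1)))
  ll <- 0
  for (key in names(pattern_counts)) {
    g <- as.integer(strsplit(key, "")[[1]])
    p <- 0
    seen <- character(0)
    for (c1 in opts[[as.character(g[1])]])
      for (c2 in opts[[as.character(g[2])]]) {
        h1 <- 1 + 2 * c1[1] + c2[1]
        h2 <- 1 + 2 * c1[2] + c2[2]
        id <- paste(sort(c(h1, h2)), collapse = "-")
        if (id %in% seen) next
        seen <- c(seen, id)
        p <- p + pair_prob(h1, h2)
      }
    ll <- ll + pattern_counts[[key]] * log(p)
  }
  ll
}

# brute-force likelihood maximiser by nested grid refinement
hap2_grid_mle <- function(codes) {
  key <- paste0(codes[, 1], codes[, 2])
  pattern_counts <- as.list(table(key))
  best <- rep(0.25, 4)
  width <- 0.25
  for (level in 1:5) {
    grid <- seq(-width, width, length.out = 11)
    cands <- expand.grid(d1 = grid, d2 = grid, d3 = grid)
    best_ll <- -Inf
    best_new <- best
    for (i in seq_len(nrow(cands))) {
      f123 <- best[1:3] + as.numeric(cands[i, ])
      f4 <- 1 - sum(f123)
      f <- c(f123, f4)
      if (any(f < 0)) next
      ll <- hap2_loglik(pmax(f, 1e-12), pattern_counts)
      if (ll > best_ll) { best_ll <- ll; best_new <- f }
    }
    best <- best_new
    width <- width / 5
  }
  best
}

# unphased 2-SNP genotypes drawn from known haplotype frequencies
sim_hap2 <- function(n, freqs, seed) {
  withr::with_seed(seed, {
    h1 <- sample.int(4, n, replace = TRUE, prob = freqs)
    h2 <- sample.int(4, n, replace = TRUE, prob = freqs)
    bit <- function(h, k) (h - 1) %/% c(2, 1)[k] %% 2
    codes <- cbind(1L + bit(h1, 1) + bit(h2, 1), 1L + bit(h1, 2) + bit(h2, 2))
    colnames(codes) <- c("snp1", "snp2")
    codes
  })
}

# logic-tree oracles
eval_tree_oracle <- function(tree, X) {
  expr <- parse(text = mmpassoc:::deparse_tree(tree))
  env <- as.data.frame(X == 1)
  as.logical(eval(expr[[1]], envir = env))
}

random_tree <- function(vars, n_leaves) {
  leaf <- function() lt_leaf(sample(vars, 1), neg = runif(1) < 0.5)
  tree <- leaf()
  for (i in seq_len(n_leaves - 1)) {
    tree <- if (runif(1) < 0.5) lt_and(tree, leaf()) else lt_or(tree, leaf())
  }
  tree
}
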