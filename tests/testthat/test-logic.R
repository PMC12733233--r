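test_that("dummy encoding maps codes per the study convention", {
  codes <- matrix(c(1L, 2L, 3L), ncol = 1, dimnames = list(NULL, "rs1"))
  B <- binarize(codes)
  expect_equal(matrix(as.integer(B), ncol = 2),
               matrix(c(0L, 1L, 1L, 0L, 0L, 1L), ncol = 2))
  expect_equal(colnames(B), c("rs1_1", "rs1_2"))
})

test_that("binarize/decode is a bijection over all 27 joint genotypes", {
  combos <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  colnames(combos) <- paste0("s", 1:3)
  storage.mode(combos) <- "integer"
  B <- binarize(combos)
  expect_equal(ncol(B), 6)
  expect_equal(nrow(unique(B)), 27)  # all joint codes map to distinct rows
  expect_equal(unname(decode_binarized(B)), unname(combos))
})

test_that("rows with missing genotypes are dropped with a record", {
  codes <- rbind(c(1L, 2L), c(NA, 3L), c(2L, 2L))
  colnames(codes) <- c("a", "b")
  B <- binarize(codes)
  expect_equal(nrow(B), 2)
  expect_equal(attr(B, "dropped"), 2L)
})

test_that("tree evaluation matches hand-computed and oracle truth tables", {
  t1 <- lt_and(lt_leaf("X1"), lt_leaf("X2", neg = TRUE))
  expect_true(evaluate_tree(t1, matrix(c(1, 0), 1, dimnames = list(NULL,
              c("X1", "X2")))))
  expect_false(evaluate_tree(t1, matrix(c(1, 1), 1, dimnames = list(NULL,
               c("X1", "X2")))))
  single <- lt_leaf("X1")
  X <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "X1"))
  expect_equal(evaluate_tree(single, X), c(FALSE, TRUE))
  expect_error(evaluate_tree(lt_leaf("nope"), X), "unknown variable")

  vars <- paste0("V", 1:6)
  grid <- as.matrix(expand.grid(rep(list(0:1), 6)))
  colnames(grid) <- vars
  withr::with_seed(17, {
    for (i in 1:20) {
      tr <- random_tree(vars, sample(2:4, 1))
      expect_equal(evaluate_tree(tr, grid), eval_tree_oracle(tr, grid))
    }
  })
})

test_that("prime implicants are equivalent to and minimal for the tree", {
  vars <- paste0("V", 1:4)
  grid <- as.matrix(expand.grid(rep(list(0:1), 4)))
  colnames(grid) <- vars
  withr::with_seed(23, {
    for (i in 1:15) {
      tr <- random_tree(vars, sample(2:4, 1))
      val <- evaluate_tree(tr, grid)
      imps <- extract_interactions(tr)
      if (all(val) || !any(val)) {
        expect_equal(length(imps), 0)
        next
      }
      # disjunction of implicants == tree on every input
      expect_equal(mmpassoc:::eval_implicants(imps, grid), val)
      for (imp in imps) {
        # implicant implies the function
        sat <- mmpassoc:::eval_implicants(list(imp), grid)
        expect_true(all(val[sat]))
        # primality: dropping any literal breaks implication
        for (v in names(imp)) {
          red <- imp[setdiff(names(imp), v)]
          if (length(red) == 0) {
            expect_false(all(val))
          } else {
            attr(red, "label") <- "tmp"
            sat_red <- mmpassoc:::eval_implicants(list(red), grid)
            expect_false(all(val[sat_red]))
          }
        }
      }
    }
  })
})

test_that("annealing is bit-for-bit reproducible under a fixed seed", {
  withr::with_seed(31, {
    X <- matrix(rbinom(600, 1, 0.5), 100, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    y <- rbinom(100, 1, 0.5)
  })
  f1 <- anneal_fit(X, y, max_leaves = 6, control = test_logic_control(),
                   seed = 42)
  f2 <- anneal_fit(X, y, max_leaves = 6, control = test_logic_control(),
                   seed = 42)
  expect_identical(f1$tree, f2$tree)
  expect_identical(f1$score, f2$score)
})

test_that("a planted OR rule is recovered despite 5% label noise", {
  withr::with_seed(37, {
    n <- 300
    X <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    rule <- X[, 1] == 1 | X[, 3] == 1
    y <- ifelse(runif(n) < 0.05, 1 - rule, rule)
    fit <- anneal_fit(X, as.integer(y), max_leaves = 6,
                      control = test_logic_control(), seed = 8)
    agree <- mean(predict(fit, X) == as.integer(rule))
    expect_gte(agree, 0.95)
  })
})

test_that("annealed score matches exhaustive search over <= 2-leaf trees", {
  exhaustive_best <- function(X, y) {
    p <- ncol(X)
    leaves <- expand.grid(var = seq_len(p), neg = c(FALSE, TRUE))
    score_of <- function(v) {
      a <- sum(v & y == 1); b <- sum(v & y == 0)
      c_ <- sum(!v & y == 1); d <- sum(!v & y == 0)
      min(a, b) + min(c_, d)
    }
    best <- Inf
    cols <- lapply(seq_len(nrow(leaves)), function(i) {
      v <- X[, leaves$var[i]] == 1
      if (leaves$neg[i]) !v else v
    })
    for (i in seq_along(cols)) {
      best <- min(best, score_of(cols[[i]]))
      for (j in seq_along(cols)) {
        best <- min(best, score_of(cols[[i]] & cols[[j]]),
                    score_of(cols[[i]] | cols[[j]]))
      }
    }
    best
  }
  withr::with_seed(53, {
    for (rep in 1:5) {
      X <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3,
                  dimnames = list(NULL, paste0("V", 1:3)))
      y <- rbinom(8, 1, 0.5)
      if (length(unique(y)) < 2) next
      fit <- anneal_fit(X, y, max_leaves = 2,
                        control = logic_control(moves_per_temp = 50,
                                                cool = 0.9,
                                                max_moves = 4000,
                                                stop_no_improve = 3000,
                                                leaf_penalty = 0),
                        seed = rep)
      expect_equal(fit$score, exhaustive_best(X, y))
    }
  })
})

test_that("pure-noise outcomes stay near the baseline error", {
  withr::with_seed(59, {
    n <- 200
    X <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    y <- rbinom(n, 1, 0.5)
    fit <- anneal_fit(X, y, max_leaves = 6, control = test_logic_control(),
                      seed = 5)
    baseline <- min(sum(y), n - sum(y)) / n
    expect_gte(fit$misclass, baseline - 0.15)
  })
})

test_that("bagged importance ranks a planted single-variable effect first", {
  withr::with_seed(61, {
    n <- 250
    X <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    y <- rbinom(n, 1, plogis(-1 + 2.2 * X[, 2]))
    res <- logic_fs(X, y, n_bootstrap = 30, max_leaves = 4,
                    control = test_logic_control(), seed = 9)
    expect_equal(res$interaction[1], "V2")
    expect_equal(res$interaction[which.max(res$importance)], "V2")
    expect_true(all(res$prop >= 0 & res$prop <= 1))
  })
})

test_that("label-permuted data yield no dominant interaction", {
  withr::with_seed(67, {
    n <- 250
    X <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    y <- sample(rep(0:1, c(110, 140)))
    res <- logic_fs(X, y, n_bootstrap = 30, max_leaves = 4,
                    control = test_logic_control(), seed = 10)
    expect_true(nrow(res) == 0 || max(res$prop) < 0.6)
  })
})

test_that("interaction frequency table uses Fisher's exact test", {
  counts <- matrix(c(10L, 10L, 10L, 10L), 2)
  codes <- cbind(rep(c(1L, 3L), each = 20))
  colnames(codes) <- "snp1"
  gt <- genotype_table(codes, toy_panel(1), samples = sprintf("s%d", 1:40))
  cc <- join_cohort(gt, phenotype_table(
    data.frame(sample = sprintf("s%d", 1:40), status = rep(0:1, 20))))
  out <- interaction_frequency_table(cc, "snp1_2")
  expect_equal(out$p_fisher, 1)
  expect_equal(sum(out$table), 40)
  expect_equal(unname(colSums(out$table)), c(20, 20))

  # Fisher p equals hypergeometric enumeration on random tables
  withr::with_seed(71, {
    for (i in 1:10) {
      t <- matrix(rpois(4, 6), 2)
      if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
      p_enum <- local({
        m <- sum(t[1, ]); n2 <- sum(t[2, ]); k <- sum(t[, 1])
        xs <- max(0, k - n2):min(k, m)
        probs <- dhyper(xs, m, n2, k)
        sum(probs[probs <= dhyper(t[1, 1], m, n2, k) * (1 + 1e-7)])
      })
      expect_equal(fisher.test(t)$p.value, p_enum, tolerance = 1e-9)
    }
  })
})

test_that("degenerate interaction margins warn and report p = 1", {
  codes <- cbind(rep(1L, 10))
  colnames(codes) <- "snp1"
  gt <- genotype_table(codes, toy_panel(1), samples = sprintf("s%d", 1:10))
  cc <- join_cohort(gt, phenotype_table(
    data.frame(sample = sprintf("s%d", 1:10), status = rep(0:1, 5))))
  expect_warning(out <- interaction_frequency_table(cc, "snp1_1"),
                 "degenerate")
  expect_equal(out$p_fisher, 1)
})
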