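#' Annealing schedule and search-size settings for logic regression
#'
#' The search is a Metropolis simulated annealing over tree moves (relabel
#' leaf, complement leaf, flip operator, grow leaf, prune subtree) with
#' geometric cooling. `t_start = NULL` picks the start temperature
#' automatically so that roughly 90% of the uphill moves observed on a short
#' probe walk would be accepted.
#'
#' @param t_start Start temperature (score units, i.e. misclassified
#'   counts); `NULL` = automatic.
#' @param cool Geometric cooling factor per temperature step.
#' @param moves_per_temp Proposals evaluated at each temperature.
#' @param max_moves Total proposal budget.
#' @param stop_no_improve Stop after this many proposals without improving
#'   the best score.
#' @param t_min Temperature floor.
#' @param leaf_penalty Complexity penalty added to the misclassification
#'   score per leaf beyond the first (in misclassified-count units). Tree
#'   size is not selected by cross-validation here, so a small positive
#'   penalty keeps the search from absorbing bootstrap noise into extra
#'   leaves; set to 0 for the unpenalised search.
#' @return A list of class `logic_control`.
#' @export
logic_control <- function(t_start = NULL, cool = 0.99, moves_per_temp = 1000,
                          max_moves = 100000, stop_no_improve = 25000,
                          t_min = 1e-3, leaf_penalty = 2) {
  stopifnot(cool > 0, cool < 1, moves_per_temp >= 1, max_moves >= 1,
            stop_no_improve >= 1, leaf_penalty >= 0)
  structure(list(t_start = if (is.null(t_start)) -1 else t_start,
                 cool = cool, moves_per_temp = moves_per_temp,
                 max_moves = max_moves, stop_no_improve = stop_no_improve,
                 t_min = t_min, leaf_penalty = leaf_penalty),
            class = "logic_control")
}

#' Fit one logic tree by simulated annealing
#'
#' Searches Boolean trees over the binary predictors (up to `max_leaves`
#' leaves) minimising the training misclassification when each of the two
#' tree-value groups predicts its majority class. The search is bit-for-bit
#' reproducible for a fixed `seed` and control settings.
#'
#' @param X Binary 0/1 design matrix (e.g. from [binarize()]).
#' @param y Binary outcome with both levels present.
#' @param max_leaves Maximum leaves per tree (study default 10).
#' @param control A [logic_control()].
#' @param seed Integer seed for the search's own RNG.
#' @return An object of class `logic_fit`: `tree`, `score` (misclassified
#'   count), `misclass` (rate), `pred_true`/`pred_false` (class predicted in
#'   the tree-TRUE / tree-FALSE group), `n`.
#' @export
anneal_fit <- function(X, y, max_leaves = 10, control = logic_control(),
                       seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("outcome is constant")
  res <- .anneal_cpp(X, y, as.integer(max_leaves), control$t_start,
                     control$cool, as.integer(control$moves_per_temp),
                     as.integer(control$max_moves),
                     as.integer(control$stop_no_improve), control$t_min,
                     control$leaf_penalty, as.integer(seed))
  tree <- tree_from_nodes(res$nodes, res$root, colnames(X))
  v <- evaluate_tree(tree, X)
  maj <- as.integer(mean(y) >= 0.5)
  pred_true <- if (any(v)) as.integer(mean(y[v]) >= 0.5) else maj
  pred_false <- if (any(!v)) as.integer(mean(y[!v]) >= 0.5) else maj
  structure(list(tree = tree, score = res$score,
                 misclass = res$score / length(y),
                 pred_true = pred_true, pred_false = pred_false,
                 n = length(y), n_moves = res$n_moves),
            class = "logic_fit")
}

#' @export
print.logic_fit <- function(x, ...) {
  cat("<logic_fit> ", deparse_tree(x$tree), "\n  training misclassification ",
      sprintf("%.3f (%d/%d)\n", x$misclass, x$score, x$n), sep = "")
  invisible(x)
}

#' @export
predict.logic_fit <- function(object, newdata, ...) {
  v <- evaluate_tree(object$tree, newdata)
  ifelse(v, object$pred_true, object$pred_false)
}

# prediction from a DNF implicant set with the fitted orientation
predict_dnf <- function(implicants, X, pred_true, pred_false) {
  v <- eval_implicants(implicants, X)
  ifelse(v, pred_true, pred_false)
}

#' Bagged logic regression with interaction importances
#'
#' Fits one logic tree per bootstrap sample, decomposes each fitted tree
#' into its prime-implicant interactions, and reports per interaction:
#' * `prop` — the fraction of bootstrap models whose tree contains the
#'   interaction;
#' * `importance` — the mean drop in out-of-bag (OOB) classification
#'   accuracy when the interaction is removed from the models that contain
#'   it.
#'
#' @inheritParams anneal_fit
#' @param n_bootstrap Number of bootstrap replicates (study default 100).
#' @param seed Seed for the bootstrap/search stream; `NULL` continues the
#'   caller's RNG stream.
#' @return A tibble sorted by decreasing `prop`: `interaction`, `prop`,
#'   `importance`, `n_models`.
#' @export
logic_fs <- function(X, y, n_bootstrap = 100, max_leaves = 10,
                     control = logic_control(), seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (length(unique(y)) < 2) stop("outcome is constant")
  with_seed_(seed, {
    stats_env <- new.env(parent = emptyenv())
    assign("count", list(), envir = stats_env)
    assign("imp", list(), envir = stats_env)
    failures <- 0L
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      fit_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      res <- tryCatch({
        fit <- anneal_fit(X[idx, , drop = FALSE], y[idx],
                          max_leaves = max_leaves, control = control,
                          seed = fit_seed)
        # canonical orientation: implicants describe the class-1 (risk)
        # region, complementing the tree when its TRUE group predicts 0
        imps <- if (fit$pred_true == fit$pred_false) list() else
          extract_interactions(fit$tree, complement = fit$pred_true == 0)
        if (length(imps) && length(oob)) {
          Xo <- X[oob, , drop = FALSE]
          yo <- y[oob]
          full_correct <- sum(predict_dnf(imps, Xo, 1L, 0L) == yo)
          for (imp in imps) {
            lab <- interaction_label(imp)
            reduced <- imps[vapply(imps, interaction_label, "") != lab]
            red_correct <- sum(predict_dnf(reduced, Xo, 1L, 0L) == yo)
            delta <- (full_correct - red_correct) / length(oob)
            cnt <- get("count", stats_env)
            im <- get("imp", stats_env)
            cnt[[lab]] <- (cnt[[lab]] %||% 0L) + 1L
            im[[lab]] <- c(im[[lab]], delta)
            assign("count", cnt, stats_env)
            assign("imp", im, stats_env)
          }
        }
        TRUE
      }, error = function(e) FALSE)
      if (!isTRUE(res)) failures <- failures + 1L
    }
    if (failures >= 0.8 * n_bootstrap)
      stop("logic_fs: ", failures, "/", n_bootstrap,
           " bootstrap replicates failed")
    cnt <- get("count", stats_env)
    im <- get("imp", stats_env)
    if (length(cnt) == 0)
      return(tibble::tibble(interaction = character(), prop = numeric(),
                            importance = numeric(), n_models = integer()))
    out <- tibble::tibble(
      interaction = names(cnt),
      prop = unlist(cnt) / (n_bootstrap - failures),
      importance = vapply(names(cnt), function(k) mean(im[[k]]), 0),
      n_models = unlist(cnt))
    dplyr::arrange(out, dplyr::desc(.data$prop))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Real-versus-permuted-null importance comparison
#'
#' The inference protocol for multi-locus interactions: the bagged
#' logic-regression analysis is repeated `n_iter` times on the real labels
#' and `n_iter` times on permuted labels (a fresh permutation each
#' iteration, identical settings otherwise). Interactions with mean
#' proportion above `threshold` across the real iterations are kept and
#' ranked by mean OOB importance. The null reference for the k-th ranked
#' real interaction is rank-matched: the k-th largest importance that the
#' same analysis finds in each null iteration. An interaction is flagged
#' when the percentile bootstrap CI of its mean real importance lies
#' entirely above the CI of its rank-matched null mean.
#'
#' Rank matching is what makes the null a fair yardstick: every dataset --
#' including label-permuted ones -- offers *some* chance association that
#' the search will find and assign positive importance, so the best real
#' interactions are compared against the best importances the same
#' analysis extracts from null data, not against the near-zero importance
#' of one pre-named interaction that rarely reappears under permutation.
#' The same-interaction null proportion and mean importance are also
#' reported (`prop_null`, `imp_null_same`).
#'
#' @inheritParams logic_fs
#' @param n_iter Repetitions per arm (study protocol 200; reduce for
#'   exploratory runs).
#' @param threshold Mean-proportion selection threshold (study 0.15).
#' @param ci_resamples Bootstrap resamples for the percentile CI.
#' @param conf CI level.
#' @return An object of class `logic_null_comparison`: a tibble `summary`
#'   (interaction, mean proportions and importances real/null, CI bounds,
#'   `flagged`) plus the protocol settings.
#' @export
null_comparison <- function(X, y, n_iter = 200, n_bootstrap = 100,
                            max_leaves = 10, control = logic_control(),
                            threshold = 0.15, ci_resamples = 2000,
                            conf = 0.95, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  with_seed_(seed, {
    real <- vector("list", n_iter)
    null <- vector("list", n_iter)
    for (i in seq_len(n_iter)) {
      real[[i]] <- logic_fs(X, y, n_bootstrap = n_bootstrap,
                            max_leaves = max_leaves, control = control)
      yperm <- sample(y)  # fresh permutation each null iteration
      null[[i]] <- logic_fs(X, yperm, n_bootstrap = n_bootstrap,
                            max_leaves = max_leaves, control = control)
    }
    empty_summary <- tibble::tibble(
      interaction = character(), rank = integer(), prop_real = numeric(),
      prop_null = numeric(), imp_real = numeric(), imp_null = numeric(),
      imp_null_same = numeric(), real_lo = numeric(), real_hi = numeric(),
      null_lo = numeric(), null_hi = numeric(), flagged = logical())
    labs <- unique(unlist(lapply(real, function(r) r$interaction)))
    if (length(labs) == 0)
      return(structure(list(summary = empty_summary, n_iter = n_iter,
                            threshold = threshold, n_bootstrap = n_bootstrap),
                       class = "logic_null_comparison"))
    get_col <- function(runs, lab, col) {
      vapply(runs, function(r) {
        k <- match(lab, r$interaction)
        if (is.na(k)) 0 else r[[col]][k]
      }, 0)
    }
    boot_ci <- function(v) {
      means <- vapply(seq_len(ci_resamples), function(b)
        mean(v[sample.int(length(v), length(v), replace = TRUE)]), 0)
      stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      names = FALSE)
    }
    sel <- labs[vapply(labs, function(lab)
      mean(get_col(real, lab, "prop")) > threshold, logical(1))]
    if (length(sel) == 0)
      return(structure(list(summary = empty_summary, n_iter = n_iter,
                            threshold = threshold, n_bootstrap = n_bootstrap),
                       class = "logic_null_comparison"))
    imp_means <- vapply(sel, function(lab)
      mean(get_col(real, lab, "importance")), 0)
    sel <- sel[order(imp_means, decreasing = TRUE)]
    # rank-matched null: the k-th largest importance per null iteration
    null_sorted <- lapply(null, function(r)
      sort(r$importance, decreasing = TRUE))
    null_at_rank <- function(k) {
      vapply(null_sorted, function(v) if (length(v) >= k) v[k] else 0, 0)
    }
    rows <- lapply(seq_along(sel), function(k) {
      lab <- sel[k]
      imp_real <- get_col(real, lab, "importance")
      imp_null <- null_at_rank(k)
      ci_r <- boot_ci(imp_real)
      ci_n <- boot_ci(imp_null)
      tibble::tibble(interaction = lab, rank = k,
                     prop_real = mean(get_col(real, lab, "prop")),
                     prop_null = mean(get_col(null, lab, "prop")),
                     imp_real = mean(imp_real), imp_null = mean(imp_null),
                     imp_null_same = mean(get_col(null, lab, "importance")),
                     real_lo = ci_r[1], real_hi = ci_r[2],
                     null_lo = ci_n[1], null_hi = ci_n[2],
                     flagged = ci_r[1] > ci_n[2])
    })
    summary <- dplyr::bind_rows(c(list(empty_summary), rows))
    structure(list(summary = summary, n_iter = n_iter,
                   threshold = threshold, n_bootstrap = n_bootstrap),
              class = "logic_null_comparison")
  })
}

#' @export
print.logic_null_comparison <- function(x, ...) {
  cat("<logic_null_comparison> ", x$n_iter,
      " iterations per arm, selection threshold ", x$threshold, "\n",
      sep = "")
  if (nrow(x$summary) == 0) {
    cat("no interaction exceeded the selection threshold\n")
  } else {
    print(as.data.frame(x$summary), digits = 3)
  }
  invisible(x)
}

#' Carrier frequency table for a Boolean genotype interaction
#'
#' Cross-tabulates carriers of a Boolean combination of dummy-encoded
#' genotypes against a binary outcome and tests the association with
#' Fisher's exact test (two-sided) — the companion frequency analysis of
#' the importance plots.
#'
#' @param cohort A [join_cohort()] result.
#' @param interaction Either a character Boolean expression over the dummy
#'   variables (e.g. `"rs1799750_2 & !rs2276109_1"`, operators `&`, `|`,
#'   `!`) or an implicant from [extract_interactions()].
#' @param outcome `"status"` or a sub-phenotype name.
#' @return A list: `table` (2x2 counts, carrier x outcome), `p_fisher`.
#' @export
interaction_frequency_table <- function(cohort, interaction,
                                        outcome = "status") {
  B <- binarize(cohort$genotypes)
  y <- cohort_outcome(cohort, outcome)
  if (length(attr(B, "dropped"))) y <- y[-attr(B, "dropped")]
  keep <- !is.na(y)
  B <- B[keep, , drop = FALSE]
  y <- y[keep]
  carrier <- if (is.character(interaction)) {
    env <- as.data.frame(B == 1)
    as.logical(eval(parse(text = interaction), envir = env))
  } else {
    eval_implicants(list(interaction), B)
  }
  tab <- table(carrier = factor(carrier, levels = c(FALSE, TRUE)),
               outcome = factor(y, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; Fisher p reported as 1")
    return(list(table = tab, p_fisher = 1))
  }
  list(table = tab, p_fisher = fisher.test(tab)$p.value)
}
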