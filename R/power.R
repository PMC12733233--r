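POWER_MODELS <- c("additive", "dominant", "recessive")

#' Analytic power of a single-SNP logistic association test
#'
#' Power of the 1-df chi-square (score) test of the genetic term in a
#' logistic regression, for a case-control design. Control genotype
#' frequencies follow HWE at the given minor allele frequency; case
#' genotype frequencies are the exponential tilt
#' `f_case(g) \propto f_control(g) * OR^x(g)` implied by a logistic model
#' with the inheritance coding `x` (additive dose 0/1/2, dominant or
#' recessive indicator). The expected Fisher information of the
#' retrospective logistic fit gives the non-centrality, and power is the
#' upper tail of the non-central chi-square at the two-sided alpha. The
#' approximation tracks the finite-sample score/likelihood-ratio tests; the
#' Wald statistic is avoided because it degenerates (Hauck-Donner) for the
#' sparse recessive contrasts this design produces at low MAF.
#'
#' @param or_ Odds ratio per coded unit (> 0); `or_ = 1` returns `alpha`.
#' @param maf Control minor allele frequency in (0, 1).
#' @param n_cases,n_controls Group sizes.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
genetic_power <- function(or_, maf, n_cases, n_controls,
                          model = c("additive", "dominant", "recessive"),
                          alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(or_ > 0, maf > 0, maf < 1, n_cases >= 1, n_controls >= 1,
            alpha > 0, alpha < 1)
  p <- maf
  f0 <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  x <- switch(model, additive = c(0, 1, 2), dominant = c(0, 1, 1),
              recessive = c(0, 0, 1))
  f1 <- f0 * or_^x
  f1 <- f1 / sum(f1)
  N <- n_cases * f1 + n_controls * f0
  pr <- n_cases * f1 / N
  w <- N * pr * (1 - pr)
  info <- rbind(c(sum(w), sum(w * x)), c(sum(w * x), sum(w * x^2)))
  v <- solve(info)[2, 2]
  ncp <- log(or_)^2 / v
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Minimal detectable odds ratio (MDOR) by grid search
#'
#' Searches an OR grid upward from 1 for the smallest odds ratio whose
#' analytic power reaches the target — the study's post hoc sensitivity
#' analysis. When the target is unreachable below `or_max` the result
#' carries `mdor = NA` and `open_bound = TRUE` (reported as "> or_max").
#'
#' @inheritParams genetic_power
#' @param target_power Target power (study values 0.80 and 0.90).
#' @param grid_step OR grid resolution.
#' @param or_max Upper search bound.
#' @return A tibble: `model`, `maf`, `target_power`, `mdor`,
#'   `power_at_mdor`, `open_bound`.
#' @export
mdor_search <- function(maf, model, target_power = 0.8, n_cases = 160,
                        n_controls = 136, alpha = 0.05, grid_step = 0.01,
                        or_max = 10) {
  stopifnot(grid_step > 0)
  model <- match.arg(model, POWER_MODELS)
  grid <- seq(1 + grid_step, or_max, by = grid_step)
  pw <- vapply(grid, genetic_power, 0, maf = maf, n_cases = n_cases,
               n_controls = n_controls, model = model, alpha = alpha)
  hit <- which(pw >= target_power)
  if (length(hit) == 0)
    return(tibble::tibble(model = model, maf = maf,
                          target_power = target_power, mdor = NA_real_,
                          power_at_mdor = NA_real_, open_bound = TRUE))
  k <- hit[1]
  tibble::tibble(model = model, maf = maf, target_power = target_power,
                 mdor = grid[k], power_at_mdor = pw[k], open_bound = FALSE)
}

#' MDOR table over the study's models and control MAFs
#'
#' Convenience wrapper running [mdor_search()] for each combination of
#' model, MAF and target power at the study's sample sizes.
#'
#' @inheritParams mdor_search
#' @param mafs Named vector of control MAFs (default: the study's,
#'   [study_control_mafs()]).
#' @param models Inheritance models to tabulate.
#' @param target_powers Target powers.
#' @return A tibble, one row per combination, with an `snp` column when
#'   `mafs` is named.
#' @export
mdor_table <- function(mafs = study_control_mafs(),
                       models = POWER_MODELS,
                       target_powers = c(0.8, 0.9), n_cases = 160,
                       n_controls = 136, alpha = 0.05, grid_step = 0.01,
                       or_max = 10) {
  rows <- list()
  for (m in models) for (i in seq_along(mafs)) for (tp in target_powers) {
    r <- mdor_search(mafs[i], m, target_power = tp, n_cases = n_cases,
                     n_controls = n_controls, alpha = alpha,
                     grid_step = grid_step, or_max = or_max)
    if (!is.null(names(mafs))) r$snp <- names(mafs)[i]
    rows[[length(rows) + 1]] <- r
  }
  dplyr::bind_rows(rows)
}

#' Monte-Carlo power estimate (simulation oracle)
#'
#' Empirical rejection rate of the logistic score (Rao) test over simulated
#' case-control datasets drawn from the same design as [genetic_power()].
#' Used to validate the analytic approximation.
#'
#' @inheritParams genetic_power
#' @param n_sim Number of simulated datasets.
#' @param seed RNG seed (`NULL` continues the caller's stream).
#' @return Empirical power.
#' @export
mc_power <- function(or_, maf, n_cases, n_controls, model = "additive",
                     alpha = 0.05, n_sim = 2000, seed = NULL) {
  model <- match.arg(model, POWER_MODELS)
  p <- maf
  f0 <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  x <- switch(model, additive = c(0, 1, 2), dominant = c(0, 1, 1),
              recessive = c(0, 0, 1))
  f1 <- f0 * or_^x
  f1 <- f1 / sum(f1)
  with_seed_(seed, {
    rej <- vapply(seq_len(n_sim), function(s) {
      g0 <- sample.int(3, n_controls, replace = TRUE, prob = f0)
      g1 <- sample.int(3, n_cases, replace = TRUE, prob = f1)
      xx <- x[c(g0, g1)]
      yy <- rep(0:1, c(n_controls, n_cases))
      if (length(unique(xx)) < 2) return(FALSE)
      fit0 <- glm(yy ~ 1, family = binomial())
      fit1 <- suppressWarnings(glm(yy ~ xx, family = binomial()))
      p_score <- anova(fit0, fit1, test = "Rao")[2, "Pr(>Chi)"]
      !is.na(p_score) && p_score < alpha
    }, logical(1))
    mean(rej)
  })
}
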