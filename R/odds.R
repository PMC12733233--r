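#' Woolf confidence interval for a 2x2 odds ratio
#'
#' Bounds are `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. The
#' interval is undefined (both bounds `NA`) whenever any cell is zero,
#' matching the convention of reporting "0.00 (0.00)" rows without an
#' interval.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' woolf_ci(20, 10, 38, 91)  # 2.05 - 11.19
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  check_cells(a, b, c, d)
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  stopifnot(level > 0, level < 1)
  if (min(a, b, c, d) == 0) return(c(low = NA_real_, high = NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  lo <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(low = exp(lo - z * se), high = exp(lo + z * se))
}

#' Crude (cross-product) odds ratio with Woolf CI
#'
#' `OR = (a * d) / (b * c)`. When a zero cell makes the ratio degenerate the
#' estimate is reported as the `0` or `Inf` sentinel with the CI omitted; no
#' continuity correction is applied. The p-value is the likelihood-ratio
#' (G-)test of independence, equivalent to the LRT on an unadjusted logistic
#' fit.
#'
#' @inheritParams woolf_ci
#' @return A tibble (one row): `or`, `ci_low`, `ci_high`, `p`.
#' @examples
#' crude_odds_ratio(20, 10, 38, 91)  # OR 4.79 (2.05; 11.19)
#' @export
crude_odds_ratio <- function(a, b, c, d, level = 0.95) {
  check_cells(a, b, c, d)
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  or <- if (b * c > 0) (a * d) / (b * c) else if (a == 0 || d == 0) 0 else Inf
  # a==0 (or d==0) together with b*c==0 is still reported as the 0 sentinel
  ci <- woolf_ci(a, b, c, d, level)
  p <- g_test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  tibble::tibble(or = or, ci_low = ci[["low"]], ci_high = ci[["high"]], p = p)
}

check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative")
  if (sum(cells) == 0) stop("table total must be positive")
  invisible(cells)
}

# likelihood-ratio (G) test of independence on an r x c count table
g_test <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  g <- 2 * sum(tab[keep] * log(tab[keep] / exp_tab[keep]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  pchisq(g, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment for a test family
#'
#' Step-up FDR adjustment `adj(i) = min_{j >= i} p_(j) * m / j`, capped at 1
#' and mapped back to the input order (delegates to [stats::p.adjust()]).
#' The two families of the study design are the case-control family (3 SNPs
#' x 4 models, m = 12) and the within-case family (3 SNPs x 4 outcomes x 4
#' models, m = 48); the codominant model contributes a single block p-value
#' to its family even though it has two genotype contrasts.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
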