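#' Configuration for the synthetic-cohort generator
#'
#' The defaults reproduce the design of the emulated study: 160 cases / 136
#' controls, the three-MMP panel at the control MAFs, case/control age and
#' body-mass distributions of 36 (7) vs 27 (4) years and 78 (10) vs 73 (16)
#' kg, and sub-phenotype prevalences among cases matching the printed group
#' sizes (ACLF multiple 59/160, ACLS 129/160, ACLRP 40/160, ACLRC 19/160).
#' Sub-phenotypes are drawn independently among cases (the published strata
#' overlap). Genotypes are independent across SNPs unless haplotype
#' frequencies are supplied.
#'
#' @param n_cases,n_controls Group sizes.
#' @param panel An [snp_panel()].
#' @param maf Per-SNP population (control) minor allele frequencies.
#' @param hap_freqs Optional named haplotype frequency vector (labels as in
#'   [em_haplotype_frequencies()]) inducing LD between the panel SNPs; only
#'   compatible with null genetic effects.
#' @param status_effects Optional list of `list(snp=, model=, or=)` entries:
#'   case genotypes are drawn from the exponential-tilt distribution
#'   implied by a logistic effect of that size (controls stay at HWE).
#' @param subtype_effects Optional list of `list(outcome=, snp=, model=,
#'   or=)` entries: the sub-phenotype is assigned among cases by a logistic
#'   model on the encoded genotype, with the intercept solved so the
#'   marginal prevalence matches `subtype_prev`.
#' @param subtype_prev Named prevalences of the four sub-phenotypes among
#'   cases.
#' @param covariate_means List with `case`/`control` entries of
#'   `c(age_mean, age_sd, mass_mean, mass_sd)`.
#' @param missing_rate Uniform genotype missingness rate.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 160, n_controls = 136, panel = mmp_panel(),
                       maf = study_control_mafs(), hap_freqs = NULL,
                       status_effects = NULL, subtype_effects = NULL,
                       subtype_prev = c(aclf = 59 / 160, acls = 129 / 160,
                                        aclrp = 40 / 160, aclrc = 19 / 160),
                       covariate_means = list(
                         control = c(age_mean = 27, age_sd = 4,
                                     mass_mean = 73, mass_sd = 16),
                         case = c(age_mean = 36, age_sd = 7,
                                  mass_mean = 78, mass_sd = 10)),
                       missing_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  panel <- as_panel(panel)
  stopifnot(n_cases >= 1, n_controls >= 1,
            length(maf) == nrow(panel), all(maf > 0), all(maf < 1),
            missing_rate >= 0, missing_rate < 1,
            all(subtype_prev >= 0), all(subtype_prev <= 1))
  if (!is.null(hap_freqs)) {
    if (abs(sum(hap_freqs) - 1) > 1e-8)
      stop("haplotype frequencies must sum to 1")
    if (!is.null(status_effects))
      stop("haplotype LD simulation supports null status effects only")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, panel = panel,
                 maf = maf, hap_freqs = hap_freqs,
                 status_effects = status_effects,
                 subtype_effects = subtype_effects,
                 subtype_prev = subtype_prev,
                 covariate_means = covariate_means,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw genotype codes under Hardy-Weinberg proportions
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency in (0, 1); the limit `maf -> 0` gives
#'   all code 1.
#' @param seed Optional seed (`NULL` continues the caller's stream).
#' @return Integer codes in `{1, 2, 3}` drawn from `(p^2, 2pq, q^2)`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  stopifnot(maf >= 0, maf < 1)
  q <- maf; p <- 1 - maf
  with_seed_(seed,
    sample.int(3L, n, replace = TRUE, prob = c(p^2, 2 * p * q, q^2)))
}

# exponential-tilt case genotype distribution for one SNP
tilt_probs <- function(maf, model, or_) {
  q <- maf; p <- 1 - q
  f0 <- c(p^2, 2 * p * q, q^2)
  x <- switch(model, log_additive = c(0, 1, 2), additive = c(0, 1, 2),
              dominant = c(0, 1, 1), recessive = c(0, 0, 1),
              overdominant = c(0, 1, 0))
  f1 <- f0 * or_^x
  f1 / sum(f1)
}

# intercept of a logistic subtype model hitting a target prevalence in
# expectation over the genotype distribution
solve_intercept <- function(prev, gprobs, x, log_or) {
  f <- function(b0) sum(gprobs * stats::plogis(b0 + log_or * x)) - prev
  uniroot(f, c(-30, 30))$root
}

#' Simulate a full case-control cohort
#'
#' Draws genotypes (HWE per SNP, or from haplotype frequencies when LD is
#' configured), applies any configured genotype-status effect by
#' exponential tilting of the case genotype distribution, samples the
#' demographic covariates from group-specific normal distributions, and
#' assigns the binary sub-phenotypes among cases by independent Bernoulli
#' draws or by a genotype-dependent logistic model. A fixed seed makes the
#' cohort (and files written from it) byte-identical across runs.
#'
#' @param cfg A [sim_config()].
#' @return A [join_cohort()]-compatible `cohort` object.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg, carrier_expr = NULL, carrier_or = 1) {
  L <- nrow(cfg$panel)
  n <- cfg$n_cases + cfg$n_controls
  status <- rep(c(0L, 1L), c(cfg$n_controls, cfg$n_cases))

  if (!is.null(cfg$hap_freqs)) {
    codes <- draw_codes_from_haps(n, cfg)
  } else if (!is.null(carrier_expr)) {
    codes <- draw_codes_tilted_joint(cfg, carrier_expr, carrier_or, status)
  } else {
    codes <- matrix(NA_integer_, n, L, dimnames = list(NULL, cfg$panel$id))
    for (j in seq_len(L)) {
      eff <- effect_for(cfg$status_effects, cfg$panel$id[j])
      f0 <- tilt_probs(cfg$maf[j], "dominant", 1)  # HWE baseline
      f1 <- if (is.null(eff)) f0 else
        tilt_probs(cfg$maf[j], eff$model, eff$or)
      codes[status == 0, j] <- sample.int(3L, cfg$n_controls, TRUE, prob = f0)
      codes[status == 1, j] <- sample.int(3L, cfg$n_cases, TRUE, prob = f1)
    }
  }

  cm <- cfg$covariate_means
  age <- ifelse(status == 1,
                rnorm(n, cm$case["age_mean"], cm$case["age_sd"]),
                rnorm(n, cm$control["age_mean"], cm$control["age_sd"]))
  mass <- ifelse(status == 1,
                 rnorm(n, cm$case["mass_mean"], cm$case["mass_sd"]),
                 rnorm(n, cm$control["mass_mean"], cm$control["mass_sd"]))

  pheno <- tibble::tibble(
    sample = c(sprintf("ctrl_%03d", seq_len(cfg$n_controls)),
               sprintf("case_%03d", seq_len(cfg$n_cases))),
    status = status, age = round(age, 1), body_mass = round(mass, 1))

  for (sub in names(cfg$subtype_prev)) {
    prev <- cfg$subtype_prev[[sub]]
    v <- rep(NA_integer_, n)
    eff <- effect_for(cfg$subtype_effects, sub, by = "outcome")
    if (is.null(eff)) {
      v[status == 1] <- rbinom(cfg$n_cases, 1, prev)
    } else {
      j <- match(eff$snp, cfg$panel$id)
      x <- switch(eff$model, log_additive = c(0, 1, 2),
                  dominant = c(0, 1, 1), recessive = c(0, 0, 1),
                  overdominant = c(0, 1, 0))
      gprobs <- tabulate(codes[status == 1, j], 3) / cfg$n_cases
      b0 <- solve_intercept(prev, gprobs, x, log(eff$or))
      pr <- stats::plogis(b0 + log(eff$or) * x[codes[status == 1, j]])
      v[status == 1] <- rbinom(cfg$n_cases, 1, pr)
    }
    pheno[[sub]] <- v
  }

  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(n * L) < cfg$missing_rate, n, L)
    codes[drop] <- NA_integer_
  }
  gt <- genotype_table(codes, cfg$panel, samples = pheno$sample)
  join_cohort(gt, phenotype_table(pheno))
}

effect_for <- function(effects, id, by = "snp") {
  if (is.null(effects)) return(NULL)
  for (e in effects) if (identical(e[[by]], id)) return(e)
  NULL
}

draw_codes_from_haps <- function(n, cfg) {
  L <- nrow(cfg$panel)
  labels <- names(cfg$hap_freqs)
  alleles <- strsplit(labels, "-", fixed = TRUE)
  minor <- t(vapply(alleles, function(a) a == cfg$panel$minor_allele,
                    logical(L)))
  h1 <- sample.int(length(labels), n, TRUE, prob = cfg$hap_freqs)
  h2 <- sample.int(length(labels), n, TRUE, prob = cfg$hap_freqs)
  codes <- 1L + minor[h1, , drop = FALSE] + minor[h2, , drop = FALSE]
  storage.mode(codes) <- "integer"
  colnames(codes) <- cfg$panel$id
  codes
}

# joint 3^L genotype distribution with a Boolean carrier effect on status:
# controls ~ product-HWE; cases ~ tilt by OR^carrier
draw_codes_tilted_joint <- function(cfg, carrier_expr, or_, status) {
  L <- nrow(cfg$panel)
  combos <- as.matrix(expand.grid(rep(list(1:3), L)))
  colnames(combos) <- cfg$panel$id
  probs <- rep(1, nrow(combos))
  for (j in seq_len(L)) {
    q <- cfg$maf[j]; p <- 1 - q
    probs <- probs * c(p^2, 2 * p * q, q^2)[combos[, j]]
  }
  carrier <- evaluate_carrier(carrier_expr, combos)
  q_carrier <- sum(probs[carrier])
  if (q_carrier == 0 || q_carrier == 1)
    warning("planted interaction is never/always true under the genotype model")
  p_case <- probs * or_^carrier
  p_case <- p_case / sum(p_case)
  idx <- integer(length(status))
  idx[status == 0] <- sample.int(nrow(combos), sum(status == 0), TRUE,
                                 prob = probs)
  idx[status == 1] <- sample.int(nrow(combos), sum(status == 1), TRUE,
                                 prob = p_case)
  codes <- combos[idx, , drop = FALSE]
  storage.mode(codes) <- "integer"
  rownames(codes) <- NULL
  codes
}

# carrier expression: function(codes) -> logical, or character expression
# over dummy variables (<snp>_1, <snp>_2) as used by the logic module
evaluate_carrier <- function(expr, codes) {
  if (is.function(expr)) return(as.logical(expr(codes)))
  B <- binarize(codes)
  env <- as.data.frame(B == 1)
  as.logical(eval(parse(text = expr), envir = env))
}

#' Simulate a cohort with a planted Boolean interaction effect
#'
#' Raises the case odds by `or_` for carriers of a Boolean combination of
#' genotypes (e.g. a compound genotype such as homozygous-major at one
#' locus AND heterozygous at another). Controls are drawn from the
#' product-HWE genotype distribution; cases from its exponential tilt, the
#' retrospective-sampling equivalent of a logistic carrier effect.
#'
#' @param cfg A [sim_config()] (its `status_effects` must be `NULL`).
#' @param expression A function of the code matrix returning a logical
#'   carrier indicator, or a character Boolean expression over the
#'   dummy-encoded variables (see [binarize()]).
#' @param or_ Carrier odds ratio (1 = null).
#' @return A `cohort`.
#' @export
plant_logic_interaction <- function(cfg, expression, or_) {
  stopifnot(inherits(cfg, "sim_config"), or_ > 0)
  if (!is.null(cfg$status_effects))
    stop("combine either per-SNP status effects or a planted interaction")
  with_seed_(cfg$seed,
             simulate_cohort_impl(cfg, carrier_expr = expression,
                                  carrier_or = or_))
}
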