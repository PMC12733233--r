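---
title: "Candidate-gene association analysis of MMP polymorphisms and ACL injury"
author: "mmpassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association analysis of MMP polymorphisms and ACL injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpassoc)
```

## The study design this package implements

`mmpassoc` re-implements, as a tested and reusable pipeline, the analysis of
a candidate-gene case–control study of anterior cruciate ligament (ACL)
injury in male football players: 160 injured cases and 136 uninjured
controls genotyped at three biallelic matrix metalloproteinase (MMP)
polymorphisms — the *MMP1* promoter indel rs1799750 (alleles D/I, minor I),
the *MMP10* coding variant rs486055 (C/T, minor T) and the *MMP12* promoter
variant rs2276109 (A/G, minor G). Within the case group, four binary
sub-phenotypes describe the injury: ACLF (injury frequency, single vs.
multiple), ACLS (strain), ACLRP (partial rupture) and ACLRC (complete
rupture). Cases and controls differ demographically (age 36 ± 7 vs. 27 ± 4
years; body mass 78 ± 10 vs. 73 ± 16 kg), which motivates the
covariate-adjusted estimators.

Genotypes are coded `1` (homozygous major/reference), `2` (heterozygous),
`3` (homozygous minor), and the minor allele is always treated as the risk
factor. The individual-level data of the motivating study are not public;
what is public are the genotype count tables, test summaries and protocol
descriptions. The package therefore ships (a) the printed count tables as
plain data (`acl_within_case_counts()` and friends), against which the
estimators can be validated exactly, and (b) a synthetic-cohort generator
(`simulate_cohort()`) whose defaults emulate the study design, so that every
stage — including the stochastic multi-locus protocol — can be exercised
end-to-end without any external data.

## Single-locus models

`run_single_locus_scan()` evaluates every SNP × outcome × genetic-model
combination. The genetic models collapse the three genotypes into exposure
contrasts: codominant (each genotype vs. the homozygous-major reference,
a 2-df block test), dominant (`{2,3}` vs. `{1}`), recessive (`{3}` vs.
`{1,2}`), overdominant (`{2}` vs. `{1,3}`) and log-additive (allele dose
0/1/2).

Two estimators are provided and labelled explicitly:

* **crude** — the cross-product odds ratio `ad/bc` of the collapsed 2×2
  table with the Woolf confidence interval
  `exp(log(OR) ± z · sqrt(1/a + 1/b + 1/c + 1/d))`, and a likelihood-ratio
  (G-)test block p-value. This is the estimator whose output matches the
  published within-case tables row for row; it is also what
  `scripts/acceptance.R` recomputes.
* **adjusted** — maximum-likelihood logistic regression with covariates
  (age, body mass), Wald intervals per contrast and a likelihood-ratio test
  of the genotype block. The published case–control odds ratios are of this
  kind and cannot be reproduced from counts alone; the package instead
  validates the adjusted estimator by parameter recovery on synthetic
  cohorts with planted effects.

Zero-cell tables get no continuity correction: the estimate is reported as
the `0` (no exposed cases / no unexposed non-cases) or `Inf` sentinel with
the interval omitted, and the report renderer prints both as `0.00 (0.00)`,
the convention used in the published tables.

Multiple testing follows Benjamini–Hochberg step-up FDR control
(`bh_adjust()`, delegating to `stats::p.adjust`). A scan is one FDR family:
the case–control family has m = 12 members (3 SNPs × 4 models) and the
within-case family m = 48 (3 × 4 outcomes × 4 models); the codominant block
contributes a single p-value to its family even though it has two genotype
contrasts. Applied to the published p-value columns, this reconstruction
reproduces the published FDR columns exactly, ties included.

Hardy–Weinberg equilibrium is checked with an exact test
(`hwe_test()`): the heterozygote count is enumerated conditional on the
observed allele counts and the two-sided p-value sums the probabilities of
all tables no more probable than the observed one. A 1-df Pearson
chi-square p-value is reported alongside because the motivating study does
not state its method; on the published case-group counts the exact test
reproduces the published values (0.749, 1.00, 0.115) to three decimals.

## EM haplotype analysis

`em_haplotype_frequencies()` estimates multi-SNP haplotype frequencies from
unphased genotypes by expectation-maximisation. Each individual's
compatible (unordered) phase pairs receive posterior weights proportional
to `f_a · f_b` (doubled for heterogeneous pairs); the M-step re-estimates
frequencies from expected haplotype counts. The log-likelihood is asserted
non-decreasing at every iteration, and iteration stops when the gain drops
below `tol` (default 1e-8). Initialisation is uniform over the haplotypes
compatible with the sample and label order is lexicographic, so the result
is deterministic; individuals missing any panel genotype are dropped
listwise, the simplest policy for a 3-SNP panel with sporadic missingness.
The test suite verifies the EM against a brute-force multinomial-likelihood
grid maximiser on 2-SNP toys (agreement to 1e-4) — a check that in
development caught a subtle phase-enumeration bug, which is exactly the
kind of defect a likelihood-based oracle is for.

`haplo_glm()` regresses a binary outcome on additive haplotype doses under
phase uncertainty: design rows are expanded over compatible pairs, weighted
by the phase posteriors, and the weighted logistic fit and posterior update
are iterated to convergence (each pair's weight is multiplied by the
likelihood of the observed outcome under the current model). The most
frequent haplotype is the reference; haplotypes below a pooling threshold
(default 0.01, the convention of the standard haplotype-GLM tools) are
pooled into a `rare` term. On a single-SNP panel the procedure reduces
exactly (to 1e-6) to the log-additive logistic fit, and with unambiguous
phase it reduces to ordinary logistic regression on known doses — both are
tested. The motivating study describes this analysis but reports no
haplotype results, so the module's validation is purely oracle- and
property-based.

## Logic regression and the permutation-null protocol

The multi-locus analysis searches for Boolean combinations of
dummy-encoded genotypes that discriminate the outcome. Each SNP becomes
two binary variables — `SNP_1` (carries at least one minor allele) and
`SNP_2` (homozygous minor) — so a 3-SNP panel spans a 6-bit space of 64
combinations, of which the 27 joint genotypes are a distinct subset.

`anneal_fit()` (compiled code) searches trees of AND/OR nodes over possibly
complemented leaves, up to `max_leaves` (study default 10), by Metropolis
simulated annealing over five move types (relabel leaf, complement leaf,
flip operator, grow, prune). The objective is the 2-group training
misclassification plus a small complexity penalty,
`leaf_penalty · (leaves − 1)` with a default of 2 misclassified-count
units. The penalty is a deliberate design choice: single-tree logic
regression normally selects tree size by cross-validation, which the bagged
protocol here cannot afford, and an unpenalised search absorbs bootstrap
noise into junk leaves whose spurious interactions then dominate the
importance measures. The start temperature is chosen automatically so that
roughly 90% of typical uphill moves on a short probe walk would be
accepted; cooling is geometric. The search uses its own xorshift RNG, so a
fixed seed reproduces the fitted tree bit for bit on any platform.

Fitted trees are decomposed into **interactions** = prime implicants of
their Boolean function (Quine–McCluskey minimisation of the truth table
over the variables in the tree). Trees are first orientation-canonicalised:
if the tree-TRUE group predicts class 0, the complement of the function is
minimised instead, so that an interaction always describes a risk
combination. Without this, a classifier and its De Morgan complement —
identical as predictors — would be counted under two different interaction
sets, halving every recovery statistic.

`logic_fs()` bags the fit over bootstrap samples and reports, per
interaction, the proportion of models containing it and the mean drop in
out-of-bag classification accuracy when it is removed from the models that
contain it. `null_comparison()` implements the inference protocol: the
analysis is repeated `n_iter` times on the real labels and `n_iter` times
on freshly permuted labels, interactions with mean proportion above 0.15
are ranked by mean importance, and the k-th ranked real interaction is
compared against the k-th largest importance the same analysis finds in
each null iteration (percentile bootstrap CIs of both means; flagged when
the real CI lies entirely above the null CI). Rank matching is essential:
every fixed dataset — including one with permuted labels — contains *some*
chance association that the analysis finds consistently, so a pre-named
interaction's own null importance (near zero, because that specific
combination rarely resurfaces under permutation) is not a fair yardstick.
The one-sided rule tests the scientifically relevant direction, elevated
importance.

The full study protocol is 200 iterations with 100 bootstraps. The test
suite and the acceptance script run a reduced protocol — 50 iterations, 40
bootstraps, 2 500 annealing proposals per fit, 10 seeded repeats — which
recovers a planted compound-genotype effect (odds ratio 3 at the study's
sample size) in ≥80% of repeats while flagging nothing on double-null data.
These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in minutes; the full-protocol
defaults remain available through the function arguments.

## Power and the minimal detectable odds ratio

`genetic_power()` computes the power of the 1-df chi-square test of the
genetic term in a logistic case–control model. Control genotype
frequencies follow HWE at the control minor-allele frequency; case
frequencies are the exponential tilt `f_case(g) ∝ f_control(g) · OR^x(g)`
implied by the logistic model with additive, dominant or recessive coding —
under retrospective sampling this is exact, and the retrospective logistic
slope equals the prospective one. The expected Fisher information yields
the non-centrality and power follows from the non-central chi-square. The
statistic being approximated is the score (Rao) test — the standard trend /
chi-square association test: the asymptotically equivalent Wald statistic
was rejected as the reference because it degenerates (the Hauck–Donner
effect) for the sparse recessive contrast at low MAF that this very design
produces, where its finite-sample rejection rate falls to a third of every
asymptotic approximation. A Monte-Carlo oracle (`mc_power()`) simulating
the same design and rejecting on the score test agrees with the analytic
power within three percentage points across a model × MAF grid (MAF down
to 0.15, recessive included) at the study's sample sizes.

`mdor_search()` walks an OR grid (default step 0.01 from 1.01 to 10) and
returns the smallest OR reaching the target power, flagging an open upper
bound when the target is unreachable — the situation the study reports for
the recessive model at low MAF. Because the published count-table column
headers conflict with the stated group sizes, which column holds the
controls is configurable (`study_control_mafs()`); the default is the
column summing to 136, the stated control N, whose rs486055 MAF of 0.15
matches the study's recessive-model power remark. Under these MAFs
({0.46, 0.15, 0.11}) the additive MDORs at 80% power fall in 1.61–1.98 and
the dominant ones in 2.01–2.25, inside the published 1.6–2.1 and 2.1–2.4
bands up to the approximation ambiguity of the power formula.

## The synthetic-cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the
analysis assumes. Defaults are the study conditions: 160 cases / 136
controls; per-SNP HWE genotypes at the control MAFs; group-specific normal
age and body-mass distributions at the published moments; sub-phenotype
prevalences among cases matching the published group sizes (ACLF multiple
59/160, ACLS 129/160, ACLRP 40/160, ACLRC 19/160), drawn independently
because the published strata overlap; no linkage disequilibrium (none is
reported for the three loci — LD is available through explicit haplotype
frequencies, for null effects only); uniform missingness (default 0);
covariate–outcome coefficients default to 0 because the study implies but
never quantifies confounding. Effects are planted either per SNP
(exponential tilt of the case genotype distribution — exact retrospective
sampling), per sub-phenotype (logistic model among cases with the intercept
solved to hit the target prevalence), or as a Boolean carrier effect over
the joint 27-genotype distribution (`plant_logic_interaction()`).

What the generator does *not* emulate: population structure, genotyping
error beyond uniform missingness, LD with unobserved causal variants,
correlated sub-phenotypes, and non-normal covariates. Passing recovery
tests therefore show that the estimators are correct under the model the
analysis itself assumes — not that the published biological findings are
correct, nor that real cohorts are free of confounding beyond age and body
mass.

## Numerical conventions and degenerate inputs

* Report tables round ORs and CI bounds to 2 decimals, half away from
  zero; internal computation is full precision.
* Zero-cell 2×2 tables: sentinels `0`/`Inf`, CI omitted, no continuity
  correction; G-test returns 1 on degenerate margins.
* Exact HWE includes tables tied with the observed probability (within a
  1e-12 relative tolerance) in the two-sided sum; monomorphic loci give
  p = 1.
* EM ties are avoided by lexicographic label order; the log-likelihood
  monotonicity assertion turns numerical regressions into hard errors.
* Separation in logistic fits flags the estimate rather than failing; a
  rank-deficient design is an error.
* Every stochastic stage takes an explicit seed; `sim_config()` requires
  one.

## Reduced problem sizes used by the test suite

Unit tests run toys (tens to hundreds of samples). The acceptance-style
checks use: 50 seeds for the planted dominant-OR recovery at the study's
group sizes; 2 000 Monte-Carlo datasets per power cell on a 3 × 3 grid;
and the reduced logic-regression protocol described above (about 9 minutes
of the suite's runtime). These sizes are the package's choices for routine
verification; all protocol parameters scale back up through function
arguments.
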