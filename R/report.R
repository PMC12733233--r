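#' Render a scan result as a publication-style association table
#'
#' Formats the output of [run_single_locus_scan()] in the layout of the
#' study's tables: rows grouped by model with a `1.00` reference row,
#' `OR (95% CI)` at 2 decimal places (half-up), counts as `N (%)` within
#' outcome level, and `P/FDR P` rendered on the first row of each block.
#' Degenerate zero-cell estimates render as `0.00 (0.00)` with the interval
#' omitted. Rendering is a pure formatting step: every number is traceable
#' to an estimate column, and re-rendering is idempotent.
#'
#' @param scan A tibble from [run_single_locus_scan()].
#' @param layout `"within_case"` (keeps the outcome column) or
#'   `"case_control"`.
#' @return A tibble of character columns.
#' @export
render_assoc_table <- function(scan, layout = c("within_case",
                                                "case_control")) {
  layout <- match.arg(layout)
  if (nrow(scan) == 0)
    return(tibble::tibble(snp = character(), model = character()))
  fmt_or <- function(or, lo, hi, ref) {
    dplyr::case_when(
      ref ~ "1.00",
      is.na(or) ~ "-",
      !is.finite(or) | or == 0 | is.na(lo) ~ "0.00 (0.00)",
      TRUE ~ sprintf("%.2f (%.2f; %.2f)", round_half_up(or),
                     round_half_up(lo), round_half_up(hi)))
  }
  fmt_p <- function(p, fdr) ifelse(is.na(p), "",
                                   paste0(signif(p, 2), "/", signif(fdr, 2)))
  pct <- function(nn) {
    out <- rep(NA_character_, length(nn))
    out
  }
  out <- scan
  # counts with within-column percentages per (snp, outcome, model) block
  out <- dplyr::group_by(out, .data$snp, .data$outcome, .data$model)
  out <- dplyr::mutate(out,
    n0_pct = ifelse(is.na(.data$n0), "-",
                    sprintf("%d (%.1f)", .data$n0,
                            100 * .data$n0 / sum(.data$n0, na.rm = TRUE))),
    n1_pct = ifelse(is.na(.data$n1), "-",
                    sprintf("%d (%.1f)", .data$n1,
                            100 * .data$n1 / sum(.data$n1, na.rm = TRUE))))
  out <- dplyr::ungroup(out)
  # P/FDR on the first non-reference row of each block only
  grp <- paste(out$snp, out$outcome, out$model)
  eligible <- which(!out$ref & !is.na(out$p))
  keep <- eligible[!duplicated(grp[eligible])]
  show_p <- seq_len(nrow(out)) %in% keep
  res <- tibble::tibble(
    snp = out$snp,
    outcome = out$outcome,
    model = out$model,
    genotype = ifelse(is.na(out$genotype), "-", out$genotype),
    `N (%) level 0` = out$n0_pct,
    `N (%) level 1` = out$n1_pct,
    `OR (95% CI)` = fmt_or(out$or, out$ci_low, out$ci_high, out$ref),
    `P/FDR P` = ifelse(show_p, fmt_p(out$p, out$p_fdr), ""))
  if (layout == "case_control") res$outcome <- NULL
  res
}

#' Write a rendered association table as delimited text
#' @param rendered A tibble from [render_assoc_table()].
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_assoc_table <- function(rendered, path, sep = "\t") {
  write.table(rendered, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured analysis pipeline
#'
#' Single entry point dispatching the package's analyses from a
#' configuration list (or a YAML file): `simulate` (generate a cohort and
#' write its genotype/phenotype files), `hwe`, `scan`, `haplo`, `logicfs`
#' and `power`, executed in that dependency order. Every stochastic stage
#' draws from the configured `seed`, so a fixed configuration yields
#' identical outputs. Each output table is written as delimited text to
#' `out_dir` together with a `provenance.yaml` recording the configuration,
#' seed and package version. Errors are re-raised with the failing stage
#' named.
#'
#' @param config A list or path to a YAML file. Top-level fields:
#'   `analysis` (character vector), `seed`, `genotypes`/`phenotypes` (input
#'   paths, unless simulating), `out_dir`, and optional per-stage parameter
#'   blocks (`simulate`, `scan`, `haplo`, `logicfs`, `power`).
#' @param out_dir Output directory (overrides the config field).
#' @return Invisibly, a named list with each stage's result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$analysis))
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% stop("config requires a seed")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()
  analyses <- config$analysis
  panel <- if (!is.null(config$panel))
    snp_panel(config$panel$id, config$panel$major_allele,
              config$panel$minor_allele) else mmp_panel()

  cohort <- NULL
  if ("simulate" %in% analyses) {
    cohort <- stage("simulate", {
      args <- config$simulate %||% list()
      args$seed <- args$seed %||% seed
      args$panel <- panel
      if (!is.null(args$maf)) args$maf <- unlist(args$maf)
      cfg <- do.call(sim_config, args)
      cc <- simulate_cohort(cfg)
      write_genotypes(cc$genotypes, file.path(out_dir, "genotypes.csv"))
      write_phenotypes(cc$phenotypes, file.path(out_dir, "phenotypes.csv"))
      cc
    })
    results$simulate <- cohort
  } else if (!is.null(config$genotypes)) {
    cohort <- stage("core_io", {
      gt <- read_genotypes(config$genotypes, panel)
      pt <- read_phenotypes(config$phenotypes)
      join_cohort(gt, pt)
    })
  }

  if ("hwe" %in% analyses) {
    results$hwe <- stage("hwe", {
      h <- hwe_scan(cohort, group = config$hwe$group %||% "cases")
      write.table(h, file.path(out_dir, "hwe.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      h
    })
  }
  if ("scan" %in% analyses) {
    results$scan <- stage("scan", {
      args <- config$scan %||% list()
      sc <- run_single_locus_scan(
        cohort,
        outcomes = args$outcomes %||% "status",
        models = args$models %||% c("codominant", "dominant", "recessive",
                                    "overdominant"),
        covariates = args$covariates %||% character(),
        estimator = args$estimator %||% "crude")
      write.table(sc, file.path(out_dir, "scan.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      layout <- if (identical(args$outcomes %||% "status", "status"))
        "case_control" else "within_case"
      write_assoc_table(render_assoc_table(sc, layout),
                        file.path(out_dir, "scan_table.tsv"))
      sc
    })
  }
  if ("haplo" %in% analyses) {
    results$haplo <- stage("haplo", {
      args <- config$haplo %||% list()
      hs <- em_haplotype_frequencies(cohort, tol = args$tol %||% 1e-8,
                                     max_iter = args$max_iter %||% 1000)
      write.table(hs$haplotypes, file.path(out_dir, "haplotype_freqs.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      fit <- haplo_glm(cohort, outcome = args$outcome %||% "status",
                       covariates = args$covariates %||% character(),
                       rare_threshold = args$rare_threshold %||% 0.01,
                       hs = hs)
      write.table(fit$estimates, file.path(out_dir, "haplo_glm.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      list(frequencies = hs, glm = fit)
    })
  }
  if ("logicfs" %in% analyses) {
    results$logicfs <- stage("logicfs", {
      args <- config$logicfs %||% list()
      B <- binarize(cohort$genotypes)
      y <- cohort_outcome(cohort, args$outcome %||% "status")
      if (length(attr(B, "dropped"))) y <- y[-attr(B, "dropped")]
      ctl <- do.call(logic_control, args$control %||% list())
      nc <- null_comparison(B, y, n_iter = args$n_iter %||% 200,
                            n_bootstrap = args$n_bootstrap %||% 100,
                            max_leaves = args$max_leaves %||% 10,
                            control = ctl,
                            threshold = args$threshold %||% 0.15,
                            seed = seed)
      write.table(nc$summary, file.path(out_dir, "logicfs.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      nc
    })
  }
  if ("power" %in% analyses) {
    results$power <- stage("power", {
      args <- config$power %||% list()
      tab <- mdor_table(
        mafs = unlist(args$mafs %||% study_control_mafs()),
        models = args$models %||% POWER_MODELS,
        target_powers = args$target_powers %||% c(0.8, 0.9),
        n_cases = args$n_cases %||% 160,
        n_controls = args$n_controls %||% 136,
        alpha = args$alpha %||% 0.05,
        grid_step = args$grid_step %||% 0.01)
      write.table(tab, file.path(out_dir, "power_mdor.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      tab
    })
  }
  prov <- list(package = "mmpassoc",
               version = as.character(utils::packageVersion("mmpassoc")),
               seed = seed, config = config)
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(results)
}
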