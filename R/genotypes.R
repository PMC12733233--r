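#' Construct a genotype table
#'
#' Stores per-sample, per-SNP genotype codes relative to a [snp_panel()]:
#' `1` homozygous major, `2` heterozygous, `3` homozygous minor, `NA`
#' missing.
#'
#' @param codes Integer matrix (samples x SNPs) with values in
#'   `{1, 2, 3, NA}`. Column names, when present, must match the panel ids.
#' @param panel An [snp_panel()].
#' @param samples Character vector of unique sample identifiers
#'   (case-sensitive); defaults to the matrix rownames or `S1..Sn`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(codes, panel, samples = NULL) {
  panel <- as_panel(panel)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (ncol(codes) != nrow(panel))
    stop("codes must have one column per panel SNP")
  if (!is.null(colnames(codes)) && !identical(colnames(codes), panel$id)) {
    if (!setequal(colnames(codes), panel$id))
      stop("code columns do not match panel SNP ids")
    codes <- codes[, panel$id, drop = FALSE]
  }
  colnames(codes) <- panel$id
  if (is.null(samples)) samples <- rownames(codes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  samples <- as.character(samples)
  if (length(samples) != nrow(codes))
    stop("one sample id per row required")
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ", paste(samples[duplicated(samples)],
                                         collapse = ", "))
  bad <- !is.na(codes) & !(codes %in% 1:3)
  if (any(bad))
    stop("genotype codes must be 1, 2, 3 or NA")
  rownames(codes) <- samples
  structure(list(samples = samples, snps = panel, codes = codes),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("SNPs:", paste0(x$snps$id, " (", x$snps$major_allele, "/",
                      x$snps$minor_allele, ")", collapse = ", "), "\n")
  miss <- sum(is.na(x$codes))
  if (miss > 0) cat("missing genotypes:", miss, "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$codes)

# "A/B" allele-pair string -> code, relative to one panel row
geno_string_to_code <- function(s, major, minor) {
  s <- trimws(s)
  out <- rep(NA_integer_, length(s))
  filled <- !is.na(s) & nzchar(s) & s != "./." & s != "NA"
  parts <- strsplit(s[filled], "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed genotype value(s): ",
         paste(unique(s[filled][bad]), collapse = ", "))
  al <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  unknown <- !(al[, 1] %in% c(major, minor)) | !(al[, 2] %in% c(major, minor))
  if (any(unknown))
    stop("allele outside panel definition (", major, "/", minor, "): ",
         paste(unique(s[filled][unknown]), collapse = ", "))
  out[filled] <- 1L + (al[, 1] == minor) + (al[, 2] == minor)
  out
}

code_to_geno_string <- function(code, major, minor) {
  c(paste0(major, "/", major), paste0(major, "/", minor),
    paste0(minor, "/", minor), NA_character_)[ifelse(is.na(code), 4L, code)]
}

#' Read genotypes from delimited text or VCF
#'
#' The delimited dialect is one row per sample: a `sample` id column plus one
#' column per SNP holding `"X/Y"` allele pairs (empty or `NA` = missing).
#' VCF files are read with \pkg{vcfR}; `REF`/`ALT` are mapped onto the
#' panel's major/minor alleles by symbol (never by frequency), so a VCF whose
#' REF is the panel's minor allele is handled correctly.
#'
#' @param path File to read.
#' @param panel An [snp_panel()] declaring the expected SNPs and alleles.
#' @param format `"delimited"` or `"vcf"`; `"auto"` chooses `"vcf"` for
#'   `.vcf`/`.vcf.gz` extensions.
#' @param sep Field separator for the delimited format; `NULL` sniffs
#'   comma vs. tab from the header line.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, panel, format = c("auto", "delimited", "vcf"),
                           sep = NULL) {
  format <- match.arg(format)
  panel <- as_panel(panel)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "delimited"
  if (format == "vcf") return(read_genotypes_vcf(path, panel))

  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  }
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  idcol <- if ("sample" %in% names(df)) "sample" else names(df)[1]
  missing_snps <- setdiff(panel$id, names(df))
  if (length(missing_snps))
    stop("genotype file lacks SNP column(s): ",
         paste(missing_snps, collapse = ", "))
  codes <- matrix(NA_integer_, nrow = nrow(df), ncol = nrow(panel))
  for (j in seq_len(nrow(panel))) {
    codes[, j] <- tryCatch(
      geno_string_to_code(df[[panel$id[j]]], panel$major_allele[j],
                          panel$minor_allele[j]),
      error = function(e) stop("column ", panel$id[j], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  genotype_table(codes, panel, samples = df[[idcol]])
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  codes <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel))
  for (j in seq_len(nrow(panel))) {
    k <- which(ids == panel$id[j])
    if (length(k) != 1)
      stop("SNP ", panel$id[j], " not found exactly once in VCF")
    ref <- fix[k, "REF"]; alt <- fix[k, "ALT"]
    if (!setequal(c(ref, alt),
                  c(panel$major_allele[j], panel$minor_allele[j])))
      stop("VCF alleles ", ref, "/", alt, " do not match panel for ",
           panel$id[j])
    g <- gt[k, ]
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    minor_as_alt <- alt == panel$minor_allele[j]
    codes[, j] <- vapply(alleles, function(a) {
      if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_integer_)
      n_alt <- sum(a == "1")
      n_minor <- if (minor_as_alt) n_alt else 2L - n_alt
      1L + n_minor
    }, integer(1))
  }
  genotype_table(codes, panel, samples = samples)
}

#' Write genotypes as delimited text
#'
#' Inverse of [read_genotypes()] for the delimited dialect; a read of the
#' written file reproduces the codes exactly.
#'
#' @param gt A [genotype_table()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_genotypes <- function(gt, path, sep = ",") {
  stopifnot(inherits(gt, "genotype_table"))
  df <- data.frame(sample = gt$samples, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(gt$snps)))
    df[[gt$snps$id[j]]] <- code_to_geno_string(
      gt$codes[, j], gt$snps$major_allele[j], gt$snps$minor_allele[j])
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Swap the major/minor labelling of a SNP
#'
#' Relabelling maps genotype codes 1 <-> 3 and leaves heterozygotes fixed;
#' applying it twice restores the original table.
#'
#' @param gt A [genotype_table()].
#' @param snp SNP id to relabel.
#' @return A new `genotype_table`.
#' @export
swap_alleles <- function(gt, snp) {
  stopifnot(inherits(gt, "genotype_table"))
  j <- match(snp, gt$snps$id)
  if (is.na(j)) stop("unknown SNP: ", snp)
  panel <- gt$snps
  tmp <- panel$major_allele[j]
  panel$major_allele[j] <- panel$minor_allele[j]
  panel$minor_allele[j] <- tmp
  codes <- gt$codes
  codes[, j] <- 4L - codes[, j]
  genotype_table(codes, snp_panel(panel$id, panel$major_allele,
                                  panel$minor_allele), gt$samples)
}
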