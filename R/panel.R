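#' Define a biallelic SNP panel
#'
#' A panel holds, per SNP, the identifier and the two allele symbols. The
#' major/minor assignment fixes the genotype coding used throughout the
#' package: `1` = homozygous major (reference), `2` = heterozygous,
#' `3` = homozygous minor. The minor allele is treated as the risk factor by
#' every genetic-model encoding.
#'
#' @param id Character vector of SNP identifiers (non-empty, unique).
#' @param major_allele,minor_allele Character vectors of allele symbols;
#'   `major_allele[i] != minor_allele[i]` for every SNP.
#' @return A tibble of class `snp_panel` with columns `id`, `major_allele`,
#'   `minor_allele`.
#' @examples
#' snp_panel("rs2276109", "A", "G")
#' @export
snp_panel <- function(id, major_allele, minor_allele) {
  id <- as.character(id)
  major_allele <- as.character(major_allele)
  minor_allele <- as.character(minor_allele)
  stopifnot(length(id) == length(major_allele),
            length(id) == length(minor_allele))
  if (any(!nzchar(id))) stop("SNP ids must be non-empty strings")
  if (anyDuplicated(id)) stop("duplicate SNP ids in panel")
  if (any(major_allele == minor_allele))
    stop("major and minor allele must differ for every SNP")
  out <- tibble::tibble(id = id, major_allele = major_allele,
                        minor_allele = minor_allele)
  class(out) <- c("snp_panel", class(out))
  out
}

#' The three-MMP ACL injury panel
#'
#' The default panel of the package: the MMP1 promoter insertion/deletion
#' rs1799750 (major D = deletion carrier reference per the study coding,
#' minor I), the MMP10 coding variant rs486055 (C/T) and the MMP12 promoter
#' variant rs2276109 (A/G).
#'
#' @return An [snp_panel()] with three SNPs.
#' @export
mmp_panel <- function() {
  snp_panel(id = c("rs1799750", "rs486055", "rs2276109"),
            major_allele = c("D", "C", "A"),
            minor_allele = c("I", "T", "G"))
}

as_panel <- function(x) {
  if (inherits(x, "snp_panel")) return(x)
  if (is.data.frame(x) &&
      all(c("id", "major_allele", "minor_allele") %in% names(x)))
    return(snp_panel(x$id, x$major_allele, x$minor_allele))
  stop("not an snp_panel")
}
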