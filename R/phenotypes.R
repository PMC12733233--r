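SUBTYPE_COLS <- c("aclf", "acls", "aclrp", "aclrc")

#' Construct a phenotype table
#'
#' Holds case/control status, the optional binary injury sub-phenotypes of
#' the case group, and the demographic covariates. Sub-phenotypes are defined
#' for cases only: `aclf` codes injury frequency (0 single, 1 multiple) and
#' `acls`/`aclrp`/`aclrc` code strain, partial rupture and complete rupture
#' (0 no, 1 yes). Controls must carry no sub-phenotype label because, by
#' design, they have no previous ACL injury.
#'
#' @param data A data frame with columns `sample`, `status` (0 control /
#'   1 case) and optionally `aclf`, `acls`, `aclrp`, `aclrc`, `age`
#'   (years), `body_mass` (kg), plus any extra covariates.
#' @return A tibble of class `phenotype_table`.
#' @export
phenotype_table <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("sample", "status") %in% names(data)))
    stop("phenotype data needs 'sample' and 'status' columns")
  data$sample <- as.character(data$sample)
  if (anyDuplicated(data$sample))
    stop("duplicate sample ids in phenotype table")
  st <- data$status
  if (any(is.na(st)) || !all(st %in% c(0, 1)))
    stop("status must be 0 (control) or 1 (case) with no missing values")
  data$status <- as.integer(st)
  for (col in intersect(SUBTYPE_COLS, names(data))) {
    v <- data[[col]]
    if (all(is.na(v))) { data[[col]] <- NULL; next }  # empty column = absent
    if (!all(v %in% c(0, 1, NA)))
      stop("sub-phenotype ", col, " must be binary 0/1")
    if (any(!is.na(v) & data$status == 0))
      stop("sub-phenotype ", col, " labelled on a control sample; ",
           "sub-phenotypes are defined for cases only")
    data[[col]] <- as.integer(v)
  }
  for (col in intersect(c("age", "body_mass"), names(data)))
    data[[col]] <- as.numeric(data[[col]])
  class(data) <- c("phenotype_table", class(data))
  data
}

#' Read a phenotype table from delimited text
#'
#' @param path File with a header declaring `sample`, `status` and optional
#'   sub-phenotype/covariate columns.
#' @param sep Field separator; `NULL` sniffs comma vs. tab.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  phenotype_table(df)
}

#' Write a phenotype table as delimited text
#' @param pt A [phenotype_table()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_phenotypes <- function(pt, path, sep = ",") {
  write.table(as.data.frame(pt), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
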