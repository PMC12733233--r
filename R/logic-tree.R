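#' Dummy-encode a genotype table for logic regression
#'
#' Each SNP becomes two binary columns: `<snp>_1` = carries at least one
#' minor allele (codes 2 or 3), `<snp>_2` = homozygous minor (code 3), so
#' genotype codes map as 1 -> (0,0), 2 -> (1,0), 3 -> (1,1). The encoding is
#' a bijection: [decode_binarized()] restores the codes. Samples with any
#' missing genotype are dropped (their indices are kept in the `"dropped"`
#' attribute).
#'
#' @param x A [genotype_table()] or an integer code matrix with SNP column
#'   names.
#' @return Integer 0/1 matrix with `2 * n_snps` columns.
#' @export
binarize <- function(x) {
  codes <- if (inherits(x, "genotype_table")) x$codes else as.matrix(x)
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("SNP", seq_len(ncol(codes)))
  if (any(!is.na(codes) & !(codes %in% 1:3)))
    stop("genotype codes must be 1, 2, 3 or NA")
  keep <- complete.cases(codes)
  dropped <- which(!keep)
  codes <- codes[keep, , drop = FALSE]
  out <- matrix(0L, nrow = nrow(codes), ncol = 2L * ncol(codes))
  colnames(out) <- as.vector(rbind(paste0(colnames(codes), "_1"),
                                   paste0(colnames(codes), "_2")))
  for (j in seq_len(ncol(codes))) {
    out[, 2L * j - 1L] <- as.integer(codes[, j] >= 2L)
    out[, 2L * j] <- as.integer(codes[, j] == 3L)
  }
  rownames(out) <- rownames(codes)
  attr(out, "dropped") <- dropped
  out
}

#' Decode a dummy-encoded matrix back to genotype codes
#' @param b Matrix produced by [binarize()].
#' @return Integer code matrix (values 1/2/3).
#' @export
decode_binarized <- function(b) {
  stopifnot(ncol(b) %% 2 == 0)
  j1 <- seq(1, ncol(b), by = 2)
  codes <- 1L + b[, j1, drop = FALSE] + b[, j1 + 1, drop = FALSE]
  storage.mode(codes) <- "integer"
  colnames(codes) <- sub("_1$", "", colnames(b)[j1])
  codes
}

#' Build logic-tree nodes
#'
#' Constructors for the Boolean trees evaluated by [evaluate_tree()]: a leaf
#' references a binary variable (optionally complemented); internal nodes
#' combine two subtrees with AND or OR.
#'
#' @param var Column name (or index) of the binary design matrix.
#' @param neg Complement the leaf?
#' @param left,right Subtrees.
#' @return A nested list of class `logic_tree`.
#' @export
lt_leaf <- function(var, neg = FALSE) {
  structure(list(op = "leaf", var = var, neg = isTRUE(neg)),
            class = "logic_tree")
}

#' @rdname lt_leaf
#' @export
lt_and <- function(left, right) {
  structure(list(op = "and", left = left, right = right),
            class = "logic_tree")
}

#' @rdname lt_leaf
#' @export
lt_or <- function(left, right) {
  structure(list(op = "or", left = left, right = right),
            class = "logic_tree")
}

#' Evaluate a logic tree on binary rows
#'
#' @param tree A `logic_tree`.
#' @param X Binary (0/1 or logical) matrix or data frame whose columns cover
#'   every leaf variable of the tree.
#' @return Logical vector, one value per row of `X`.
#' @export
evaluate_tree <- function(tree, X) {
  X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  switch(tree$op,
    leaf = {
      v <- tree$var
      if (is.character(v) && !(v %in% colnames(X)))
        stop("unknown variable in tree: ", v)
      col <- as.logical(X[, v])
      if (tree$neg) !col else col
    },
    and = evaluate_tree(tree$left, X) & evaluate_tree(tree$right, X),
    or  = evaluate_tree(tree$left, X) | evaluate_tree(tree$right, X),
    stop("invalid tree node"))
}

#' @export
print.logic_tree <- function(x, ...) {
  cat(deparse_tree(x), "\n")
  invisible(x)
}

deparse_tree <- function(tree) {
  switch(tree$op,
    leaf = paste0(if (tree$neg) "!" else "", tree$var),
    and = paste0("(", deparse_tree(tree$left), " & ",
                 deparse_tree(tree$right), ")"),
    or = paste0("(", deparse_tree(tree$left), " | ",
                deparse_tree(tree$right), ")"))
}

tree_vars <- function(tree) {
  if (tree$op == "leaf") return(as.character(tree$var))
  sort(unique(c(tree_vars(tree$left), tree_vars(tree$right))))
}

tree_n_leaves <- function(tree) {
  if (tree$op == "leaf") return(1L)
  tree_n_leaves(tree$left) + tree_n_leaves(tree$right)
}

# convert the flat node matrix returned by the C++ search to a logic_tree
tree_from_nodes <- function(nodes, root, var_names) {
  build <- function(i) {
    if (nodes[i, "op"] == 0L)
      lt_leaf(var_names[nodes[i, "var"]], neg = nodes[i, "neg"] == 1L)
    else if (nodes[i, "op"] == 1L)
      lt_and(build(nodes[i, "left"]), build(nodes[i, "right"]))
    else
      lt_or(build(nodes[i, "left"]), build(nodes[i, "right"]))
  }
  build(root)
}

#' Prime-implicant interactions of a logic tree
#'
#' Converts the tree's Boolean function into its set of prime implicants
#' (minimal conjunctions of literals whose disjunction equals the function)
#' via Quine-McCluskey minimisation of the truth table over the variables
#' appearing in the tree. Each implicant is the "interaction" unit of the
#' bagged importance measures, labelled canonically, e.g.
#' `"rs1799750_2 & !rs2276109_1"`.
#'
#' @param tree A `logic_tree`.
#' @param complement Extract the implicants of the complemented function
#'   (used to canonicalise fitted trees so that TRUE always marks the
#'   risk group: a tree and its De Morgan complement describe the same
#'   classifier with opposite orientation).
#' @return A list of implicants; each is a named integer vector (1 = plain
#'   literal, 0 = complemented) with a `label` attribute. A constant tree
#'   yields an empty list.
#' @export
extract_interactions <- function(tree, complement = FALSE) {
  vars <- tree_vars(tree)
  k <- length(vars)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(grid) <- vars
  val <- evaluate_tree(tree, grid)
  if (complement) val <- !val
  if (all(val) || !any(val)) return(list())
  primes <- qm_primes(grid[val, , drop = FALSE])
  lapply(seq_len(nrow(primes)), function(i) {
    row <- primes[i, ]
    lit <- row[!is.na(row)]
    attr(lit, "label") <- paste0(ifelse(lit == 1, "", "!"), names(lit),
                                 collapse = " & ")
    lit
  })
}

# Quine-McCluskey prime implicants; minterms = 0/1 matrix (rows = minterms),
# don't-cares represented as NA during merging
qm_primes <- function(minterms) {
  imps <- unique(minterms)
  key <- function(m) apply(m, 1, paste, collapse = ".")
  primes <- NULL
  repeat {
    n <- nrow(imps)
    used <- rep(FALSE, n)
    merged <- list()
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- imps[i, ]; b <- imps[j, ]
          if (!identical(is.na(a), is.na(b))) next
          diff <- which(!is.na(a) & a != b)
          if (length(diff) == 1) {
            m <- a; m[diff] <- NA
            merged[[length(merged) + 1]] <- m
            used[i] <- TRUE; used[j] <- TRUE
          }
        }
      }
    }
    primes <- rbind(primes, imps[!used, , drop = FALSE])
    if (length(merged) == 0) break
    imps <- unique(do.call(rbind, merged))
  }
  unique(primes)
}

interaction_label <- function(imp) attr(imp, "label")

# DNF model prediction: TRUE iff any implicant is satisfied
eval_implicants <- function(implicants, X) {
  X <- as.matrix(X)
  if (length(implicants) == 0) return(rep(FALSE, nrow(X)))
  sat <- vapply(implicants, function(imp) {
    hit <- rep(TRUE, nrow(X))
    for (v in names(imp))
      hit <- hit & (as.logical(X[, v]) == (imp[[v]] == 1))
    hit
  }, logical(nrow(X)))
  if (nrow(X) == 1) return(any(sat))
  rowSums(matrix(sat, nrow = nrow(X))) > 0
}
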