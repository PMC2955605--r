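#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns; row names carry the gene identifiers. This constructor
#' only validates and normalises its input — downstream functions accept any
#' matrix that satisfies the same invariants.
#'
#' @param values Numeric matrix, n genes x m samples, all values finite.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to the row names of `values`.
#' @return The validated numeric matrix with `gene_ids` as row names.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4), gene_ids = c("a", "b", "c"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix (genes x samples)")
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("G", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids),
         ") does not match the number of rows (", nrow(values), ")")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  if (nrow(values) < 2L) stop("need at least 2 genes")
  if (ncol(values) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  rownames(values) <- gene_ids
  values
}

# Internal: check an expression matrix without rebuilding it.
check_expression <- function(expr) {
  expression_matrix(expr)
  invisible(expr)
}

# Internal: validate that a matrix is square/symmetric with matching ids.
check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix")
  }
  invisible(m)
}
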