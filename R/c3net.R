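#' Per-gene maximum-MI partner selection
#'
#' For every gene i with a nonempty significant neighborhood
#' N(i) = \{j : C_ij = 1, j != i\}, selects the neighbor with the maximal
#' mutual information, j_c(i) = argmax over N(i) of I_ij. This is the
#' maximization step that makes the inference conservative: each gene may
#' contribute at most the single edge to its strongest significant partner.
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @param conn Binary connectivity matrix from [threshold_connectivity()],
#'   same shape and gene ids as `mi`.
#' @return Integer vector of partner indices (1-based), `NA` for genes with an
#'   empty neighborhood; named by gene id when `mi` has dimnames. Ties are
#'   broken toward the smallest gene index.
#' @export
select_partners <- function(mi, conn) {
  check_square(mi, "MI matrix")
  check_square(conn, "connectivity matrix")
  if (!identical(dim(mi), dim(conn))) {
    stop("MI and connectivity matrices must have identical dimensions")
  }
  if (!is.null(dimnames(mi)) && !is.null(dimnames(conn)) &&
      !identical(rownames(mi), rownames(conn))) {
    stop("gene ids of MI and connectivity matrices disagree")
  }
  n <- nrow(mi)
  partners <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ns <- which(conn[i, ] != 0)
    ns <- ns[ns != i]
    if (length(ns)) partners[i] <- ns[which.max(mi[i, ns])]
  }
  names(partners) <- rownames(mi)
  partners
}

#' Directed partner matrix (one edge per selecting gene)
#'
#' The asymmetric intermediate in which row i carries a single 1 at column
#' j_c(i): exactly the edges "claimed" by each gene before symmetrization.
#' Useful as a diagnostic of which endpoint selected each edge.
#'
#' @param partners Integer partner vector from [select_partners()].
#' @param n Number of genes (defaults to `length(partners)`).
#' @return n x n 0/1 integer matrix.
#' @export
partner_matrix <- function(partners, n = length(partners)) {
  if (length(partners) != n) stop("partner vector length must equal n")
  ok <- !is.na(partners)
  if (any(partners[ok] < 1 | partners[ok] > n | partners[ok] == which(ok))) {
    stop("partner indices must be in 1..n and never the gene itself")
  }
  aj <- matrix(0L, n, n)
  aj[cbind(which(ok), partners[ok])] <- 1L
  if (!is.null(names(partners))) {
    dimnames(aj) <- list(names(partners), names(partners))
  }
  aj
}

#' Symmetric adjacency from a partner vector
#'
#' Sets A_ij = A_ji = 1 for every gene i with selected partner j — the
#' symmetrization of the directed partner matrix. Because several genes may
#' select the same partner, the undirected network can contain hubs even
#' though each gene adds at most one edge; the edge count never exceeds the
#' number of genes.
#'
#' @inheritParams partner_matrix
#' @return Symmetric n x n 0/1 integer adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(partners, n = length(partners)) {
  aj <- partner_matrix(partners, n)
  a <- (aj | t(aj)) * 1L
  storage.mode(a) <- "integer"
  dimnames(a) <- dimnames(aj)
  a
}

#' Conservative-core network from an MI matrix and a threshold
#'
#' Thresholds the MI matrix into a connectivity matrix, selects each gene's
#' maximum-MI significant partner and symmetrizes into the final undirected
#' adjacency.
#'
#' @inheritParams select_partners
#' @param threshold Significance cut-off on the MI values.
#' @return Symmetric 0/1 adjacency matrix with attribute `partners` (the
#'   partner vector) retained for diagnostics.
#' @examples
#' mi <- rbind(c(0, .7, .9, .8), c(.7, 0, .6, .5),
#'             c(.9, .6, 0, .1), c(.8, .5, .1, 0))
#' c3net(mi, threshold = 0.55)  # star centered on gene 1
#' @export
c3net <- function(mi, threshold) {
  conn <- threshold_connectivity(mi, threshold)
  partners <- select_partners(mi, conn)
  a <- build_adjacency(partners)
  attr(a, "partners") <- partners
  a
}

# Internal: fast vectorized c3net used inside optimal-cutoff scans.
# Identical output to c3net(); max.col(ties.method = "first") reproduces the
# smallest-index tie-break.
c3net_fast <- function(mi, threshold) {
  n <- nrow(mi)
  w <- mi
  w[w <= threshold] <- 0
  diag(w) <- 0
  j <- max.col(w, ties.method = "first")
  ok <- w[cbind(seq_len(n), j)] > 0
  a <- matrix(0L, n, n)
  if (any(ok)) {
    idx <- cbind(which(ok), j[ok])
    a[idx] <- 1L
    a[idx[, 2:1, drop = FALSE]] <- 1L
  }
  dimnames(a) <- dimnames(mi)
  a
}

#' Full conservative-core inference pipeline
#'
#' End-to-end inference from raw expression data: estimate the pairwise MI
#' matrix, build the pooled permutation null, threshold at the empirical
#' (1 - alpha) quantile, then apply the per-gene maximization step. The
#' returned network has at most as many edges as genes.
#'
#' @param expr Numeric expression matrix, genes x samples.
#' @param estimator,bins,order,copula Passed to [mi_matrix()].
#' @param alpha Significance level for the permutation test.
#' @param n_permutations Permutation rounds for the null.
#' @param rng_seed Seed for the permutation null.
#' @return Symmetric 0/1 adjacency matrix with attributes `partners`,
#'   `threshold` and `mi` (the estimated MI matrix).
#' @export
c3net_infer <- function(expr, estimator = c("gaussian", "bspline"),
                        alpha = 0.05, n_permutations = 100L, rng_seed = NULL,
                        bins = 10L, order = 3L, copula = NULL) {
  estimator <- match.arg(estimator)
  expr <- expression_matrix(expr)
  mi <- mi_matrix(expr, estimator, bins = bins, order = order, copula = copula)
  nm <- build_null(expr, estimator, n_permutations = n_permutations,
                   alpha = alpha, rng_seed = rng_seed,
                   bins = bins, order = order, copula = copula)
  a <- c3net(mi, nm$threshold)
  attr(a, "threshold") <- nm$threshold
  attr(a, "mi") <- mi
  a
}

#' Edge list view of an adjacency matrix
#'
#' @param adj Symmetric adjacency (0/1 or weighted); only the upper triangle
#'   is consulted.
#' @param weights Optional symmetric score matrix; adds a `weight` column.
#' @return Data frame with columns `gene_a`, `gene_b` (and `weight`), one row
#'   per unordered pair, in lexicographic order of the pair labels.
#' @export
as_edge_list <- function(adj, weights = NULL) {
  check_square(adj, "adjacency")
  ids <- rownames(adj)
  if (is.null(ids)) ids <- paste0("G", seq_len(nrow(adj)))
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  a <- pmin(ids[idx[, 1]], ids[idx[, 2]])
  b <- pmax(ids[idx[, 1]], ids[idx[, 2]])
  out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  if (!is.null(weights)) out$weight <- weights[idx]
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
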