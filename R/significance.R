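#' Pooled permutation null model for mutual information
#'
#' Builds the null distribution of pairwise MI under independence by
#' repeatedly shuffling every gene's samples independently (destroying all
#' between-gene dependence while keeping each marginal) and pooling the
#' pairwise MI values of all shuffled rounds. A single matrix-wide
#' significance threshold is the empirical (1 - alpha) quantile of the pooled
#' null.
#'
#' @param expr Numeric expression matrix, genes x samples.
#' @param estimator,bins,order,copula Passed to [mi_matrix()].
#' @param n_permutations Number of full-matrix shuffling rounds (default 100;
#'   each round contributes n(n-1)/2 pooled values).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param rng_seed Integer seed making the null reproducible; `NULL` uses the
#'   current RNG state.
#' @param bonferroni If `TRUE`, the quantile is taken at
#'   `1 - alpha / (n(n-1)/2)` instead (a Bonferroni-style correction over all
#'   gene pairs); off by default, matching the single-threshold usage.
#' @return An object of class `mi_null` with elements `null_values` (sorted),
#'   `n_permutations`, `alpha` and `threshold` — the cut-off I0 to be passed
#'   to [threshold_connectivity()].
#' @examples
#' x <- expression_matrix(matrix(rnorm(100), 5, 20))
#' nm <- build_null(x, n_permutations = 20, rng_seed = 1)
#' nm$threshold
#' @export
build_null <- function(expr, estimator = c("gaussian", "bspline"),
                       n_permutations = 100L, alpha = 0.05, rng_seed = NULL,
                       bins = 10L, order = 3L, copula = NULL,
                       bonferroni = FALSE) {
  estimator <- match.arg(estimator)
  expr <- expression_matrix(expr)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(expr)
  m <- ncol(expr)
  up <- upper.tri(matrix(0, n, n))
  null_values <- vector("list", n_permutations)
  for (k in seq_len(n_permutations)) {
    perm <- expr
    for (i in seq_len(n)) perm[i, ] <- perm[i, sample.int(m)]
    mi <- suppressWarnings(
      mi_matrix(perm, estimator, bins = bins, order = order, copula = copula))
    null_values[[k]] <- mi[up]
  }
  null_values <- sort(unlist(null_values))
  a_eff <- if (bonferroni) alpha / (n * (n - 1) / 2) else alpha
  structure(
    list(null_values = null_values,
         n_permutations = as.integer(n_permutations),
         alpha = alpha,
         threshold = empirical_quantile(null_values, 1 - a_eff)),
    class = "mi_null")
}

# Internal: type-1 (inverse-ECDF) empirical quantile of a sorted vector —
# the ceiling(N * p)-th order statistic.
empirical_quantile <- function(sorted_values, p) {
  n <- length(sorted_values)
  sorted_values[max(1L, ceiling(n * p))]
}

#' @export
print.mi_null <- function(x, ...) {
  cat("Pooled permutation null:", length(x$null_values), "values from",
      x$n_permutations, "rounds\n")
  cat("alpha =", x$alpha, "  threshold I0 =", format(x$threshold), "\n")
  invisible(x)
}

#' Binary connectivity matrix from an MI matrix and a threshold
#'
#' Marks a gene pair as connected when its mutual information strictly
#' exceeds the significance threshold; ties at the threshold are treated as
#' non-significant. The result is the connectivity matrix C whose rows define
#' each gene's significant neighborhood.
#'
#' @param mi Symmetric MI (or score) matrix with zero diagonal.
#' @param threshold Nonnegative cut-off.
#' @return Symmetric 0/1 integer matrix with zero diagonal and the same
#'   dimnames as `mi`.
#' @export
threshold_connectivity <- function(mi, threshold) {
  check_square(mi, "MI matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single nonnegative number")
  }
  conn <- (mi > threshold) * 1L
  diag(conn) <- 0L
  storage.mode(conn) <- "integer"
  dimnames(conn) <- dimnames(mi)
  conn
}
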