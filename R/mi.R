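#' Copula-transform an expression matrix
#'
#' Replaces every gene's expression profile by its empirical copula values
#' rank/(m+1), with average ranks for ties, mapping each row into the open
#' interval (0, 1) while preserving rank order. After this transform the
#' Gaussian mutual information estimator depends on the dependence structure
#' only, making it invariant under strictly monotone per-gene transformations
#' of the raw data.
#'
#' @param expr Numeric matrix, genes x samples (see [expression_matrix()]).
#' @return Matrix of the same shape with values in (0, 1).
#' @details A constant gene row has all samples tied, so every entry maps to
#'   0.5; such rows are flagged with a warning because they carry no
#'   dependence information.
#' @examples
#' copula_transform(rbind(a = c(0.2, 3.5, 1.1), b = c(1, 2, 3)))
#' @export
copula_transform <- function(expr) {
  expr <- expression_matrix(expr)
  m <- ncol(expr)
  flat <- apply(expr, 1L, function(r) max(r) == min(r))
  if (any(flat)) {
    warning("constant gene row(s) mapped to 0.5: ",
            paste(rownames(expr)[flat], collapse = ", "))
  }
  out <- t(apply(expr, 1L, rank, ties.method = "average")) / (m + 1)
  dimnames(out) <- dimnames(expr)
  out
}

#' Gaussian mutual information between two profiles
#'
#' Parametric estimator of the mutual information of two real-valued vectors
#' under a bivariate Gaussian model,
#' \deqn{I(X,Y) = \tfrac12 \log\!\big(\sigma_X^2 \sigma_Y^2 / |C|\big)
#'             = -\tfrac12 \log(1 - \rho^2),}
#' where \eqn{|C|} is the determinant of the 2x2 sample covariance matrix and
#' \eqn{\rho} the sample correlation. Returned in nats.
#'
#' @param x,y Numeric vectors of equal length (at least 3), all finite.
#' @return Nonnegative mutual information in nats.
#' @examples
#' gaussian_mi(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho = 0.8 -> -0.5*log(0.36)
#' @export
gaussian_mi <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance input: mutual information undefined")
  }
  r <- stats::cor(x, y)
  if (1 - r^2 <= .Machine$double.eps) {
    stop("singular covariance (|rho| = 1): perfect dependence")
  }
  max(0, -0.5 * log(1 - r^2))
}

# Internal: B-spline membership weights of samples over `bins` bins.
# Knot convention: uniform augmented knots on [0, bins - order + 1] after
# min-max scaling of x, so the basis at each sample sums to 1. order = 1
# reduces to the indicator basis of a hard equal-width histogram.
bspline_weights <- function(x, bins, order) {
  m <- length(x)
  rng <- range(x)
  top <- bins - order + 1
  if (rng[2] > rng[1]) {
    z <- (x - rng[1]) / (rng[2] - rng[1]) * top
  } else {
    z <- rep(0, m)  # constant input: all mass in the first bin
  }
  # keep the right boundary sample inside the last half-open knot interval
  z <- pmin(z, top * (1 - 1e-12))
  knots <- c(rep(0, order), seq_len(max(top - 1, 0)), rep(top, order))
  w <- splines::splineDesign(knots, z, ord = order)
  stopifnot(ncol(w) == bins)
  w
}

#' B-spline mutual information between two profiles
#'
#' Fuzzy-membership histogram estimator: each sample is spread over `bins`
#' bins per variable with B-spline basis weights; marginal and joint
#' probabilities are the average weights and average outer products, and the
#' mutual information is the usual discrete sum over these probabilities.
#' With `order = 1` the basis degenerates to bin indicators and the estimator
#' equals plain equal-width histogram MI. Returned in bits (log base 2).
#'
#' @param x,y Numeric vectors of equal length, all finite.
#' @param bins Number of bins (default 10).
#' @param order Spline order (1 = piecewise constant, 3 = quadratic; default 3).
#' @return Nonnegative mutual information in bits.
#' @export
bspline_mi <- function(x, y, bins = 10L, order = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (order < 1L || bins < order) stop("need bins >= order >= 1")
  if (length(x) < bins) stop("need at least `bins` samples")
  wx <- bspline_weights(x, bins, order)
  wy <- bspline_weights(y, bins, order)
  m <- length(x)
  px <- colMeans(wx)
  py <- colMeans(wy)
  pxy <- crossprod(wx, wy) / m
  pos <- pxy > 0
  max(0, sum(pxy[pos] * log2(pxy[pos] / outer(px, py)[pos])))
}

#' Pairwise mutual information matrix
#'
#' Estimates mutual information for every gene pair of an expression matrix.
#' The Gaussian estimator is, by default, applied to copula-transformed data
#' (the standard pipeline); the B-spline estimator bins raw values. The
#' diagonal is stored as 0 by convention — self-pairs are excluded from every
#' downstream neighborhood.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param estimator `"gaussian"` (nats) or `"bspline"` (bits).
#' @param bins,order B-spline estimator parameters.
#' @param copula Apply [copula_transform()] first? Defaults to `TRUE` for the
#'   Gaussian estimator and `FALSE` for the B-spline estimator.
#' @return Symmetric n x n matrix with zero diagonal, gene ids as dimnames and
#'   an attribute `units` ("nats" or "bits"). Degenerate pairs (constant
#'   profiles or perfectly dependent pairs, for which the Gaussian estimator
#'   is undefined) are reported as 0 with a warning rather than aborting the
#'   whole matrix.
#' @examples
#' x <- expression_matrix(matrix(rnorm(40), 4, 10))
#' mi_matrix(x)
#' @export
mi_matrix <- function(expr, estimator = c("gaussian", "bspline"),
                      bins = 10L, order = 3L, copula = NULL) {
  estimator <- match.arg(estimator)
  expr <- expression_matrix(expr)
  if (is.null(copula)) copula <- estimator == "gaussian"
  n <- nrow(expr)
  if (copula) expr <- suppressWarnings(copula_transform(expr))

  if (estimator == "gaussian") {
    sds <- apply(expr, 1L, stats::sd)
    r <- suppressWarnings(stats::cor(t(expr)))
    r[!is.finite(r)] <- 0
    bad <- outer(sds == 0, sds == 0, "|")         # flat profile(s)
    sing <- !bad & (1 - r^2 <= .Machine$double.eps)  # perfect dependence
    diag(sing) <- FALSE
    mi <- -0.5 * log(pmax(1 - r^2, .Machine$double.xmin))
    mi[bad | sing] <- 0
    if (any(bad[upper.tri(bad)])) {
      warning("constant gene profile(s): affected pairs reported as MI 0")
    }
    if (any(sing[upper.tri(sing)])) {
      warning("perfectly dependent gene pair(s): reported as MI 0")
    }
    units <- "nats"
  } else {
    mi <- matrix(0, n, n)
    warn <- character(0)
    w <- vector("list", n)
    for (i in seq_len(n)) {
      w[[i]] <- tryCatch(bspline_weights(expr[i, ], bins, order),
                         error = function(e) NULL)
    }
    m <- ncol(expr)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- tryCatch({
          if (is.null(w[[i]]) || is.null(w[[j]])) stop("degenerate profile")
          px <- colMeans(w[[i]]); py <- colMeans(w[[j]])
          pxy <- crossprod(w[[i]], w[[j]]) / m
          pos <- pxy > 0
          max(0, sum(pxy[pos] * log2(pxy[pos] / outer(px, py)[pos])))
        }, error = function(e) {
          warn <<- c(warn, paste0(rownames(expr)[i], "-", rownames(expr)[j]))
          0
        })
        mi[i, j] <- mi[j, i] <- v
      }
    }
    if (length(warn)) {
      warning("degenerate pair(s) reported as MI 0: ",
              paste(warn, collapse = ", "))
    }
    units <- "bits"
  }
  diag(mi) <- 0
  mi <- pmax(mi, 0)
  dimnames(mi) <- list(rownames(expr), rownames(expr))
  attr(mi, "units") <- units
  mi
}
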