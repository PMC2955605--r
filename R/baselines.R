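#' Relevance network
#'
#' The classical baseline: keep every gene pair whose mutual information
#' exceeds the significance threshold. Identical to
#' [threshold_connectivity()] viewed as a network; every other method in this
#' package infers a subset of these edges or rescoring of them.
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @param threshold Significance cut-off.
#' @return Symmetric 0/1 adjacency matrix.
#' @export
rn <- function(mi, threshold) {
  threshold_connectivity(mi, threshold)
}

#' ARACNE: relevance network pruned by the data processing inequality
#'
#' Starts from the relevance network and removes, within every fully
#' connected triplet (i, j, k), the weakest edge: (i, j) is marked for
#' removal when \eqn{I_{ij} < (1 - \epsilon)\,\min(I_{ik}, I_{jk})}. The DPI
#' states that for a Markov chain i -> k -> j the direct information
#' I_ij cannot exceed either link through k, so such edges are likely
#' indirect. The tolerance `eps` relaxes the comparison multiplicatively.
#' All removals are computed on the original matrix and applied
#' simultaneously, so triplet scan order cannot change the result.
#'
#' @inheritParams rn
#' @param eps DPI tolerance in \[0, 1); 0 is the strict inequality, values
#'   near 1 disable pruning. Default 0.1 (the value customarily used for
#'   benchmarking).
#' @return Symmetric 0/1 adjacency matrix, always a subset of `rn(mi,
#'   threshold)`.
#' @export
aracne <- function(mi, threshold, eps = 0.1) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  adj <- rn(mi, threshold)
  n <- nrow(adj)
  w <- mi * adj          # 0 where no significant edge
  # cap[i, j] = max over k of min(w[i, k], w[j, k]); third vertices that do
  # not close a triangle contribute 0 and can never trigger a removal
  cap <- matrix(0, n, n)
  for (k in which(colSums(w > 0) >= 2L)) {  # k must close a triangle
    cap <- pmax(cap, outer(w[, k], w[, k], pmin))
  }
  drop <- adj == 1L & mi < (1 - eps) * cap
  adj[drop] <- 0L
  adj
}

#' CLR: context likelihood of relatedness scores
#'
#' Background-corrects each MI value against the distributions of the two
#' genes it involves: with row mean \eqn{\mu_i} and standard deviation
#' \eqn{\sigma_i} over gene i's off-diagonal MI values, the rectified
#' z-score is \eqn{z_i(j) = \max(0, (I_{ij} - \mu_i)/\sigma_i)} and the edge
#' weight is \eqn{\sqrt{z_i(j)^2 + z_j(i)^2}}. A network is obtained by
#' thresholding the weights.
#'
#' @param mi Symmetric MI matrix with zero diagonal, at least 3 genes.
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
clr <- function(mi) {
  check_square(mi, "MI matrix")
  n <- nrow(mi)
  if (n < 3L) stop("CLR needs at least 3 genes for row statistics")
  mu <- rowSums(mi) / (n - 1)   # diagonal is stored as 0
  sg <- vapply(seq_len(n), function(i) stats::sd(mi[i, -i]), numeric(1))
  if (any(sg == 0)) {
    warning("gene row(s) with zero MI spread contribute zero z-scores")
  }
  z <- (mi - mu) / ifelse(sg > 0, sg, Inf)
  z[z < 0] <- 0
  w <- sqrt(z^2 + t(z)^2)
  diag(w) <- 0
  dimnames(w) <- dimnames(mi)
  w
}

#' MRNET: maximum relevance / minimum redundancy network scores
#'
#' For every target gene, ranks candidate regulators by greedy forward
#' selection: at each step the candidate j maximizing
#' \eqn{s_j = I_{jt} - \mathrm{mean}_{k \in S} I_{jk}} (relevance to the
#' target minus average redundancy with the already-selected set S) is added,
#' and its score at selection time is recorded; selection stops when the best
#' score drops to zero or below. The undirected weight of a pair is the
#' larger of its two directed scores; a network is obtained by thresholding.
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
mrnet <- function(mi) {
  check_square(mi, "MI matrix")
  n <- nrow(mi)
  if (n < 2L) stop("need at least 2 genes")
  dscore <- matrix(0, n, n)  # dscore[j, t]: score of regulator j for target t
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(n), t)
    sel <- integer(0)
    while (length(cand)) {
      if (length(sel)) {
        red <- rowMeans(mi[cand, sel, drop = FALSE])
      } else {
        red <- 0
      }
      s <- mi[cand, t] - red
      best <- which.max(s)            # ties -> smallest index (cand sorted)
      if (s[best] <= 0) break
      dscore[cand[best], t] <- s[best]
      sel <- c(sel, cand[best])
      cand <- cand[-best]
    }
  }
  w <- pmax(dscore, t(dscore))
  diag(w) <- 0
  dimnames(w) <- dimnames(mi)
  w
}
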