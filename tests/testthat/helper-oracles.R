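# Strip dimnames and diagnostic attributes, keeping only the matrix shape.
bare <- function(m) matrix(as.integer(m), nrow(m), ncol(m))

# Independent brute-force oracles, written as literal transcriptions of the
# definitions, deliberately sharing no code with the package internals.

# Maximization-step inference: per gene, scan its significant row by hand.
brute_c3net <- function(mi, conn) {
  n <- nrow(mi)
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    best <- NA_integer_
    best_v <- -Inf
    for (j in seq_len(n)) {
      if (j != i && conn[i, j] == 1 && mi[i, j] > best_v) {
        best <- j
        best_v <- mi[i, j]
      }
    }
    if (!is.na(best)) a[i, best] <- a[best, i] <- 1L
  }
  a
}

# DPI pruning: enumerate every triplet explicitly; simultaneous removal.
brute_aracne <- function(mi, threshold, eps = 0.1) {
  n <- nrow(mi)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && mi[i, j] > threshold) adj[i, j] <- 1L
  }
  drop <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && k != i && k != j &&
        adj[i, j] == 1 && adj[i, k] == 1 && adj[j, k] == 1 &&
        mi[i, j] < (1 - eps) * min(mi[i, k], mi[j, k])) {
      drop[i, j] <- drop[j, i] <- TRUE
    }
  }
  adj[drop] <- 0L
  adj
}

# CLR weights recomputed cell by cell.
brute_clr <- function(mi) {
  n <- nrow(mi)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    zi <- (mi[i, j] - mean(mi[i, -i])) / stats::sd(mi[i, -i])
    zj <- (mi[j, i] - mean(mi[j, -j])) / stats::sd(mi[j, -j])
    w[i, j] <- sqrt(max(0, zi)^2 + max(0, zj)^2)
  }
  w
}

# MRNET greedy forward selection recomputed independently.
brute_mrnet <- function(mi) {
  n <- nrow(mi)
  d <- matrix(0, n, n)
  for (t in seq_len(n)) {
    sel <- c()
    repeat {
      cand <- setdiff(seq_len(n), c(t, sel))
      if (!length(cand)) break
      sc <- sapply(cand, function(j) {
        red <- if (length(sel)) mean(sapply(sel, function(k) mi[j, k])) else 0
        mi[j, t] - red
      })
      if (max(sc) <= 0) break
      pick <- cand[which.max(sc)]
      d[pick, t] <- max(sc)
      sel <- c(sel, pick)
    }
  }
  pmax(d, t(d))
}

# Pair-by-pair confusion counts.
brute_compare <- function(inferred, truth) {
  n <- nrow(inferred)
  tp <- fp <- fn <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- inferred[i, j] != 0 || inferred[j, i] != 0
    b <- truth[i, j] != 0 || truth[j, i] != 0
    if (a && b) tp <- tp + 1L
    if (a && !b) fp <- fp + 1L
    if (!a && b) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

brute_fscore <- function(inferred, truth) {
  ct <- brute_compare(inferred, truth)
  p <- if (ct$TP + ct$FP > 0) ct$TP / (ct$TP + ct$FP) else 0
  r <- if (ct$TP + ct$FN > 0) ct$TP / (ct$TP + ct$FN) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# Best F over every achievable strict-threshold network, by direct scan.
brute_best_fscore <- function(scores, truth) {
  vals <- unique(scores[upper.tri(scores)])
  vals <- vals[vals > 0]  # a strict nonnegative cut-off can never admit 0s
  nets <- lapply(vals, function(v) (scores >= v & upper.tri(scores)))
  best <- 0
  for (net in nets) {
    a <- (net | t(net)) * 1L
    best <- max(best, brute_fscore(a, truth))
  }
  best
}

# Plug-in equal-width histogram MI in bits.
brute_hist_mi <- function(x, y, bins) {
  cut_idx <- function(v) {
    br <- seq(min(v), max(v), length.out = bins + 1)
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), bins)
  }
  p <- table(factor(cut_idx(x), 1:bins), factor(cut_idx(y), 1:bins))
  p <- p / length(x)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in 1:bins) for (j in 1:bins) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}
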