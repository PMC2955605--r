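# Internal: symmetrize a possibly directed 0/1 adjacency.
symmetrize <- function(adj) {
  check_square(adj, "adjacency")
  a <- (adj | t(adj)) * 1L
  diag(a) <- 0L
  dimnames(a) <- dimnames(adj)
  a
}

# Internal: check two networks live on the same gene universe.
check_universe <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("networks have different gene universes (", nrow(a), " vs ",
         nrow(b), " genes)")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    off <- union(setdiff(rownames(a), rownames(b)),
                 setdiff(rownames(b), rownames(a)))
    if (length(off) == 0) off <- "same ids in different order"
    stop("gene universes disagree: ", paste(off, collapse = ", "))
  }
  invisible(NULL)
}

#' Compare an inferred network with a known true network
#'
#' Counts true positive, false positive and false negative undirected edges
#' and derives precision p = TP/(TP+FP), recall r = TP/(TP+FN) and the
#' F-score F = 2pr/(p+r). A directed truth is symmetrized first, since the
#' inferred networks carry no direction. An optional candidate mask restricts
#' scoring to a subset of gene pairs (e.g. regulator x target pairs);
#' inferred edges outside the mask are discarded before counting, not held
#' against the method.
#'
#' @param inferred,truth Symmetric 0/1 adjacency matrices on the same genes.
#' @param mask Optional logical (or 0/1) matrix of the same shape marking the
#'   scorable pairs; symmetrized internally.
#' @return List of class `grn_eval`: `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `fscore`. Undefined ratios (empty network or empty truth) are reported
#'   as 0.
#' @export
compare_networks <- function(inferred, truth, mask = NULL) {
  inferred <- symmetrize(inferred)
  truth <- symmetrize(truth)
  check_universe(inferred, truth)
  up <- upper.tri(inferred)
  if (!is.null(mask)) {
    check_universe(inferred, mask * 1L)
    mask <- (mask | t(mask))
    up <- up & mask
  }
  inf <- inferred[up] != 0
  tru <- truth[up] != 0
  tp <- sum(inf & tru)
  fp <- sum(inf & !tru)
  fn <- sum(!inf & tru)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(TP = tp, FP = fp, FN = fn,
                 precision = p, recall = r, fscore = f),
            class = "grn_eval")
}

#' @export
print.grn_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  precision %.4f  recall %.4f  F %.4f\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Optimal score cut-off by F-score maximization
#'
#' Scans candidate thresholds over the distinct off-diagonal score values
#' (plus one value above the maximum, i.e. the empty network) and returns the
#' threshold maximizing the F-score of the induced network against the truth.
#' This separates the quality of an inference *algorithm* from the choice of
#' significance level: each method is evaluated at its own best cut-off.
#' Ties in F are broken toward the smallest threshold (the densest network
#' among the maximizers).
#'
#' @param scores Symmetric score matrix (MI values or method-specific edge
#'   weights) with zero diagonal.
#' @param truth True network adjacency on the same genes.
#' @param infer Function `(scores, threshold) -> adjacency` mapping a cut-off
#'   to a network. The default keeps all edges above the threshold (the
#'   relevance-network rule); pass [c3net()] or a wrapped [aracne()] to tune
#'   those methods instead.
#' @param mask Optional candidate-pair mask, as in [compare_networks()].
#' @param max_candidates Cap on the number of thresholds scanned. When the
#'   distinct score values exceed it, an evenly spaced subset of the sorted
#'   distinct values is used. Default `Inf` (scan all).
#' @return List with elements `threshold`, `result` (the `grn_eval` at that
#'   threshold) and `n_candidates`.
#' @export
optimal_cutoff <- function(scores, truth, infer = threshold_connectivity,
                           mask = NULL, max_candidates = Inf) {
  check_square(scores, "score matrix")
  truth <- symmetrize(truth)
  check_universe(scores, truth)
  if (sum(truth) == 0) stop("truth network is empty: F-score undefined")
  vals <- sort(unique(scores[upper.tri(scores)]))
  if (length(vals) > max_candidates) {
    vals <- vals[unique(round(seq(1, length(vals),
                                  length.out = max_candidates)))]
  }
  # thresholding is by strict inequality, so a candidate equal to a score
  # value would exclude that edge; nudge below each distinct value so the
  # network at candidate k contains the edges scored >= vals[k], and add one
  # candidate above the maximum (the empty network)
  cand <- c(pmax(vals * (1 - 1e-9) - .Machine$double.xmin, 0),
            max(vals) + 1)
  best_f <- -1
  best_t <- cand[1]
  best_r <- NULL
  for (th in cand) {
    res <- compare_networks(infer(scores, th), truth, mask = mask)
    if (res$fscore > best_f) {
      best_f <- res$fscore
      best_t <- th
      best_r <- res
    }
  }
  list(threshold = best_t, result = best_r, n_candidates = length(cand))
}

#' Ensemble summary of F-scores
#'
#' The four summary statistics (max, min, mean, median) of the F-scores of an
#' ensemble of evaluations — the distribution view that a single data set
#' cannot provide.
#'
#' @param results Nonempty list of `grn_eval` objects, or a numeric vector of
#'   F-scores.
#' @return Named numeric vector `c(max, min, mean, median)`.
#' @export
ensemble_summary <- function(results) {
  if (length(results) == 0) stop("empty ensemble")
  f <- if (is.numeric(results)) results
       else vapply(results, function(r) r$fscore, numeric(1))
  c(max = max(f), min = min(f), mean = mean(f), median = stats::median(f))
}

#' Per-edge true positive rates over an ensemble
#'
#' For every edge of the true network, the fraction of ensemble networks that
#' recover it (its mean TPR), binned into the conventional four color
#' classes: black (0.75, 1], blue (0.5, 0.75], green (0.25, 0.5] and red
#' [0, 0.25]. Exposes which structural elements of the network are easy or
#' hard for a method — leaf edges versus collider edges, for instance.
#'
#' @param networks Nonempty list of inferred adjacency matrices on the
#'   truth's gene universe.
#' @param truth True network adjacency.
#' @return Data frame with one row per true edge: `gene_a`, `gene_b`, `tpr`,
#'   `color`.
#' @export
edge_tpr <- function(networks, truth) {
  if (length(networks) == 0) stop("empty ensemble")
  truth <- symmetrize(truth)
  edges <- which(upper.tri(truth) & truth != 0, arr.ind = TRUE)
  hits <- matrix(0, nrow(edges), length(networks))
  for (k in seq_along(networks)) {
    a <- symmetrize(networks[[k]])
    check_universe(a, truth)
    hits[, k] <- a[edges] != 0
  }
  tpr <- rowMeans(hits)
  ids <- rownames(truth)
  if (is.null(ids)) ids <- paste0("G", seq_len(nrow(truth)))
  data.frame(
    gene_a = ids[edges[, 1]],
    gene_b = ids[edges[, 2]],
    tpr = tpr,
    color = as.character(cut(tpr, breaks = c(0, 0.25, 0.5, 0.75, 1),
                             labels = c("red", "green", "blue", "black"),
                             include.lowest = TRUE)),
    stringsAsFactors = FALSE)
}

#' Mean score over the edges a method declared significant
#'
#' Averages the underlying score (MI value, z-score, ...) over the edges of
#' an inferred network. High values do not imply high F-scores — a selected
#' edge can be a false positive with a large MI — which is exactly the
#' heterogeneity this diagnostic exposes.
#'
#' @param scores Symmetric score matrix.
#' @param network Nonempty adjacency matrix on the same genes.
#' @return Mean score per selected edge.
#' @export
mean_mi_per_significant_edge <- function(scores, network) {
  network <- symmetrize(network)
  check_universe(scores, network)
  sel <- upper.tri(network) & network != 0
  if (!any(sel)) stop("network has no edges")
  mean(scores[sel])
}
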