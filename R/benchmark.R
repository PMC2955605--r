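#' Benchmark inference methods over a simulated ensemble
#'
#' Runs the full evaluation protocol: generate `n_datasets` expression
#' datasets from a true regulatory model (kinetics resampled per dataset),
#' estimate the MI matrix of each, and score every requested method against
#' the true network at its own optimal cut-off (F-score-maximizing
#' threshold). The resulting table supports the max/min/mean/median ensemble
#' summaries and per-edge TPR analyses.
#'
#' @param model A `regulatory_model` — the true network.
#' @param n_datasets Ensemble size N.
#' @param p Samples per dataset.
#' @param rng_seed Seed for the whole ensemble.
#' @param methods Subset of `c("c3net", "rn", "aracne", "clr", "mrnet")`.
#' @param eps ARACNE DPI tolerance.
#' @param estimator,bins,order Passed to [mi_matrix()].
#' @param max_candidates Cap on thresholds scanned per method and dataset
#'   (see [optimal_cutoff()]); default 200.
#' @param ranges Kinetic resampling ranges.
#' @param keep_networks If `TRUE`, attach the inferred optimal-cutoff
#'   networks as attribute `networks` (a list of lists, per dataset per
#'   method) for per-edge TPR analysis.
#' @return Data frame with one row per dataset x method: `dataset`, `method`,
#'   `threshold`, `TP`, `FP`, `FN`, `precision`, `recall`, `fscore`.
#' @export
benchmark_ensemble <- function(model, n_datasets, p, rng_seed = NULL,
                               methods = c("c3net", "rn", "aracne",
                                           "clr", "mrnet"),
                               eps = 0.1,
                               estimator = c("gaussian", "bspline"),
                               bins = 10L, order = 3L,
                               max_candidates = 200L,
                               ranges = kinetic_ranges(),
                               keep_networks = FALSE) {
  estimator <- match.arg(estimator)
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- model_adjacency(model)
  datasets <- generate_ensemble(model, n_datasets, p, rng_seed = rng_seed,
                                ranges = ranges)
  rows <- vector("list", n_datasets * length(methods))
  nets <- if (keep_networks) vector("list", n_datasets) else NULL
  r <- 0L
  for (k in seq_len(n_datasets)) {
    mi <- suppressWarnings(
      mi_matrix(datasets[[k]], estimator, bins = bins, order = order))
    scores_of <- list(
      c3net = mi, rn = mi, aracne = mi,
      clr = function() clr(mi), mrnet = function() mrnet(mi))
    infer_of <- list(
      c3net = c3net_fast,
      rn = threshold_connectivity,
      aracne = function(s, t) aracne(s, t, eps = eps),
      clr = threshold_connectivity,
      mrnet = threshold_connectivity)
    if (keep_networks) nets[[k]] <- list()
    for (mth in methods) {
      sc <- scores_of[[mth]]
      if (is.function(sc)) sc <- sc()
      opt <- optimal_cutoff(sc, truth, infer = infer_of[[mth]],
                            max_candidates = max_candidates)
      r <- r + 1L
      rows[[r]] <- data.frame(
        dataset = k, method = mth, threshold = opt$threshold,
        TP = opt$result$TP, FP = opt$result$FP, FN = opt$result$FN,
        precision = opt$result$precision, recall = opt$result$recall,
        fscore = opt$result$fscore, stringsAsFactors = FALSE)
      if (keep_networks) {
        nets[[k]][[mth]] <- infer_of[[mth]](sc, opt$threshold)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  if (keep_networks) attr(out, "networks") <- nets
  out
}

#' Summarize a benchmark table per method
#'
#' @param bench Data frame from [benchmark_ensemble()].
#' @return Data frame with one row per method and columns `max`, `min`,
#'   `mean`, `median` of the F-score.
#' @export
benchmark_summary <- function(bench) {
  methods <- unique(bench$method)
  do.call(rbind, lapply(methods, function(m) {
    s <- ensemble_summary(bench$fscore[bench$method == m])
    data.frame(method = m, max = s[["max"]], min = s[["min"]],
               mean = s[["mean"]], median = s[["median"]],
               stringsAsFactors = FALSE)
  }))
}
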