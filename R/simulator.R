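#' Default kinetic parameter ranges for the transcription simulator
#'
#' Ranges on the unit activity scale from which per-edge and per-gene kinetic
#' parameters are (re)drawn: maximum transcription rate V, Hill
#' half-saturation K, Hill coefficient h, basal level b, and the standard
#' deviation of the multiplicative lognormal measurement noise.
#'
#' @param V,K,b,sigma_bio,sigma_noise Length-2 numeric ranges (uniform
#'   draws). `sigma_bio` is the intrinsic (biological) noise applied to every
#'   gene's activity before it propagates to downstream genes, so indirect
#'   dependence decays with regulatory path length; `sigma_noise` is the
#'   experimental measurement noise applied once to the reported values.
#' @param h Integer set for the Hill coefficient (uniform draw).
#' @return Named list of ranges.
#' @export
kinetic_ranges <- function(V = c(0.5, 1.5), K = c(0.2, 0.8), h = c(1L, 2L, 3L),
                           b = c(0, 0.05), sigma_bio = c(0.05, 0.2),
                           sigma_noise = c(0.05, 0.2)) {
  list(V = V, K = K, h = h, b = b, sigma_bio = sigma_bio,
       sigma_noise = sigma_noise)
}

# Internal: validate a regulatory model.
check_model <- function(model) {
  stopifnot(inherits(model, "regulatory_model"))
  e <- model$edges
  if (nrow(e) && any(e$regulator == e$target)) stop("self-loops not allowed")
  if (nrow(e) && (any(e$K <= 0) || any(e$h < 1))) {
    stop("kinetic parameters must be positive (K > 0, h >= 1)")
  }
  if (any(model$gene_params$V <= 0) || any(model$gene_params$b < 0)) {
    stop("per-gene parameters must satisfy V > 0, b >= 0")
  }
  if (model$sigma_noise < 0 || model$sigma_bio < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (!all(e$sign %in% c("activation", "repression"))) {
    stop("edge signs must be 'activation' or 'repression'")
  }
  invisible(model)
}

# Internal: assemble a regulatory_model object.
new_model <- function(genes, tfs, edges, gene_params, sigma_bio,
                      sigma_noise) {
  check_model(structure(
    list(genes = genes, tfs = tfs, edges = edges,
         gene_params = gene_params, sigma_bio = sigma_bio,
         sigma_noise = sigma_noise),
    class = "regulatory_model"))
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat("Regulatory model:", length(x$genes), "genes (",
      length(x$tfs), "TFs ),", nrow(x$edges), "directed signed edges\n")
  cat("sigma_bio =", format(x$sigma_bio),
      "  sigma_noise =", format(x$sigma_noise), "\n")
  invisible(x)
}

#' True-network adjacency of a regulatory model
#'
#' @param model A `regulatory_model`.
#' @param directed Keep edge direction (regulator in rows)? Default `FALSE`
#'   (symmetrized, matching the undirected inferred networks).
#' @return 0/1 adjacency matrix with gene ids as dimnames.
#' @export
model_adjacency <- function(model, directed = FALSE) {
  n <- length(model$genes)
  a <- matrix(0L, n, n, dimnames = list(model$genes, model$genes))
  if (nrow(model$edges)) {
    a[cbind(match(model$edges$regulator, model$genes),
            match(model$edges$target, model$genes))] <- 1L
  }
  if (directed) a else symmetrize(a)
}

#' Generate a scale-free-like source regulatory network
#'
#' Builds a directed acyclic topology mimicking a transcriptional regulatory
#' network: the first `n_tfs` genes are transcription factors joined into a
#' regulatory hierarchy (each TF after the first receives one edge from a
#' preferentially chosen earlier TF), and every remaining gene attaches as a
#' target of one or two TFs chosen with probability proportional to their
#' current out-degree plus one (preferential attachment, producing the
#' right-skewed out-degree distribution of real TRNs). Edge signs are drawn
#' at random (activation with probability 0.7); kinetic parameters are drawn
#' from `ranges`.
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of transcription factors (must be < `n_genes`).
#' @param rng_seed Integer seed; `NULL` uses the current RNG state.
#' @param ranges Kinetic parameter ranges, see [kinetic_ranges()].
#' @param p_second_regulator Probability that a target gets a second TF
#'   regulator (default 0.2).
#' @return A `regulatory_model`: directed signed edge table with per-edge
#'   kinetics, per-gene basal/maximal rates, and a noise level.
#' @export
make_source_network <- function(n_genes, n_tfs, rng_seed = NULL,
                                ranges = kinetic_ranges(),
                                p_second_regulator = 0.2) {
  if (n_tfs < 1L || n_tfs >= n_genes) {
    stop("need 1 <= n_tfs < n_genes (got ", n_tfs, " TFs for ",
         n_genes, " genes)")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]
  reg <- integer(0)
  tgt <- integer(0)
  outdeg <- rep(0, n_tfs)
  # TF hierarchy: edges always point from lower to higher index -> acyclic
  for (i in seq_len(n_tfs)[-1]) {
    src <- sample.int(i - 1L, 1L, prob = outdeg[seq_len(i - 1L)] + 1)
    reg <- c(reg, src); tgt <- c(tgt, i)
    outdeg[src] <- outdeg[src] + 1
  }
  # targets attach preferentially to high-out-degree TFs
  for (i in setdiff(seq_len(n_genes), seq_len(n_tfs))) {
    k <- 1L + stats::rbinom(1L, 1L, p_second_regulator)
    src <- sample.int(n_tfs, min(k, n_tfs), prob = outdeg + 1)
    reg <- c(reg, src); tgt <- c(tgt, rep(i, length(src)))
    outdeg[src] <- outdeg[src] + 1
  }
  n_edges <- length(reg)
  edges <- data.frame(
    regulator = genes[reg],
    target = genes[tgt],
    sign = sample(c("activation", "repression"), n_edges,
                  replace = TRUE, prob = c(0.7, 0.3)),
    K = stats::runif(n_edges, ranges$K[1], ranges$K[2]),
    h = sample(ranges$h, n_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  gene_params <- data.frame(
    gene = genes,
    b = stats::runif(n_genes, ranges$b[1], ranges$b[2]),
    V = stats::runif(n_genes, ranges$V[1], ranges$V[2]),
    stringsAsFactors = FALSE)
  new_model(genes, tfs, edges, gene_params,
            stats::runif(1, ranges$sigma_bio[1], ranges$sigma_bio[2]),
            stats::runif(1, ranges$sigma_noise[1], ranges$sigma_noise[2]))
}

#' Sample a subnetwork by neighbor addition
#'
#' Starting from one random seed gene, repeatedly adds a uniformly chosen
#' gene from the undirected neighborhood of the current set until `n` genes
#' are selected, then returns the induced directed subnetwork. Neighbor
#' addition keeps the sample connected and visits hub genes more often than
#' leaves, preserving the local structure of the source topology.
#'
#' @param source A `regulatory_model`.
#' @param n Number of genes to sample (at most the source size).
#' @param rng_seed Integer seed; `NULL` uses the current RNG state.
#' @return The induced `regulatory_model` on the sampled genes.
#' @export
sample_subnetwork <- function(source, n, rng_seed = NULL) {
  check_model(source)
  ng <- length(source$genes)
  if (n < 1L || n > ng) stop("n must be between 1 and the source size")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  adj <- model_adjacency(source, directed = FALSE)
  keep <- sample.int(ng, 1L)
  while (length(keep) < n) {
    nb <- which(rowSums(adj[, keep, drop = FALSE]) > 0)
    nb <- setdiff(nb, keep)
    if (length(nb) == 0) {
      stop("neighborhood exhausted at ", length(keep),
           " genes: the source component is too small; retry with a ",
           "different seed or a connected source")
    }
    keep <- c(keep, nb[sample.int(length(nb), 1L)])
  }
  keep <- sort(keep)
  genes <- source$genes[keep]
  e <- source$edges[source$edges$regulator %in% genes &
                    source$edges$target %in% genes, , drop = FALSE]
  rownames(e) <- NULL
  new_model(genes, intersect(source$tfs, genes), e,
            source$gene_params[match(genes, source$gene_params$gene), ,
                               drop = FALSE],
            source$sigma_bio, source$sigma_noise)
}

#' Redraw the kinetic parameters of a model
#'
#' Independently resamples every per-edge (K, h) and per-gene (b, V)
#' parameter and the noise level from the given ranges, keeping the topology
#' and signs fixed. Used between ensemble datasets to emulate biological
#' variability.
#'
#' @param model A `regulatory_model`.
#' @param ranges See [kinetic_ranges()].
#' @param rng_seed Integer seed; `NULL` uses the current RNG state.
#' @return The model with fresh kinetic parameters.
#' @export
resample_kinetics <- function(model, ranges = kinetic_ranges(),
                              rng_seed = NULL) {
  check_model(model)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ne <- nrow(model$edges)
  ng <- length(model$genes)
  model$edges$K <- stats::runif(ne, ranges$K[1], ranges$K[2])
  model$edges$h <- sample(ranges$h, ne, replace = TRUE)
  model$gene_params$b <- stats::runif(ng, ranges$b[1], ranges$b[2])
  model$gene_params$V <- stats::runif(ng, ranges$V[1], ranges$V[2])
  model$sigma_bio <- stats::runif(1, ranges$sigma_bio[1],
                                  ranges$sigma_bio[2])
  model$sigma_noise <- stats::runif(1, ranges$sigma_noise[1],
                                    ranges$sigma_noise[2])
  model
}

# Internal: igraph view of the directed topology.
model_graph <- function(model) {
  igraph::graph_from_data_frame(
    model$edges[, c("regulator", "target"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = model$genes, stringsAsFactors = FALSE))
}

#' Simulate steady-state expression data from a regulatory model
#'
#' Draws independent steady-state samples: in each sample, root genes (genes
#' without regulators) take activities uniform on (0, 1) — the analogue of
#' varying experimental conditions — and every downstream gene's level is
#' computed in topological order as
#' \deqn{x = b + V \prod_{a \in \mathrm{act}} \frac{x_a^h}{K^h + x_a^h}
#'              \prod_{r \in \mathrm{rep}} \frac{K^h}{K^h + x_r^h},}
#' the Michaelis-Menten/Hill transfer function with multiplicative
#' combination of independent regulator binding. Two multiplicative
#' lognormal noise sources act on every gene: intrinsic biological noise
#' `exp(N(0, sigma_bio^2))` perturbs the activity that propagates to
#' downstream genes (so dependence decays along regulatory paths, and
#' co-regulated siblings are less dependent than direct regulator-target
#' pairs), and experimental noise `exp(N(0, sigma_noise^2))` perturbs the
#' reported measurement only. Only acyclic models are supported — the
#' closed-form topological evaluation is the steady state.
#'
#' @param model An acyclic `regulatory_model`.
#' @param p Number of samples (at least 3).
#' @param rng_seed Integer seed; `NULL` uses the current RNG state.
#' @param root_values Optional matrix of fixed activities for the root genes
#'   (rows named by root gene, `p` columns); mainly for calibration and
#'   testing.
#' @return Expression matrix, genes x samples, all values positive.
#' @export
simulate_expression <- function(model, p, rng_seed = NULL,
                                root_values = NULL) {
  check_model(model)
  if (p < 3L) stop("need at least 3 samples")
  g <- model_graph(model)
  if (!igraph::is_dag(g)) {
    stop("model contains a cycle: only acyclic models have a closed-form ",
         "steady state")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- model$genes
  n <- length(genes)
  ord <- genes[as.integer(igraph::topo_sort(g, mode = "out"))]
  x <- matrix(NA_real_, n, p, dimnames = list(genes, NULL))
  e <- model$edges
  gp <- model$gene_params
  for (gene in ord) {
    inc <- e[e$target == gene, , drop = FALSE]
    if (nrow(inc) == 0) {
      if (!is.null(root_values) && gene %in% rownames(root_values)) {
        x[gene, ] <- root_values[gene, ]
      } else {
        x[gene, ] <- stats::runif(p)
      }
    } else {
      i <- match(gene, gp$gene)
      act <- rep(1, p)
      for (k in seq_len(nrow(inc))) {
        xr <- x[inc$regulator[k], ]
        kh <- inc$K[k]^inc$h[k]
        xh <- xr^inc$h[k]
        act <- act * if (inc$sign[k] == "activation") xh / (kh + xh)
                     else kh / (kh + xh)
      }
      x[gene, ] <- gp$b[i] + gp$V[i] * act
    }
    if (model$sigma_bio > 0) {
      x[gene, ] <- x[gene, ] *
        exp(stats::rnorm(p, 0, model$sigma_bio))
    }
  }
  if (model$sigma_noise > 0) {
    x <- x * exp(matrix(stats::rnorm(n * p, 0, model$sigma_noise), n, p))
  }
  x
}

#' Generate an ensemble of expression datasets
#'
#' Produces `n_datasets` independent datasets from one regulatory topology,
#' redrawing every kinetic parameter from its range before each dataset so
#' the ensemble reflects biological variability, not just sampling noise.
#' Per-dataset seeds are derived deterministically from `rng_seed`.
#'
#' @param model A `regulatory_model` (the fixed true topology).
#' @param n_datasets Ensemble size N.
#' @param p Samples per dataset.
#' @param rng_seed Integer seed for the whole ensemble.
#' @param ranges Kinetic resampling ranges, see [kinetic_ranges()].
#' @return List of length `n_datasets`; each element is an expression matrix
#'   with attributes `model` (the resampled kinetics used) and `seed`.
#' @export
generate_ensemble <- function(model, n_datasets, p, rng_seed = NULL,
                              ranges = kinetic_ranges()) {
  check_model(model)
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  lapply(seq_len(n_datasets), function(k) {
    set.seed(seeds[k])
    mk <- resample_kinetics(model, ranges)
    xk <- simulate_expression(mk, p)
    attr(xk, "model") <- mk
    attr(xk, "seed") <- seeds[k]
    xk
  })
}
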