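#' Read an expression matrix from TSV/CSV
#'
#' Expects gene ids in the first column and a header row of sample ids (the
#' microarray convention: genes in rows). Use `samples_in_rows = TRUE` for
#' the transposed dialect.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @param samples_in_rows Transpose after reading?
#' @return Validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, sep = "\t", samples_in_rows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      fill = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  num <- df[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    for (j in which(bad)) {
      v <- suppressWarnings(as.numeric(num[[j]]))
      if (anyNA(v)) {
        row <- which(is.na(v))[1]
        stop("non-numeric cell in ", path, ", column '", names(num)[j],
             "', line ", row + 1L, " (gene ", ids[row], ")")
      }
      num[[j]] <- v
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (samples_in_rows) m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  expr <- expression_matrix(expr)
  samples <- colnames(expr)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", samples)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square MI / score matrix as TSV
#'
#' @param mi Square matrix with gene ids as dimnames.
#' @param path Output path.
#' @export
write_mi_matrix <- function(mi, path) {
  check_square(mi, "MI matrix")
  ids <- rownames(mi)
  if (is.null(ids)) ids <- paste0("G", seq_len(nrow(mi)))
  df <- data.frame(gene = ids, format(mi, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square MI / score matrix written by [write_mi_matrix()]
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as dimnames.
#' @export
read_mi_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  check_square(m, "MI matrix")
  m
}

#' Write a network to disk
#'
#' Undirected edges are written once per unordered pair, lexicographically
#' sorted, so the output is byte-deterministic. Formats: `edgelist` (TSV
#' `gene_a<TAB>gene_b[<TAB>weight]`), `sif` (Cytoscape simple interaction
#' format with interaction label `mi`) and `adjacency` (square TSV).
#'
#' @param net Symmetric adjacency matrix (0/1) or, with `weights`, the
#'   adjacency of a scored network.
#' @param path Output path.
#' @param format One of `"edgelist"`, `"sif"`, `"adjacency"`.
#' @param weights Optional symmetric score matrix; adds a weight column to
#'   edge lists.
#' @export
write_network <- function(net, path, format = c("edgelist", "sif", "adjacency"),
                          weights = NULL) {
  format <- match.arg(format)
  net <- symmetrize(net)
  if (format == "adjacency") {
    return(write_mi_matrix(net, path))
  }
  el <- as_edge_list(net, weights = weights)
  lines <- if (format == "sif") {
    paste(el$gene_a, "mi", el$gene_b, sep = "\t")
  } else if (is.null(weights)) {
    c("gene_a\tgene_b", paste(el$gene_a, el$gene_b, sep = "\t"))
  } else {
    c("gene_a\tgene_b\tweight",
      paste(el$gene_a, el$gene_b, format(el$weight, digits = 17, trim = TRUE),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network edge list back into an adjacency matrix
#'
#' @param path File written by [write_network()] (`edgelist` or `sif`).
#' @param gene_ids Gene universe of the returned adjacency (edges may touch a
#'   subset of it).
#' @param format `"edgelist"` or `"sif"`.
#' @return Symmetric 0/1 adjacency matrix over `gene_ids`.
#' @export
read_network <- function(path, gene_ids, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  n <- length(gene_ids)
  a <- matrix(0L, n, n, dimnames = list(gene_ids, gene_ids))
  lines <- readLines(path)
  if (format == "edgelist" && length(lines)) lines <- lines[-1]  # header
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pair <- if (format == "sif") f[c(1, 3)] else f[1:2]
    if (!all(pair %in% gene_ids)) {
      stop("unknown gene id(s) in ", path, ": ",
           paste(setdiff(pair, gene_ids), collapse = ", "))
    }
    a[pair[1], pair[2]] <- a[pair[2], pair[1]] <- 1L
  }
  a
}

#' Export a regulatory model as a signed edge list
#'
#' Three-column TSV (`regulator`, `target`, `sign`) or SIF with the sign as
#' the interaction label. Kinetic parameters are not serialized — they are
#' resampled per dataset anyway.
#'
#' @param model A `regulatory_model`.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_regulatory_model <- function(model, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  check_model(model)
  e <- model$edges[order(model$edges$regulator, model$edges$target), ,
                   drop = FALSE]
  if (format == "sif") {
    writeLines(paste(e$regulator, e$sign, e$target, sep = "\t"), path)
  } else {
    utils::write.table(e[, c("regulator", "target", "sign")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a regulatory model from a signed edge list
#'
#' Reads the 3-column TSV written by [write_regulatory_model()] and fills in
#' kinetic parameters by drawing from `ranges`.
#'
#' @param path File path.
#' @param ranges Kinetic ranges for the redrawn parameters.
#' @param rng_seed Seed for the parameter draw.
#' @return A `regulatory_model`.
#' @export
read_regulatory_model <- function(path, ranges = kinetic_ranges(),
                                  rng_seed = NULL) {
  e <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "sign") %in% colnames(e)))
  genes <- sort(unique(c(e$regulator, e$target)))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ng <- length(genes)
  model <- new_model(
    genes, unique(e$regulator),
    data.frame(regulator = e$regulator, target = e$target, sign = e$sign,
               K = stats::runif(nrow(e), ranges$K[1], ranges$K[2]),
               h = sample(ranges$h, nrow(e), replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(gene = genes,
               b = stats::runif(ng, ranges$b[1], ranges$b[2]),
               V = stats::runif(ng, ranges$V[1], ranges$V[2]),
               stringsAsFactors = FALSE),
    stats::runif(1, ranges$sigma_bio[1], ranges$sigma_bio[2]),
    stats::runif(1, ranges$sigma_noise[1], ranges$sigma_noise[2]))
  model
}
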