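# The classic 4-gene worked example: MI matrix, its connectivity matrix at a
# cut-off separating 0.6 from 0.5, and the networks the maximization step
# must produce (a star centered on gene 1).

toy_mi <- function() {
  m <- rbind(c(0.0, 0.7, 0.9, 0.8),
             c(0.7, 0.0, 0.6, 0.5),
             c(0.9, 0.6, 0.0, 0.1),
             c(0.8, 0.5, 0.1, 0.0))
  dimnames(m) <- list(paste0("G", 1:4), paste0("G", 1:4))
  m
}

toy_conn <- function() {
  m <- rbind(c(0L, 1L, 1L, 1L),
             c(1L, 0L, 1L, 0L),
             c(1L, 1L, 0L, 0L),
             c(1L, 0L, 0L, 0L))
  dimnames(m) <- list(paste0("G", 1:4), paste0("G", 1:4))
  m
}

toy_partner_matrix <- function() {
  m <- rbind(c(0L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L))
  dimnames(m) <- list(paste0("G", 1:4), paste0("G", 1:4))
  m
}

toy_adjacency <- function() {
  m <- rbind(c(0L, 1L, 1L, 1L),
             c(1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L))
  dimnames(m) <- list(paste0("G", 1:4), paste0("G", 1:4))
  m
}

# Random symmetric MI-like matrix, optionally rounded to force ties.
rand_mi <- function(n, digits = NULL) {
  m <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2)
  if (!is.null(digits)) v <- round(v, digits)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  m
}

# Random symmetric 0/1 connectivity with zero diagonal.
rand_conn <- function(n, p = 0.5) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  m + t(m)
}

# Random 0/1 undirected network.
rand_net <- function(n, p = 0.3) rand_conn(n, p)
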