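test_that("confusion counts and F-score follow their definitions", {
  net <- rand_net(6)
  res <- compare_networks(net, net)
  expect_equal(res$FP, 0)
  expect_equal(res$FN, 0)
  if (res$TP > 0) expect_equal(res$fscore, 1)

  # 74 true and 25 false positives give precision 74/99
  inferred <- matrix(0L, 100, 100)
  truth <- matrix(0L, 100, 100)
  pairs <- which(upper.tri(truth))
  truth[pairs[1:150]] <- 1L
  inferred[pairs[1:74]] <- 1L       # 74 shared with the truth
  inferred[pairs[151:175]] <- 1L    # 25 outside it
  r <- compare_networks(inferred, truth)
  expect_equal(c(r$TP, r$FP, r$FN), c(74, 25, 76))
  expect_equal(r$precision, 74 / 99)
  expect_equal(round(r$precision, 2), 0.75)
})

test_that("confusion counts match the pair-by-pair oracle", {
  set.seed(30)
  for (rep in 1:50) {
    a <- rand_net(6)
    b <- rand_net(6)
    r <- compare_networks(a, b)
    o <- brute_compare(a, b)
    expect_equal(c(r$TP, r$FP, r$FN), c(o$TP, o$FP, o$FN))
  }
})

test_that("direction is ignored: symmetrized truths change nothing", {
  set.seed(31)
  n <- 7
  directed <- matrix(0L, n, n)
  directed[upper.tri(directed)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
  reversed <- t(directed)
  net <- rand_net(n)
  expect_identical(unclass(compare_networks(net, directed)),
                   unclass(compare_networks(net, reversed)))
})

test_that("a candidate mask discards out-of-mask edges before counting", {
  truth <- matrix(0L, 4, 4)
  truth[1, 2] <- truth[2, 1] <- 1L
  inferred <- truth
  inferred[3, 4] <- inferred[4, 3] <- 1L  # outside the mask
  mask <- matrix(0L, 4, 4)
  mask[1, 2] <- mask[1, 3] <- 1L
  r <- compare_networks(inferred, truth, mask = mask)
  expect_equal(c(r$TP, r$FP, r$FN), c(1, 0, 0))
  expect_equal(r$fscore, 1)
  # without the mask the extra edge is a false positive
  expect_equal(compare_networks(inferred, truth)$FP, 1)
})

test_that("gene-universe mismatches are reported with offending ids", {
  a <- rand_net(3)
  rownames(a) <- colnames(a) <- c("x", "y", "z")
  b <- rand_net(3)
  rownames(b) <- colnames(b) <- c("x", "y", "w")
  expect_error(compare_networks(a, b), "w")
  expect_error(compare_networks(rand_net(3), rand_net(4)), "universes")
})

test_that("optimal cutoff attains F = 1 on perfectly separated scores", {
  set.seed(32)
  truth <- rand_net(6, 0.4)
  scores <- matrix(0, 6, 6)
  scores[truth == 1] <- runif(sum(truth), 0.8, 1)
  low <- truth == 0 & !diag(6)
  scores[upper.tri(scores) & truth == 0] <- runif(sum(upper.tri(scores) & truth == 0), 0.05, 0.3)
  scores[lower.tri(scores)] <- t(scores)[lower.tri(scores)]
  diag(scores) <- 0
  opt <- optimal_cutoff(scores, truth)
  expect_equal(opt$result$fscore, 1)
  # the selected cut-off reproduces the truth exactly
  expect_equal(unname(threshold_connectivity(scores, opt$threshold)),
               unname(truth))
})

test_that("optimal cutoff matches the exhaustive scan oracle", {
  set.seed(33)
  for (rep in 1:30) {
    n <- 5
    scores <- rand_mi(n)
    truth <- rand_net(n, 0.4)
    if (sum(truth) == 0) next
    opt <- optimal_cutoff(scores, truth)
    expect_equal(opt$result$fscore, brute_best_fscore(scores, truth),
                 tolerance = 1e-12)
    # maximality against arbitrary user thresholds
    for (thr in runif(5)) {
      f_user <- compare_networks(threshold_connectivity(scores, thr),
                                 truth)$fscore
      expect_gte(opt$result$fscore, f_user - 1e-12)
    }
  }
})

test_that("ensemble summaries are the four order statistics", {
  one <- list(structure(list(fscore = 0.4), class = "grn_eval"))
  expect_equal(unname(ensemble_summary(one)), rep(0.4, 4))
  expect_equal(unname(ensemble_summary(c(0.2, 0.4, 0.6))),
               c(0.6, 0.2, 0.4, 0.4))
  set.seed(34)
  f <- runif(300)
  s <- ensemble_summary(f)
  fs <- sort(f)
  expect_equal(unname(s), c(fs[300], fs[1], mean(f),
                            (fs[150] + fs[151]) / 2))
  expect_error(ensemble_summary(list()), "empty")
})

test_that("per-edge TPR uses the printed color bins", {
  truth <- matrix(0L, 3, 3)
  truth[1, 2] <- truth[2, 1] <- 1L
  truth[2, 3] <- truth[3, 2] <- 1L
  always <- truth
  never <- matrix(0L, 3, 3)
  nets <- c(rep(list(always), 120), rep(list(never), 180))
  # edge 1-2 present in 120 of 300 -> 0.4 -> green; same for 2-3
  stats <- edge_tpr(nets, truth)
  expect_equal(stats$tpr, c(0.4, 0.4))
  expect_identical(stats$color, c("green", "green"))

  expect_identical(edge_tpr(list(always), truth)$color, c("black", "black"))
  expect_identical(edge_tpr(list(never), truth)$color, c("red", "red"))
  # boundary cases fall in the lower bin (right-closed intervals)
  nets2 <- c(rep(list(always), 3), rep(list(never), 1))
  expect_identical(edge_tpr(nets2, truth)$color, c("blue", "blue"))
})

test_that("mean MI per selected edge averages exactly the network edges", {
  net <- c3net(toy_mi(), 0.55)
  expect_equal(mean_mi_per_significant_edge(toy_mi(), net), 0.8)

  single <- matrix(0L, 4, 4)
  single[1, 3] <- single[3, 1] <- 1L
  expect_equal(mean_mi_per_significant_edge(toy_mi(), single), 0.9)

  # adding non-edges with arbitrary scores changes nothing
  noisy <- toy_mi()
  noisy[2, 4] <- noisy[4, 2] <- 99
  expect_equal(mean_mi_per_significant_edge(noisy, net), 0.8)

  expect_error(mean_mi_per_significant_edge(toy_mi(), matrix(0L, 4, 4)),
               "no edges")
})
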