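test_that("source networks satisfy the construction contract", {
  m <- make_source_network(100, 15, rng_seed = 1)
  expect_length(m$genes, 100)
  expect_length(m$tfs, 15)
  g <- corenet:::model_graph(m)
  expect_true(igraph::is_dag(g))
  # every non-TF is regulated
  indeg <- igraph::degree(g, mode = "in")
  expect_true(all(indeg[setdiff(m$genes, m$tfs)] >= 1))
  # connected as an undirected graph (so neighbor addition always works)
  expect_true(igraph::is_connected(g, mode = "weak"))
  expect_error(make_source_network(10, 10), "n_tfs")
})

test_that("same seed gives an identical topology and parameters", {
  a <- make_source_network(50, 8, rng_seed = 42)
  b <- make_source_network(50, 8, rng_seed = 42)
  expect_identical(a, b)
  c <- make_source_network(50, 8, rng_seed = 43)
  expect_false(identical(a$edges, c$edges))
})

test_that("out-degrees are right-skewed under preferential attachment", {
  m <- make_source_network(100, 15, rng_seed = 3)
  outdeg <- table(factor(m$edges$regulator, levels = m$tfs))
  expect_gt(max(outdeg), 2 * stats::median(as.integer(outdeg)))
})

test_that("neighbor addition yields connected induced subnetworks", {
  src <- make_source_network(80, 12, rng_seed = 4)
  sub <- sample_subnetwork(src, 30, rng_seed = 5)
  expect_length(sub$genes, 30)
  g <- corenet:::model_graph(sub)
  expect_true(igraph::is_connected(g, mode = "weak"))
  # induced edges only, and all induced edges kept
  expected <- src$edges[src$edges$regulator %in% sub$genes &
                        src$edges$target %in% sub$genes, ]
  expect_equal(nrow(sub$edges), nrow(expected))

  # sampling everything returns the whole source
  all_of_it <- sample_subnetwork(src, 80, rng_seed = 6)
  expect_identical(sort(all_of_it$genes), sort(src$genes))
  expect_equal(nrow(all_of_it$edges), nrow(src$edges))
})

test_that("hub genes are sampled more often than leaves", {
  src <- make_source_network(60, 8, rng_seed = 7)
  outdeg <- table(factor(src$edges$regulator, levels = src$genes))
  hub <- names(which.max(outdeg))
  leaves <- setdiff(src$genes, src$edges$regulator)
  leaf <- leaves[1]
  hits_hub <- 0
  hits_leaf <- 0
  set.seed(8)
  for (r in 1:200) {
    s <- sample_subnetwork(src, 10)
    hits_hub <- hits_hub + (hub %in% s$genes)
    hits_leaf <- hits_leaf + (leaf %in% s$genes)
  }
  expect_gt(hits_hub, hits_leaf)
})

test_that("the Hill transfer hits its half-saturation and repression limits", {
  e <- data.frame(regulator = "A", target = "B", sign = "activation",
                  K = 0.4, h = 2, stringsAsFactors = FALSE)
  gp <- data.frame(gene = c("A", "B"), b = c(0, 0.02), V = c(1, 1.2),
                   stringsAsFactors = FALSE)
  model <- corenet:::new_model(c("A", "B"), "A", e, gp,
                               sigma_bio = 0, sigma_noise = 0)
  x <- simulate_expression(model, 5, rng_seed = 1,
                           root_values = rbind(A = rep(0.4, 5)))
  # regulator at K -> target at b + V/2
  expect_equal(unname(x["B", ]), rep(0.02 + 1.2 / 2, 5), tolerance = 1e-12)

  # strong input through a repression edge drives the target to its basal b
  e$sign <- "repression"
  e$K <- 0.01
  model2 <- corenet:::new_model(c("A", "B"), "A", e, gp,
                                sigma_bio = 0, sigma_noise = 0)
  x2 <- simulate_expression(model2, 5, rng_seed = 1,
                            root_values = rbind(A = rep(0.99, 5)))
  expect_true(all(abs(x2["B", ] - 0.02) < 0.01))
})

test_that("cyclic models are rejected and outputs are positive and seeded", {
  e <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                  sign = "activation", K = 0.5, h = 1,
                  stringsAsFactors = FALSE)
  gp <- data.frame(gene = c("A", "B"), b = 0.01, V = 1,
                   stringsAsFactors = FALSE)
  cyc <- corenet:::new_model(c("A", "B"), "A", e, gp, 0.1, 0.1)
  expect_error(simulate_expression(cyc, 10), "cycle")

  src <- make_source_network(20, 4, rng_seed = 9)
  x1 <- simulate_expression(src, 50, rng_seed = 10)
  x2 <- simulate_expression(src, 50, rng_seed = 10)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0) && all(is.finite(x1)))
  expect_identical(dim(x1), c(20L, 50L))
})

test_that("a regulated pair carries more MI than independent roots", {
  e <- data.frame(regulator = "A", target = "B", sign = "activation",
                  K = 0.5, h = 2, stringsAsFactors = FALSE)
  gp <- data.frame(gene = c("A", "B", "C", "D"), b = 0.01, V = 1,
                   stringsAsFactors = FALSE)
  model <- corenet:::new_model(c("A", "B", "C", "D"), "A", e, gp,
                               sigma_bio = 0.1, sigma_noise = 0.1)
  wins <- 0
  for (r in 1:20) {
    x <- simulate_expression(model, 500, rng_seed = 100 + r)
    ct <- copula_transform(x)
    mi_edge <- gaussian_mi(ct["A", ], ct["B", ])
    mi_null <- gaussian_mi(ct["C", ], ct["D", ])
    wins <- wins + (mi_edge > mi_null)
  }
  expect_gte(wins, 19)
})

test_that("ensembles redraw kinetics per dataset, reproducibly", {
  src <- make_source_network(15, 3, rng_seed = 11)
  ens <- generate_ensemble(src, 3, 20, rng_seed = 12)
  expect_length(ens, 3)
  models <- lapply(ens, attr, "model")
  # distinct continuous draws with probability 1
  expect_false(identical(models[[1]]$edges$K, models[[2]]$edges$K))
  expect_false(identical(models[[2]]$gene_params$V, models[[3]]$gene_params$V))
  # same topology throughout
  for (m in models) {
    expect_identical(m$edges[, c("regulator", "target", "sign")],
                     src$edges[, c("regulator", "target", "sign")])
  }
  # bitwise reproducible
  ens2 <- generate_ensemble(src, 3, 20, rng_seed = 12)
  expect_identical(ens, ens2)

  # N = 1 reduces to a single simulate call with redrawn parameters
  one <- generate_ensemble(src, 1, 20, rng_seed = 13)
  expect_length(one, 1)
  expect_identical(dim(one[[1]]), c(15L, 20L))
})
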