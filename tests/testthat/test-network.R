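test_that("network construction removes self-loops, keeps direction and isolates", {
  edges <- data.frame(
    source = c("A", "A", "B"), target = c("A", "B", "A"),
    weight = c(0.5, 1, 2)
  )
  g <- build_network(c("A", "B", "C"), edges)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::graph_attr(g, "self_loops_removed"), 1)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  expect_equal(W["A", "B"], 1)
  expect_equal(W["B", "A"], 2)   # directionality preserved
  expect_true("C" %in% igraph::V(g)$name)
  expect_equal(unname(igraph::degree(g, "C")), 0)
  expect_error(build_network("A", data.frame(source = "A", target = "Z", weight = 1)),
               "outside")
  expect_error(build_network(c("A", "B"),
                             data.frame(source = "A", target = "B", weight = -1)),
               "negative")
})

test_that("node annotations survive the round-trip into vertex attributes", {
  ann <- data.frame(region = c("A", "B"), activated_in = c("OBS-only", "shared"))
  g <- build_network(ann, data.frame(source = "A", target = "B", weight = 1))
  expect_equal(igraph::V(g)$activated_in, c("OBS-only", "shared"))
})

test_that("Leiden recovers planted disconnected modules exactly", {
  g <- simulate_connectome(network_sim_config(
    n_nodes = 10, module_sizes = c(5, 5), p_within = 1, p_between = 0, seed = 1
  ))
  pt <- partition_leiden(g, seed = 4)
  expect_equal(ari(pt$membership, igraph::V(g)$module), 1)
  # a fully connected uniform-weight graph is one community
  full <- expand.grid(source = LETTERS[1:6], target = LETTERS[1:6],
                      stringsAsFactors = FALSE)
  full <- full[full$source != full$target, ]
  full$weight <- 1
  g1 <- build_network(LETTERS[1:6], full)
  expect_equal(length(unique(partition_leiden(g1, seed = 1)$membership)), 1)
  # single node: one community
  g0 <- build_network("A", data.frame(source = character(0),
                                      target = character(0),
                                      weight = numeric(0)))
  expect_equal(length(partition_leiden(g0, seed = 1)$membership), 1)
})

test_that("Leiden is deterministic under the seed", {
  g <- simulate_connectome(network_sim_config(
    n_nodes = 30, module_sizes = c(15, 15), p_within = 0.6, p_between = 0.05,
    seed = 8
  ))
  expect_identical(partition_leiden(g, seed = 3)$membership,
                   partition_leiden(g, seed = 3)$membership)
})

test_that("HITS matches the closed form on a star and its invariances", {
  W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  W["A", c("B", "C", "D")] <- 1
  s <- hits_scores(W)
  expect_equal(unname(s$hub), c(1, 0, 0, 0))
  expect_equal(unname(s$authority), c(0, 1, 1, 1) / 3)
  # scale invariance
  s2 <- hits_scores(10 * W)
  expect_equal(s2$hub, s$hub, tolerance = 1e-10)
  expect_equal(s2$authority, s$authority, tolerance = 1e-10)
  # relabeling symmetry
  set.seed(2)
  Wr <- random_digraph(6)
  p <- sample(6)
  sr <- hits_scores(Wr)
  sp <- hits_scores(Wr[p, p])
  expect_equal(sp$hub, sr$hub[p], tolerance = 1e-8)
  expect_equal(sp$authority, sr$authority[p], tolerance = 1e-8)
  # edgeless graphs are an explicit error
  expect_error(hits_scores(matrix(0, 3, 3)), "no edges")
})

test_that("HITS equals the eigen-decomposition oracle on small random graphs", {
  set.seed(11)
  worst <- 0
  for (i in 1:150) {
    W <- random_digraph(sample(2:8, 1))
    s <- hits_scores(W)
    o <- hits_eigen_oracle(W)
    worst <- max(worst, max(abs(s$hub - o$hub)), max(abs(s$authority - o$authority)))
  }
  expect_lt(worst, 1e-8)
})

test_that("the top-edge filter keeps the strongest edges with stable ties", {
  set.seed(3)
  nodes <- sprintf("N%02d", 1:20)
  edges <- data.frame(
    source = sample(nodes, 100, TRUE), target = sample(nodes, 100, TRUE),
    weight = c(rep(9, 3), runif(97))
  )
  edges <- edges[edges$source != edges$target, ]
  g <- build_network(nodes, edges)
  ne <- igraph::ecount(g)
  top <- top_edge_filter(g, 0.05)
  expect_equal(nrow(top), ceiling(0.05 * ne))
  expect_gte(min(top$weight), max(setdiff(edges$weight, top$weight)))
  expect_equal(nrow(top_edge_filter(g, 1)), ne)
  # tie at the cutoff: stable input order decides, deterministically
  tie_edges <- data.frame(source = c("N01", "N02", "N03"),
                          target = c("N02", "N03", "N01"), weight = 1)
  gt <- build_network(nodes[1:3], tie_edges)
  t1 <- top_edge_filter(gt, 1 / 3)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$source, "N01")
  expect_error(top_edge_filter(g, 0), "fraction")
})

test_that("the bootstrap keeps the target, honors the seed, and reports degenerate sd", {
  sc <- planted_hub_scenario(seed = 1)
  b1 <- bootstrap_hits(sc$target, sc$observed, sc$edges, sc$pool,
                       n_iter = 50, seed = 5)
  b2 <- bootstrap_hits(sc$target, sc$observed, sc$edges, sc$pool,
                       n_iter = 50, seed = 5)
  expect_equal(b1, b2)
  expect_equal(b1$n_iter, 50)
  expect_true(is.finite(b1$z_hub))
  # pool must strictly exceed the observed network
  expect_error(bootstrap_hits(sc$target, sc$pool, sc$edges, sc$pool),
               "strictly larger")
  # a target disconnected from everything: all bootstrap scores 0 -> sd = 0
  nodes <- c("T", sprintf("B%02d", 1:10))
  ring <- data.frame(source = sprintf("B%02d", 1:9),
                     target = sprintf("B%02d", 2:10), weight = 1)
  b3 <- bootstrap_hits("T", c("T", "B01", "B02"), ring, nodes,
                       n_iter = 30, seed = 2)
  expect_true(is.na(b3$z_hub) && is.na(b3$p_hub))
})
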