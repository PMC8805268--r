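test_that("MRMR ranking follows the greedy relevance-redundancy rule", {
  # two nodes: the single other node with its plain relevance
  W2 <- as_synergy(matrix(c(0, 0.7, 0.7, 0), 2, 2))
  r2 <- mrmr_rank(W2, 2)
  expect_identical(r2$node, 1L)
  expect_equal(r2$score, 0.7)
  # hand-worked three-node case
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.4
  W[1, 2] <- W[2, 1] <- 0.3
  r <- mrmr_rank(as_synergy(W), 3)
  expect_identical(r$node, c(1L, 2L))
  expect_equal(r$score, c(0.5, 0.4 - 0.3))
  expect_error(mrmr_rank(as_synergy(W), 9), "out of range")
})

test_that("MRMR ranking equals the exhaustive greedy oracle", {
  withr::local_seed(53)
  for (rep in 1:10) {
    W <- rand_symmetric(8)
    t0 <- sample(8, 1)
    got <- mrmr_rank(as_synergy(W), t0)
    want <- o_mrmr(W, t0)
    expect_identical(got$node, as.integer(want[, 1]))
    expect_equal(got$score, want[, 2], tolerance = 1e-12)
  }
})

test_that("network inference keeps positive symmetrized scores only", {
  # equal positive synergies: every target's first pick scores u = 0.4 > 0,
  # later picks score u - r = 0 and are pruned, leaving a star on snp01
  W <- matrix(0.4, 4, 4); diag(W) <- 0
  g <- infer_network(as_synergy(W))
  expect_identical(nrow(g$edges), 3L)
  expect_true(all(g$edges$from == "snp01"))
  expect_equal(g$edges$weight, rep(0.4, 3))
  # non-positive synergies: edgeless graph, nodes retained
  Wn <- matrix(-0.2, 4, 4); diag(Wn) <- 0
  gn <- infer_network(as_synergy(Wn))
  expect_identical(nrow(gn$edges), 0L)
  expect_length(gn$nodes, 4L)
})

test_that("network inference equals the two-pass MRNET oracle", {
  withr::local_seed(59)
  for (rep in 1:8) {
    W <- rand_symmetric(6)
    g <- infer_network(as_synergy(W))
    want <- o_mrnet_edges(W)
    ids <- sprintf("snp%02d", 1:6)
    if (is.null(want)) {
      expect_identical(nrow(g$edges), 0L)
    } else {
      got <- g$edges[order(g$edges$from, g$edges$to), ]
      ord <- order(ids[want[, 1]], ids[want[, 2]])
      expect_identical(got$from, ids[want[ord, 1]])
      expect_identical(got$to, ids[want[ord, 2]])
      expect_equal(got$weight, want[ord, 3], tolerance = 1e-12)
    }
  }
})

test_that("edge sets are invariant to positive rescaling of the synergies", {
  withr::local_seed(61)
  W <- rand_symmetric(7)
  e1 <- infer_network(as_synergy(W))$edges
  e2 <- infer_network(as_synergy(3.7 * W))$edges
  expect_identical(e1[, c("from", "to")], e2[, c("from", "to")])
  expect_equal(e2$weight, 3.7 * e1$weight, tolerance = 1e-12)
})

test_that("network inference is equivariant under node relabeling", {
  withr::local_seed(67)
  W <- rand_symmetric(6)
  perm <- sample(6)
  Wp <- W[perm, perm]
  ids <- sprintf("snp%02d", 1:6)
  e1 <- infer_network(as_synergy(W))$edges
  ep <- infer_network(structure(Wp, dimnames = list(ids[perm], ids[perm]),
                                class = c("synergy_matrix", "matrix")))$edges
  canon <- function(e) {
    pairs <- cbind(pmin(e$from, e$to), pmax(e$from, e$to))
    o <- order(pairs[, 1], pairs[, 2])
    data.frame(a = pairs[o, 1], b = pairs[o, 2], w = e$weight[o])
  }
  expect_equal(canon(e1), canon(ep), tolerance = 1e-12)
})

test_that("network statistics match hand counts on canonical graphs", {
  tri <- structure(list(gene_id = "t", nodes = c("a", "b", "c"),
                        edges = data.frame(from = c("a", "a", "b"),
                                           to = c("b", "c", "c"),
                                           weight = 1)),
                   class = "gene_graph")
  p <- network_properties(tri)
  expect_equal(p$density, 1.0)
  expect_equal(p$mean_distance, 1.0)
  expect_equal(p$transitivity, 1.0)
  path <- structure(list(gene_id = "p", nodes = c("a", "b", "c"),
                         edges = data.frame(from = c("a", "b"),
                                            to = c("b", "c"),
                                            weight = 1)),
                    class = "gene_graph")
  q <- network_properties(path)
  expect_equal(q$density, 2 / 3)
  expect_equal(q$mean_distance, 4 / 3)
  expect_equal(q$transitivity, 0.0)
  # undefined statistics are flagged as NA, not errors
  empty <- structure(list(gene_id = "e", nodes = c("a", "b"),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = numeric())),
                     class = "gene_graph")
  e <- network_properties(empty)
  expect_identical(e$mean_distance, NA_real_)
  expect_identical(e$transitivity, NA_real_)
})

test_that("network statistics agree with the BFS/triple-count oracle", {
  withr::local_seed(71)
  for (rep in 1:5) {
    m <- 10
    A <- matrix(0L, m, m)
    A[upper.tri(A)] <- rbinom(m * (m - 1) / 2, 1, 0.3)
    edges <- which(A == 1L, arr.ind = TRUE)
    ids <- sprintf("n%02d", 1:m)
    g <- structure(list(gene_id = "r", nodes = ids,
                        edges = data.frame(from = ids[edges[, 1]],
                                           to = ids[edges[, 2]],
                                           weight = 1)),
                   class = "gene_graph")
    got <- network_properties(g)
    want <- o_graph_stats(m, edges)
    expect_equal(got$density, want$density)
    expect_equal(got$mean_distance, want$mean_distance)
    expect_equal(got$transitivity, want$transitivity)
  }
})

test_that("distances count hops even when edges carry synergy weights", {
  # small positive weights must not turn into path lengths
  path <- structure(list(gene_id = "w", nodes = c("a", "b", "c"),
                         edges = data.frame(from = c("a", "b"),
                                            to = c("b", "c"),
                                            weight = c(0.003, 0.008))),
                    class = "gene_graph")
  p <- network_properties(path)
  expect_equal(p$mean_distance, 4 / 3)
  withr::local_seed(191)
  for (rep in 1:3) {
    g <- infer_network(as_synergy(rand_symmetric(7, scale = 0.02)))
    if (nrow(g$edges) == 0) next
    idx <- match(c(g$edges$from, g$edges$to), g$nodes)
    edges <- matrix(idx, ncol = 2)
    want <- o_graph_stats(7, edges)
    got <- network_properties(g)
    expect_equal(got$mean_distance, want$mean_distance)
    expect_equal(got$transitivity, want$transitivity)
    expect_equal(got$density, want$density)
  }
})

test_that("trees have zero transitivity", {
  star <- structure(list(gene_id = "s", nodes = c("h", "x", "y", "z"),
                         edges = data.frame(from = "h", to = c("x", "y", "z"),
                                            weight = 1)),
                    class = "gene_graph")
  expect_equal(network_properties(star)$transitivity, 0.0)
})

test_that("the properties table mirrors per-gene statistics", {
  withr::local_seed(73)
  graphs <- lapply(c(a = 4, b = 5), function(m) {
    g <- infer_network(as_synergy(rand_symmetric(m), gene = paste0("g", m)))
    g
  })
  tab <- network_properties_table(graphs)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$n_snps, c(4L, 5L))
  dir <- withr::local_tempdir()
  write_gene_graph(graphs[[1]], file.path(dir, "g.graphml"), "graphml")
  gr <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(as.numeric(igraph::vcount(gr)), 4)
  expect_equal(as.numeric(igraph::ecount(gr)),
               as.numeric(nrow(graphs[[1]]$edges)))
})
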