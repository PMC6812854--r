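test_that("average degree and diameter match hand values", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(degreeDiameter(p4), list(avg_degree = 1.5, diameter = 3))
  c5 <- igraph::make_ring(5)
  expect_equal(degreeDiameter(c5), list(avg_degree = 2, diameter = 2))
  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(degreeDiameter(star), list(avg_degree = 10 / 6, diameter = 2))
})

test_that("power-law fitting recovers a known exponent and rejects misfits", {
  x <- rPowerLaw(5000, alpha = 2.5, seed = 101)
  f <- fitPowerLaw(x, reps = 50, seed = 1)
  expect_lt(abs(f$alpha - 2.5), 0.1)
  expect_gt(f$ks_p, 0.05)
  expect_gte(f$xmin, 1)
  # strictly geometric data are rejected under a forced xmin = 1
  g <- withr::with_seed(7, stats::rgeom(5000, 0.4) + 1)
  fg <- fitPowerLaw(g, xmin = 1, reps = 50, seed = 1)
  expect_lt(fg$ks_p, 0.05)
  # deterministic given the seed
  f2 <- fitPowerLaw(x, reps = 50, seed = 1)
  expect_identical(f$ks_p, f2$ks_p)
  expect_error(fitPowerLaw(rep(3, 100)), "degenerate")
  expect_error(fitPowerLaw(c(-1, 2, 3)), "positive")
  expect_warning(fitPowerLaw(c(1, 1, 2, 3, 9), reps = 5), "fewer than 50")
})

test_that("rank von Neumann statistic matches hand computation", {
  # strictly increasing series of length 10: sum of squared rank
  # differences = 9, centered rank sum of squares = 82.5
  b <- bartelsRankTest(1:10)
  expect_equal(b$rvn, 9 / 82.5)
  expect_lt(b$statistic, -2)
  expect_lt(b$p_value, 0.05)
  expect_error(bartelsRankTest(rep(2, 20)), "constant")
  expect_error(bartelsRankTest(1:5), "at least 10")
})

test_that("rank von Neumann ratio has null expectation 2", {
  rvns <- withr::with_seed(500, vapply(1:1000, function(i)
    bartelsRankTest(sample(1:50))$rvn, numeric(1)))
  expect_lt(abs(mean(rvns) - 2), 0.05)
})

test_that("beta p-values track the permutation distribution", {
  x <- withr::with_seed(31, stats::rnorm(30))
  obs <- bartelsRankTest(x)
  perm <- withr::with_seed(32, vapply(1:10000, function(i)
    bartelsRankTest(sample(x))$rvn, numeric(1)))
  p_perm <- mean(abs(perm - 2) >= abs(obs$rvn - 2))
  expect_lt(abs(obs$p_value - p_perm), 0.02)
})

test_that("G(n,m) sampling is exact in n and m", {
  expect_equal(igraph::ecount(erRandomGraph(5, 10, seed = 1)), 10)  # K5
  expect_equal(igraph::ecount(erRandomGraph(10, 0, seed = 1)), 0)
  for (s in 1:25) {
    g <- erRandomGraph(30, 45, seed = s)
    expect_equal(igraph::vcount(g), 30)
    expect_equal(igraph::ecount(g), 45)
    expect_true(igraph::is_simple(g))
  }
  expect_error(erRandomGraph(5, 11, seed = 1), "must lie in")
  # same seed, same graph
  expect_identical(igraph::as_edgelist(erRandomGraph(20, 30, seed = 4)),
                   igraph::as_edgelist(erRandomGraph(20, 30, seed = 4)))
})

test_that("small-world coefficients behave on reference graphs", {
  k10 <- igraph::make_full_graph(10)
  sw <- smallWorld(k10, nRand = 5, seed = 1)
  expect_equal(sw$c_g, 1)
  expect_equal(sw$l_g, 1)
  # bipartite input is refused
  B <- igraph::make_bipartite_graph(c(0, 0, 1, 1), c(1, 3, 2, 4, 1, 4))
  expect_error(smallWorld(B), "bipartite")
  # ER self-comparison sits near 1, Watts-Strogatz well above; the ordering
  # is preserved across seeds
  for (s in c(2, 3)) {
    er <- erRandomGraph(300, 1500, seed = s)
    ws <- withr::with_seed(s, igraph::sample_smallworld(1, 300, 5, 0.05))
    s_er <- smallWorld(er, nRand = 10, seed = s)$s
    s_ws <- smallWorld(ws, nRand = 10, seed = s)$s
    expect_gt(s_er, 0.8); expect_lt(s_er, 1.2)
    expect_gt(s_ws, s_er)
  }
})

test_that("fast-greedy modularity finds the exhaustive optimum on small graphs", {
  # two triangles joined by one edge: optimum Q = 5/14 at the triangle cut
  tt <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                           a - d)
  md <- fastGreedyModularity(tt)
  expect_equal(md$q, 5 / 14)
  expect_equal(length(unique(md$membership)), 2)
  expect_equal(md$q, exhaustive_modularity(tt))
  # all-in-one partition of a clique has Q = 0
  expect_equal(modularityScore(igraph::make_full_graph(5), rep(1, 5)), 0)
  # returned Q always equals Q recomputed from the membership, and never
  # exceeds the exhaustive optimum on graphs with <= 8 nodes
  withr::with_seed(77, {
    for (i in 1:15) {
      g <- igraph::sample_gnp(sample(5:8, 1), 0.5)
      if (igraph::ecount(g) == 0) next
      g <- largestComponent(g)
      if (igraph::ecount(g) == 0 || igraph::vcount(g) < 3) next
      md <- fastGreedyModularity(g)
      expect_equal(md$q, modularityScore(g, md$membership))
      expect_lte(md$q, exhaustive_modularity(g) + 1e-12)
    }
  })
  expect_error(fastGreedyModularity(igraph::make_empty_graph(3,
                                                             directed = FALSE)),
               "no edges")
})

test_that("C(k) scaling detects hierarchical graphs and flat profiles", {
  # deterministic hierarchical (Ravasz-type) construction, 3 levels of
  # 5-node replication: C(k) ~ k^-1
  ravasz <- function(levels) {
    g <- igraph::make_full_graph(5)
    center <- 1L
    for (l in seq_len(levels - 1)) {
      n <- igraph::vcount(g)
      big <- igraph::disjoint_union(replicate(5, g, simplify = FALSE))
      # node ids of copy k are (k-1)*n + 1..n; copy 1 is the new center
      peripheral <- unlist(lapply(2:5, function(k)
        (k - 1L) * n + setdiff(seq_len(n), center)))
      big <- igraph::add_edges(big, rbind(center, peripheral))
      g <- big
    }
    g
  }
  fit <- ckScaling(ravasz(3))
  expect_lt(abs(fit$slope - (-1)), 0.25)
  expect_gt(fit$r2, 0.8)
  # complete graph: single degree class, all clustering 1, flat profile
  flat <- ckScaling(igraph::make_full_graph(6))
  expect_equal(flat$slope, 0)
  # trees have zero clustering everywhere -> error
  expect_error(ckScaling(igraph::make_tree(15, 2, mode = "undirected")),
               "clustering")
})

test_that("centrality rankings match brute-force values and tie rules", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:6))
  ct <- centralityTable(star, k = 3)
  top1 <- ct$top$node[ct$top$rank == 1]
  expect_equal(unique(top1), "hub")
  # P5 middle node lies on 4 shortest paths
  p5 <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  m <- centralityTable(p5)$metrics
  expect_equal(m$betweenness[m$node == "c"], 4)
  # symmetric nodes are ordered lexicographically
  p2 <- igraph::make_graph(~ b - a)
  expect_equal(centralityTable(p2, k = 2)$top$node[1:2], c("a", "b"))
})

test_that("the metrics timeline covers every slice and graph type", {
  ds <- simulateStructure(simulationConfig(seed = 17, nEnzymes = 250))
  ages <- enzymeAges(ds)
  tl <- metricsTimeline(ds, ages, nRand = 4, reps = 10, seed = 1)
  expect_equal(nrow(tl), 30)
  expect_setequal(unique(tl$graph_type),
                  c("bipartite", "subnetwork_projection",
                    "enzyme_projection"))
  # bipartite rows omit clustering-based fields
  bip <- tl[tl$graph_type == "bipartite", ]
  expect_true(all(is.na(bip$c_g)) && all(is.na(bip$s)))
  # projections get small-world numbers at the full slice
  enz <- tl[tl$graph_type == "enzyme_projection" & tl$nd == 1, ]
  expect_true(is.finite(enz$s) && enz$s > 0)
  expect_equal(enz$s, enz$gamma / enz$lambda)
  # every row has sizes and the ER Bartels companion where defined
  expect_true(all(is.finite(tl$n_nodes)))
  expect_true(all(is.finite(tl$bartels_stat[tl$n_nodes_lcc >= 10])))
  # deterministic given the seed
  tl2 <- metricsTimeline(ds, ages, nRand = 4, reps = 10, seed = 1)
  attr(tl, "log") <- attr(tl2, "log") <- NULL
  expect_identical(tl, tl2)
  # truncated timeline: only enzymes in era 1 -> single threshold rows
  young <- ages[ages <= 0.1]
  tl3 <- metricsTimeline(ds, young, ts = 0.1, nRand = 2, reps = 5,
                         seed = 1)
  expect_equal(unique(tl3$nd), 0.1)
})
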