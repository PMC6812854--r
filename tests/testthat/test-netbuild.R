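test_that("bipartite construction follows membership at both levels", {
  ds <- toy_dataset()
  ages <- enzymeAges(ds)
  B <- buildBipartite(ds, ages, "subnetwork")
  expect_equal(igraph::ecount(B), 4)       # 4 membership links
  expect_equal(igraph::vcount(B), 6)       # 3 maps + 3 enzymes
  expect_true(igraph::is_bipartite(B))
  # mesonetwork edges are the union over subnetworks
  M <- buildBipartite(ds, ages, "mesonetwork")
  el <- apply(igraph::as_edgelist(M), 1, paste, collapse = "-")
  expect_setequal(el, c("CAR-1.1.1.1", "CAR-2.2.2.2", "NUC-3.3.3.3"))
  # enzymes without membership never appear
  d <- rbind(domains(ds),
             data.frame(ec = "9.9.9.9", scop_ccs = "a.1.1.1", nd = 0.2))
  ds2 <- MetabolicDataset(d, memberships(ds), hierarchy(ds))
  B2 <- buildBipartite(ds2, enzymeAges(ds2), "subnetwork")
  expect_false("9.9.9.9" %in% igraph::V(B2)$name)
})

test_that("age slicing keeps young enzymes and drops empty categories", {
  ds <- toy_dataset()
  ages <- enzymeAges(ds)     # 1.1.1.1 -> 0.5, 2.2.2.2 -> 0.05, 3.3.3.3 -> 0.65
  B <- buildBipartite(ds, ages, "subnetwork")
  # t = 1 is the identity
  expect_equal(igraph::ecount(sliceByAge(B, 1.0)), igraph::ecount(B))
  # t = 0.1 keeps only enzyme 2.2.2.2 and its one edge; map00010 and
  # map00030 lose all enzymes and are dropped
  s <- sliceByAge(B, 0.1)
  expect_setequal(igraph::V(s)$name, c("map00020", "2.2.2.2"))
  expect_equal(igraph::ecount(s), 1)
  # t below every age -> empty graph
  expect_equal(igraph::vcount(sliceByAge(B, 0.01)), 0)
})

test_that("slices grow monotonically along the timeline", {
  ds <- simulateStructure(simulationConfig(seed = 8, nEnzymes = 200))
  ages <- enzymeAges(ds)
  B <- buildBipartite(ds, ages, "subnetwork")
  prev_v <- character(0); prev_e <- character(0)
  prev_pv <- character(0); prev_pe <- character(0)
  for (t in seq(0.1, 1, 0.1)) {
    s <- sliceByAge(B, t)
    v <- igraph::V(s)$name
    e <- apply(igraph::as_edgelist(s), 1, paste, collapse = "|")
    expect_true(all(prev_v %in% v))
    expect_true(all(prev_e %in% e))
    p <- projectOneMode(s, "category")
    pv <- igraph::V(p)$name
    pe <- apply(igraph::as_edgelist(p), 1, function(r)
      paste(sort(r), collapse = "|"))
    expect_true(all(prev_pv %in% pv))
    expect_true(all(prev_pe %in% pe))
    prev_v <- v; prev_e <- e; prev_pv <- pv; prev_pe <- pe
  }
})

test_that("one-mode projections carry shared-counterpart weights", {
  # e1 in {s1, s2}, e2 in {s2, s3}: subnetwork side s1-s2, s2-s3; enzyme
  # side e1-e2 through s2
  inc <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), c("e1", "e2")))
  B <- igraph::graph_from_biadjacency_matrix(inc)
  cat_w <- projection_weight_matrix(projectOneMode(B, "category"),
                                    rownames(inc))
  expect_equal(cat_w, projection_weight_oracle(B, "category"))
  expect_equal(cat_w["s1", "s2"], 1)
  expect_equal(cat_w["s1", "s3"], 0)
  enz_w <- projection_weight_matrix(projectOneMode(B, "enzyme"),
                                    colnames(inc))
  expect_equal(enz_w["e1", "e2"], 1)
  # a single enzyme in k subnetworks projects to K_k with unit weights
  inc2 <- matrix(1, nrow = 4, ncol = 1,
                 dimnames = list(paste0("s", 1:4), "e1"))
  p2 <- projectOneMode(igraph::graph_from_biadjacency_matrix(inc2),
                       "category")
  expect_equal(igraph::ecount(p2), 6)
  expect_true(all(igraph::E(p2)$weight == 1))
})

test_that("projection weights equal the biadjacency self-product", {
  withr::with_seed(99, {
    for (i in 1:40) {
      nc <- sample(2:6, 1); ne <- sample(2:6, 1)
      B <- random_bipartite_fixture(nc, ne)
      for (side in c("category", "enzyme")) {
        nodes <- igraph::V(B)$name[igraph::V(B)$type ==
                                     (side == "enzyme")]
        W <- projection_weight_matrix(projectOneMode(B, side), nodes)
        O <- projection_weight_oracle(B, side)[nodes, nodes]
        expect_equal(W, O)
        expect_true(isSymmetric(W))
        expect_true(all(W == floor(W)) && all(W >= 0))
      }
    }
  })
})

test_that("mesonetwork graph equals the contracted subnetwork graph", {
  ds <- simulateStructure(simulationConfig(seed = 13, nEnzymes = 120))
  ages <- enzymeAges(ds)
  M <- buildBipartite(ds, ages, "mesonetwork")
  S <- buildBipartite(ds, ages, "subnetwork")
  h <- hierarchy(ds)
  el <- igraph::as_edgelist(S)
  contracted <- unique(data.frame(
    cat = h$meso_code[match(el[, 1], h$map_id)], ec = el[, 2]))
  got <- igraph::as_edgelist(M)
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(contracted$cat, contracted$ec))
})

test_that("largest component selection breaks ties lexicographically", {
  g <- igraph::make_graph(~ a - b, b - c, x - y, y - z, p - q)
  lc <- largestComponent(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c"))
  # connected graph returns itself
  ring <- igraph::make_ring(5)
  expect_equal(igraph::vcount(largestComponent(ring)), 5)
  expect_error(largestComponent(igraph::make_empty_graph(0)), "empty")
})

test_that("reduced representations threshold weights and scale greyscale", {
  g <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(g)$weight <- c(1, 5, 10)
  r <- reduceRepresentation(g, minWeight = 5)
  expect_equal(igraph::ecount(r), 2)
  expect_equal(sort(igraph::E(r)$greyscale), c(0.5, 1.0))
  expect_false("a" %in% igraph::V(r)$name)   # isolated after thresholding
  # minWeight 1 keeps everything; uniform weights -> all greyscale 1
  g2 <- igraph::make_ring(4)
  igraph::E(g2)$weight <- rep(3, 4)
  r2 <- reduceRepresentation(g2, minWeight = 1)
  expect_equal(igraph::ecount(r2), 4)
  expect_true(all(igraph::E(r2)$greyscale == 1))
  expect_warning(reduceRepresentation(g, minWeight = 100), "removes all")
})
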