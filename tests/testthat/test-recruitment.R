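test_that("sharing matrix counts enzymes per subnetwork and era", {
  ds <- toy_dataset()
  ages <- enzymeAges(ds)
  sm <- sharingMatrix(ds, ages)
  # enzyme 1.1.1.1 (age 0.5) sits in both map00010 and map00020
  expect_equal(sm["map00010", "era_5"], 1L)
  expect_equal(sm["map00020", "era_5"], 1L)
  expect_equal(sm["map00020", "era_1"], 1L)
  # row sums = distinct enzymes per subnetwork
  m <- memberships(ds)
  expect_equal(unname(rowSums(sm)[m$map_id[1]]),
               length(unique(m$ec[m$map_id == m$map_id[1]])))
  # rows grouped by mesonetwork
  expect_equal(unname(attr(sm, "meso_code")),
               c("CAR", "CAR", "NUC"))
  # synthetic defaults: biphasic column profile
  ds2 <- simulateStructure(simulationConfig(seed = 4))
  sm2 <- sharingMatrix(ds2, enzymeAges(ds2))
  cols <- colSums(sm2)
  expect_equal(which.max(cols), c(era_1 = 1L))
  late <- vapply(6:8, function(i) cols[i] > cols[i - 1] &&
                   cols[i] > cols[i + 1], logical(1))
  expect_true(any(late))
})

test_that("mesonetwork link weights equal the projection weights at every t", {
  ds <- simulateStructure(simulationConfig(seed = 6, nEnzymes = 150))
  ages <- enzymeAges(ds)
  ml <- mesoLinkTable(ds, ages)
  B <- buildBipartite(ds, ages, "mesonetwork")
  for (t in c(0.2, 0.5, 1.0)) {
    proj <- projectOneMode(sliceByAge(B, t), "category")
    nodes <- sort(igraph::V(proj)$name)
    W <- projection_weight_matrix(proj, nodes)
    sub <- ml[ml$t == t, ]
    # every tabulated pair matches the projection weight...
    for (i in seq_len(nrow(sub)))
      expect_equal(sub$weight[i], W[sub$meso1[i], sub$meso2[i]])
    # ...and no projection edge is missed
    expect_equal(nrow(sub), sum(W[upper.tri(W)] > 0))
  }
  # weights monotone non-decreasing in t
  key <- paste(ml$meso1, ml$meso2)
  for (k in unique(key)) {
    w <- ml$weight[key == k][order(ml$t[key == k])]
    expect_true(all(diff(w) >= 0))
  }
})

test_that("Ward clustering merges by squared Euclidean cost", {
  # identical rows merge first at height 0
  M <- rbind(a = c(0, 1, 0), b = c(0, 1, 0), c = c(5, 5, 5))
  hc <- wardCluster(M)
  expect_equal(hc$height[1], 0)
  # first merge joins the identical rows a and b
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  # rows embedded at 0, 1, 10 on a line: cheapest Ward merge is {0, 1}
  M2 <- matrix(rep(c(0, 1, 10), 3), ncol = 3,
               dimnames = list(c("x0", "x1", "x10"), NULL))
  hc2 <- wardCluster(M2)
  expect_setequal(hc2$labels[-hc2$merge[1, ]], c("x0", "x1"))
  # merge heights are monotone non-decreasing
  ds <- simulateStructure(simulationConfig(seed = 10, nEnzymes = 150))
  B <- buildBipartite(ds, enzymeAges(ds), "subnetwork")
  lcc <- largestComponent(projectOneMode(B, "category"))
  A <- as.matrix(igraph::as_adjacency_matrix(lcc, attr = "weight",
                                             sparse = FALSE))
  hc3 <- wardCluster(A)
  expect_true(all(diff(hc3$height) >= -1e-9))
  # permuting rows changes labels, not merge heights (tie-free matrix:
  # integer co-membership counts can tie, so use continuous test data)
  M3 <- matrix(stats::rnorm(49), 7, 7,
               dimnames = list(letters[1:7], letters[1:7]))
  M3 <- M3 + t(M3)
  perm <- c(4, 1, 6, 2, 7, 3, 5)
  expect_equal(sort(wardCluster(M3[perm, perm])$height),
               sort(wardCluster(M3)$height))
  expect_error(wardCluster(matrix(1, 2, 3)), "square")
  # Newick export round-trips through ape
  nwk <- exportNewick(hc3)
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("modularity heatmap matrix follows B = A - kk^T/2m", {
  # single edge: off-diagonal 0.5, diagonal -0.5 before scaling
  g <- igraph::make_graph(~ a - b)
  hm <- modularityHeatmapMatrix(g)
  expect_equal(sort(unique(as.numeric(hm))), c(-1, 1))
  expect_equal(hm["a", "b"], 1)
  expect_equal(hm["a", "a"], -1)
  # rows of the unscaled matrix sum to zero; symmetry; scaling to [-1, 1]
  g2 <- largestComponent(igraph::sample_gnp(12, 0.4))
  A <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
  k <- rowSums(A)
  Bm <- A - outer(k, k) / sum(A)
  expect_equal(rowSums(Bm), rep(0, nrow(A)), ignore_attr = TRUE)
  hm2 <- modularityHeatmapMatrix(g2, weighted = FALSE)
  expect_true(isSymmetric(unname(unclass(hm2[, ]))))
  expect_equal(max(abs(hm2)), 1)
  ord <- attr(hm2, "order")
  expect_equal(unname(hm2), unname(Bm[ord, ord] / max(abs(Bm))),
               ignore_attr = TRUE)
  expect_error(modularityHeatmapMatrix(
    igraph::make_empty_graph(2, directed = FALSE)), "no edges")
})

test_that("Venn vocabulary enumerates all 15 nonempty subsets", {
  v <- vennGroups()
  expect_length(v, 15)
  expect_length(unique(v), 15)
  expect_true(all(c("A", "B", "E", "V", "AB", "BE", "ABE", "ABEV") %in% v))
})

test_that("Venn assignment applies the revision consensus rule", {
  taxa <- data.frame(
    ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "3.3.3.1", "3.3.3.2",
           "4.4.4.1", "4.4.4.2"),
    species = paste0("sp", 1:7),
    superkingdom = c("E", "B", "A", "B", "B", "B", "E"))
  v <- vennAssign(taxa)
  expect_equal(unname(v["1.1.1.1"]), "BE")
  expect_equal(unname(v["2.2.2.2"]), "A")
  # revised EC with agreeing successors inherits their label
  rev <- data.frame(old_ec = c("9.9.9.9", "8.8.8.8", "8.8.8.8"),
                    new_ec = c("3.3.3.1", "4.4.4.1", "4.4.4.2"))
  rev <- rbind(rev, data.frame(old_ec = "9.9.9.9", new_ec = "3.3.3.2"))
  v2 <- vennAssign(taxa, rev)
  expect_equal(unname(v2["9.9.9.9"]), "B")
  # disagreeing successors -> excluded
  expect_false("8.8.8.8" %in% names(v2))
  expect_equal(attr(v2, "excluded"), "8.8.8.8")
  expect_true(all(v2 %in% vennGroups()))
  expect_error(vennAssign(data.frame(ec = "1", superkingdom = "X")),
               "unknown superkingdom")
})

test_that("functional distributions count distinct categories per enzyme", {
  ds <- toy_dataset()
  ages <- enzymeAges(ds)
  fun <- data.frame(fsf_id = c("c.1.1", "d.2.1", "b.1.1"),
                    general = c("Metabolism", "Metabolism", "Regulation"),
                    detailed = c("Met_d1", "Met_d2", "Reg_d1"))
  venn <- c("1.1.1.1" = "BE", "2.2.2.2" = "BE", "3.3.3.3" = "B")
  fd <- functionalDistribution(ds, ages, functions = fun, venn = venn)
  # 1.1.1.1 has two Metabolism domains -> one Metabolism count
  expect_equal(fd$general_by_venn["Metabolism", "BE"], 2)
  expect_equal(fd$general_by_venn["Regulation", "B"], 1)
  # distinct detailed categories both count
  expect_equal(sum(fd$detailed_by_era[c("Met_d1", "Met_d2"), ]), 3)
  # era column sums preserve annotated enzymes per category
  expect_equal(sum(fd$detailed_by_era["Reg_d1", ]), 1)
})

test_that("catalytic residues map to role groups and conserve totals", {
  expect_equal(residueRoleGroup(c("D", "K", "S", "L")),
               c("acidic", "basic", "polar_uncharged", "nonpolar"))
  expect_error(residueRoleGroup("Z"), "unknown residue.*Z")
  catal <- data.frame(ec = c("1.1.1.1", "1.1.1.1", "3.3.3.3"),
                      residue = c("D", "K", "G"))
  venn <- c("1.1.1.1" = "BE", "3.3.3.3" = "B")
  ages <- enzymeAges(toy_dataset())
  cd <- catalyticDistribution(catal, venn, ages)
  expect_equal(cd$by_venn["acidic", "BE"], 1)
  expect_equal(cd$by_venn["basic", "BE"], 1)
  expect_equal(cd$by_venn["polar_uncharged", "B"], 1)
  # totals invariant under a different era width
  cd2 <- catalyticDistribution(catal, venn, ages, width = 0.2)
  expect_equal(sum(cd$by_era), sum(cd2$by_era))
  # charged share dominates under charged-favouring generator weights
  dss <- simulateDataset(simulationConfig(seed = 15, nEnzymes = 400))
  cat_tab <- annotations(dss)$catalysis
  share <- mean(cat_tab$residue %in% c("D", "E", "K", "R", "H"))
  expect_gt(share, 0.5)
})
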