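# tiny deterministic fixtures used across the suite

toy_dataset <- function() {
  MetabolicDataset(
    domains = data.frame(
      ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "3.3.3.3"),
      scop_ccs = c("c.1.1.1", "d.2.1.1", "c.1.1.1", "b.1.1.1"),
      nd = c(0.05, 0.5, 0.05, 0.65),
      stringsAsFactors = FALSE),
    membership = data.frame(
      ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "3.3.3.3"),
      map_id = c("map00010", "map00020", "map00020", "map00030"),
      stringsAsFactors = FALSE),
    hierarchy = data.frame(
      map_id = c("map00010", "map00020", "map00030"),
      map_name = c("Toy glycolysis", "Toy TCA", "Toy purine"),
      meso_code = c("CAR", "CAR", "NUC"),
      stringsAsFactors = FALSE))
}

# incidence-matrix oracle for one-mode projection weights: W = B B^T with a
# zeroed diagonal, rows = side nodes
projection_weight_oracle <- function(bip, side = c("category", "enzyme")) {
  side <- match.arg(side)
  inc <- igraph::as_biadjacency_matrix(bip, sparse = FALSE)
  if (side == "enzyme") inc <- t(inc)
  W <- inc %*% t(inc)
  diag(W) <- 0
  W
}

# weights of a projection graph as a symmetric matrix over given node names
projection_weight_matrix <- function(proj, nodes) {
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (igraph::ecount(proj) > 0) {
    el <- igraph::as_edgelist(proj)
    w <- igraph::E(proj)$weight
    for (i in seq_len(nrow(el))) {
      W[el[i, 1], el[i, 2]] <- w[i]
      W[el[i, 2], el[i, 1]] <- w[i]
    }
  }
  W
}

random_bipartite_fixture <- function(n_cat, n_enz, p = 0.4) {
  repeat {
    inc <- matrix(stats::rbinom(n_cat * n_enz, 1, p), n_cat, n_enz)
    if (sum(inc) > 0 && all(colSums(inc) > 0)) break
  }
  rownames(inc) <- sprintf("c%02d", seq_len(n_cat))
  colnames(inc) <- sprintf("e%02d", seq_len(n_enz))
  igraph::graph_from_biadjacency_matrix(inc)
}

# exhaustive best modularity over all partitions of small graphs
exhaustive_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- list(c(1L))
  for (i in seq_len(n - 1L)) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(k) c(p, k))
    }), recursive = FALSE)
  }
  max(vapply(parts, function(p) igraph::modularity(g, p), numeric(1)))
}

table5_domains <- function() {
  read.delim(system.file("extdata", "central_enzyme_domains.tsv",
                         package = "metanet"),
             stringsAsFactors = FALSE)
}
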