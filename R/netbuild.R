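#' Build the category-enzyme bipartite network
#'
#' Constructs the two-mode graph linking enzymes to pathway categories at
#' either the subnetwork level (one node per KEGG map) or the mesonetwork
#' level (one node per meso code; an enzyme links to a mesonetwork when it
#' belongs to any of its subnetworks). Category nodes carry
#' \code{type = FALSE}, enzyme nodes \code{type = TRUE} and an \code{age}
#' vertex attribute. Categories without member enzymes are not included, and
#' enzymes need both a membership and an assigned age to appear.
#'
#' The mesonetwork-subnetwork bipartite network is deliberately not built;
#' it carries no enzyme-sharing information.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param ages named nd vector from \code{\link{enzymeAges}}; every enzyme in
#'   the graph must be aged.
#' @param level \code{"subnetwork"} or \code{"mesonetwork"}.
#' @return An igraph bipartite graph with graph attributes \code{level} and
#'   \code{t} (= 1, the full timeline).
#' @seealso \code{\link{sliceByAge}}, \code{\link{projectOneMode}}
#' @export
buildBipartite <- function(ds, ages,
                           level = c("subnetwork", "mesonetwork")) {
  level <- match.arg(level)
  m <- memberships(ds)
  m <- m[m$ec %in% names(ages), , drop = FALSE]
  if (level == "mesonetwork") {
    h <- hierarchy(ds)
    cat_id <- h$meso_code[match(m$map_id, h$map_id)]
  } else {
    cat_id <- m$map_id
  }
  edges <- unique(data.frame(cat = cat_id, ec = m$ec,
                             stringsAsFactors = FALSE))
  cats <- sort(unique(edges$cat))
  ecs <- sort(unique(edges$ec))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(cats), name = cats, type = FALSE)
  g <- igraph::add_vertices(g, length(ecs), name = ecs, type = TRUE,
                            age = unname(ages[ecs]))
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(match(edges$cat, cats),
                                    length(cats) + match(edges$ec, ecs)))
  g <- igraph::set_graph_attr(g, "level", level)
  igraph::set_graph_attr(g, "t", 1)
}

#' Restrict a bipartite network to enzymes of age <= t
#'
#' Applying the age criterion along the timeline yields a series of growing
#' bipartite networks. Enzymes older than \code{t} are removed together with
#' their edges; category nodes left without enzymes are dropped.
#'
#' @param B bipartite igraph from \code{\link{buildBipartite}}.
#' @param t nd threshold in [0, 1].
#' @return The sliced bipartite igraph (graph attribute \code{t} updated).
#' @export
sliceByAge <- function(B, t) {
  stopifnot(t >= 0, t <= 1)
  vt <- igraph::V(B)$type
  age <- igraph::V(B)$age
  drop <- which(vt & (is.na(age) | age > t))
  g <- igraph::delete_vertices(B, drop)
  iso_cat <- which(!igraph::V(g)$type & igraph::degree(g) == 0L)
  g <- igraph::delete_vertices(g, iso_cat)
  igraph::set_graph_attr(g, "t", t)
}

#' One-mode projection of a bipartite network
#'
#' Projects the two-mode graph onto one of its sides; two same-side nodes
#' are linked iff they share at least one counterpart, with integer edge
#' weight equal to the number of shared counterparts (no normalization).
#' Nodes sharing nothing stay as isolated vertices (they count in node
#' totals but not in largest-component statistics).
#'
#' @param B bipartite igraph from \code{\link{buildBipartite}} /
#'   \code{\link{sliceByAge}}.
#' @param side \code{"category"} or \code{"enzyme"}.
#' @return Weighted undirected igraph with graph attributes \code{side},
#'   \code{level} and \code{t}.
#' @export
projectOneMode <- function(B, side = c("category", "enzyme")) {
  side <- match.arg(side)
  if (is.null(igraph::V(B)$type))
    stop("input graph is not two-mode (no 'type' attribute)", call. = FALSE)
  pr <- igraph::bipartite_projection(B, multiplicity = TRUE)
  g <- if (side == "category") pr$proj1 else pr$proj2
  if (igraph::ecount(g) == 0L)
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  g <- igraph::set_graph_attr(g, "side", side)
  g <- igraph::set_graph_attr(g, "level",
                              igraph::graph_attr(B, "level"))
  igraph::set_graph_attr(g, "t", igraph::graph_attr(B, "t"))
}

#' Largest connected component
#'
#' Returns the node-maximal connected subgraph; when several components tie
#' on size the one containing the lexicographically smallest vertex name
#' wins.
#'
#' @param G an igraph.
#' @return The induced subgraph on the largest component.
#' @export
largestComponent <- function(G) {
  if (igraph::vcount(G) == 0L)
    stop("graph is empty", call. = FALSE)
  comp <- igraph::components(G)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    nm <- igraph::V(G)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(G)))
    first_name <- vapply(best, function(b)
      min(nm[comp$membership == b]), character(1))
    best <- best[order(first_name)][1L]
  }
  igraph::induced_subgraph(G, which(comp$membership == best))
}

#' Threshold a weighted projection into a reduced representation
#'
#' Drops edges below \code{minWeight} (and nodes left isolated) and attaches
#' a \code{greyscale} edge attribute: weight divided by the maximum retained
#' weight, so the strongest sharing maps to 1 (black) and weaker links fade
#' toward white.
#'
#' @param G weighted projection graph.
#' @param minWeight minimum retained edge weight (>= 1).
#' @return The reduced igraph with a \code{greyscale} edge attribute; if the
#'   threshold removes every edge a warning is raised and the empty graph
#'   returned.
#' @export
reduceRepresentation <- function(G, minWeight = 1) {
  stopifnot(minWeight >= 1)
  w <- igraph::E(G)$weight
  g <- igraph::delete_edges(G, which(w < minWeight))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  if (igraph::ecount(g) == 0L) {
    warning("min_weight = ", minWeight, " removes all edges", call. = FALSE)
    return(igraph::set_edge_attr(g, "greyscale", value = numeric(0)))
  }
  wk <- igraph::E(g)$weight
  igraph::set_edge_attr(g, "greyscale", value = wk / max(wk))
}

#' Write a weighted edge list as TSV
#'
#' @param G igraph with (optionally) a \code{weight} edge attribute.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(G, path) {
  el <- igraph::as_edgelist(G)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   stringsAsFactors = FALSE)
  df$weight <- if (is.null(igraph::E(G)$weight)) 1L else igraph::E(G)$weight
  df <- df[order(df$source, df$target), , drop = FALSE]
  .write_tsv(df, path)
  invisible(path)
}
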