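#' Subnetwork-by-era enzyme sharing matrix
#'
#' Cell (s, era) counts the enzymes belonging to subnetwork s whose assigned
#' age falls in that era; an enzyme contributes to exactly one era per
#' subnetwork it belongs to, so each row sums to the subnetwork's distinct
#' enzyme count. Rows are ordered by mesonetwork (hierarchy order) then
#' map_id; row names are map ids and the \code{"meso_code"} attribute gives
#' their grouping.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param width era width (default 0.1).
#' @return Integer matrix (subnetworks x eras) with attribute
#'   \code{meso_code}.
#' @export
sharingMatrix <- function(ds, ages, width = 0.1) {
  h <- hierarchy(ds)
  m <- memberships(ds)
  m <- m[m$ec %in% names(ages), , drop = FALSE]
  h <- h[order(match(h$meso_code, unique(h$meso_code)), h$map_id), ,
         drop = FALSE]
  k <- nEras(width)
  out <- matrix(0L, nrow = nrow(h), ncol = k,
                dimnames = list(h$map_id, paste0("era_", seq_len(k))))
  if (nrow(m) > 0L) {
    era <- binToEra(ages[m$ec], width)
    tab <- table(factor(m$map_id, levels = h$map_id),
                 factor(era, levels = seq_len(k)))
    out[] <- as.integer(tab)
  }
  attr(out, "meso_code") <- stats::setNames(h$meso_code, h$map_id)
  out
}

#' Mesonetwork pair sharing along the timeline
#'
#' For each threshold t, counts the enzymes of age <= t belonging to both
#' mesonetworks of every pair; these are exactly the edge weights of the
#' mesonetwork one-mode projection of the age-sliced bipartite network, and
#' they grow monotonically in t.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param ts thresholds (default \code{seq(0.1, 1, 0.1)}).
#' @return data.frame with columns \code{t}, \code{meso1}, \code{meso2}
#'   (meso1 < meso2), \code{weight}; pairs sharing nothing are absent.
#' @export
mesoLinkTable <- function(ds, ages, ts = seq(0.1, 1, 0.1)) {
  h <- hierarchy(ds)
  m <- memberships(ds)
  m <- m[m$ec %in% names(ages), , drop = FALSE]
  pairs <- unique(data.frame(
    ec = m$ec,
    meso = h$meso_code[match(m$map_id, h$map_id)],
    stringsAsFactors = FALSE))
  pairs$age <- ages[pairs$ec]
  out <- list()
  for (t in ts) {
    p <- pairs[pairs$age <= t, , drop = FALSE]
    byec <- split(p$meso, p$ec)
    byec <- byec[lengths(byec) >= 2L]
    if (length(byec) == 0L) next
    pp <- do.call(rbind, lapply(byec, function(ms) {
      ms <- sort(ms)
      t(utils::combn(ms, 2L))
    }))
    key <- paste(pp[, 1], pp[, 2], sep = "\t")
    tab <- table(key)
    sp <- strsplit(names(tab), "\t", fixed = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      t = t,
      meso1 = vapply(sp, `[`, character(1), 1L),
      meso2 = vapply(sp, `[`, character(1), 2L),
      weight = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(t = numeric(0), meso1 = character(0),
                      meso2 = character(0), weight = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$t, res$meso1, res$meso2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ward clustering of a weighted adjacency matrix
#'
#' Computes pairwise squared Euclidean dissimilarities between the rows of
#' the (symmetric) weighted adjacency matrix of a projection and
#' agglomerates them with classic Ward's method (Lance-Williams update on
#' the squared distances, i.e. \code{hclust(method = "ward.D")} on
#' \code{dist()^2}; the variant that squares internally would yield
#' different merge heights). Merge heights are non-decreasing.
#'
#' @param M square symmetric numeric matrix with >= 2 rows (row names kept
#'   as dendrogram labels).
#' @return An object of class \code{hclust}.
#' @seealso \code{\link{exportNewick}}, \code{\link{modularityHeatmapMatrix}}
#' @export
wardCluster <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M))
    stop("adjacency matrix must be square", call. = FALSE)
  if (nrow(M) < 2L)
    stop("need at least 2 rows to cluster", call. = FALSE)
  if (is.null(rownames(M)))
    rownames(M) <- colnames(M) <- as.character(seq_len(nrow(M)))
  d <- stats::dist(M)^2
  stats::hclust(d, method = "ward.D")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights (via
#' \code{ape::as.phylo}), so the tree is ultrametric.
#'
#' @param hc an \code{hclust} object.
#' @param path optional file to write to.
#' @return The Newick string, invisibly when \code{path} is given.
#' @export
exportNewick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Scaled modularity matrix in dendrogram leaf order
#'
#' The modularity matrix of a (weighted) graph is B = A - k k^T / (2m),
#' where A is the adjacency (weights if present), k the node strengths and m
#' the total edge weight; every row of B sums to zero. For heatmap display B
#' is divided by max|B| so entries range over [-1, 1], and rows/columns are
#' permuted into the leaf order of the Ward dendrogram of A (computed via
#' \code{\link{wardCluster}}) unless an ordering is supplied.
#'
#' @param G igraph with >= 1 edge.
#' @param weighted use edge weights if present (default); set FALSE for the
#'   binary adjacency.
#' @param order optional explicit row/column order (names or indices); by
#'   default the Ward leaf order.
#' @return Numeric matrix scaled to [-1, 1] with attribute \code{"order"}
#'   (the leaf order used).
#' @export
modularityHeatmapMatrix <- function(G, weighted = TRUE, order = NULL) {
  if (igraph::ecount(G) == 0L)
    stop("graph has no edges", call. = FALSE)
  attrib <- if (weighted && !is.null(igraph::E(G)$weight)) "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(G, attr = attrib,
                                             sparse = FALSE))
  if (is.null(rownames(A))) {
    nm <- igraph::V(G)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(G)))
    rownames(A) <- colnames(A) <- nm
  }
  k <- rowSums(A)
  two_m <- sum(A)
  B <- A - outer(k, k) / two_m
  Bs <- B / max(abs(B))
  if (is.null(order)) {
    ord <- if (nrow(A) >= 2L) {
      hc <- wardCluster(A)
      hc$labels[hc$order]
    } else rownames(A)
  } else {
    ord <- order
  }
  out <- Bs[ord, ord, drop = FALSE]
  attr(out, "order") <- ord
  out
}

#' All superkingdom Venn group labels
#'
#' The 15 nonempty subsets of \{Archaea, Bacteria, Eukarya, Viruses\}
#' rendered as concatenated sorted letters (A, B, E, V, AB, ..., ABEV).
#'
#' @return Character vector of 15 labels.
#' @export
vennGroups <- function() {
  letters4 <- c("A", "B", "E", "V")
  out <- character(0)
  for (size in 1:4)
    out <- c(out, apply(utils::combn(letters4, size), 2, paste,
                        collapse = ""))
  out
}

#' Assign enzymes to superkingdom Venn groups
#'
#' Maps each enzyme to the sorted concatenation of the superkingdom letters
#' it is observed in (e.g. \{Bacteria, Eukarya\} -> "BE"). For enzymes whose
#' EC number has been revised and split into several successors, the
#' annotation of the successors is used only under absolute consensus: if
#' the revised ECs yield different letter sets the enzyme is excluded from
#' the taxonomic analysis.
#'
#' @param taxa data.frame with columns \code{ec}, \code{superkingdom}
#'   (letters in A, B, E, V; a \code{species} column may be present and is
#'   ignored here).
#' @param revisions optional data.frame with columns \code{old_ec},
#'   \code{new_ec} (one row per successor of a revised EC number).
#' @return Named character vector mapping EC -> Venn label; enzymes excluded
#'   by the consensus rule are listed in the \code{"excluded"} attribute
#'   (and absent from the result). ECs with no species evidence are simply
#'   unannotated (absent).
#' @export
vennAssign <- function(taxa, revisions = NULL) {
  .check_columns(taxa, c("ec", "superkingdom"), "taxa")
  bad <- setdiff(unique(taxa$superkingdom), c("A", "B", "E", "V"))
  if (length(bad) > 0L)
    stop("unknown superkingdom letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sets <- lapply(split(taxa$superkingdom, taxa$ec),
                 function(s) sort(unique(s)))
  lab <- vapply(sets, paste, character(1), collapse = "")
  excluded <- character(0)
  if (!is.null(revisions) && nrow(revisions) > 0L) {
    .check_columns(revisions, c("old_ec", "new_ec"), "revisions")
    for (old in unique(revisions$old_ec)) {
      succ <- revisions$new_ec[revisions$old_ec == old]
      succ_lab <- unique(lab[names(lab) %in% succ])
      known <- intersect(succ, names(lab))
      if (length(known) == length(succ) && length(succ_lab) == 1L) {
        lab[old] <- succ_lab
      } else {
        excluded <- c(excluded, old)
        lab <- lab[names(lab) != old]
      }
    }
  }
  lab <- lab[order(names(lab))]
  attr(lab, "excluded") <- sort(unique(excluded))
  lab
}

#' Functional category distributions
#'
#' Cross-tabulates enzyme molecular functions: each enzyme contributes one
#' count per distinct general (or detailed) category among its domains'
#' fold superfamilies, by superkingdom Venn group and by age era. Domains
#' whose superfamily lacks a category annotation fall into an
#' \code{"Unannotated"} bucket.
#'
#' @param ds a \code{\link{MetabolicDataset-class}} (its \code{functions}
#'   and \code{taxa} annotation tables are used unless supplied explicitly).
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param functions optional data.frame \code{fsf_id}, \code{general},
#'   \code{detailed}; superfamily ids are the fold-family ccs minus its last
#'   field.
#' @param venn optional named EC -> Venn label vector (from
#'   \code{\link{vennAssign}}).
#' @param width era width (default 0.1).
#' @return List with matrices \code{general_by_venn} (general category x
#'   Venn group) and \code{detailed_by_era} (detailed category x era).
#' @export
functionalDistribution <- function(ds, ages, functions = NULL, venn = NULL,
                                   width = 0.1) {
  ann <- annotations(ds)
  if (is.null(functions)) functions <- ann$functions
  if (is.null(functions))
    stop("no functional annotation table available", call. = FALSE)
  if (is.null(venn)) {
    if (is.null(ann$taxa))
      stop("no taxa table available for Venn groups", call. = FALSE)
    venn <- vennAssign(ann$taxa)
  }
  d <- domains(ds)
  d$fsf_id <- sub("\\.[0-9]+$", "", d$scop_ccs)
  idx <- match(d$fsf_id, functions$fsf_id)
  d$general <- ifelse(is.na(idx), "Unannotated", functions$general[idx])
  d$detailed <- ifelse(is.na(idx), "Unannotated", functions$detailed[idx])
  gen <- unique(d[, c("ec", "general")])
  det <- unique(d[, c("ec", "detailed")])
  gen$venn <- venn[gen$ec]
  gen <- gen[!is.na(gen$venn), , drop = FALSE]
  general_by_venn <- table(general = gen$general,
                           venn = factor(gen$venn, levels = vennGroups()))
  det <- det[det$ec %in% names(ages), , drop = FALSE]
  det$era <- binToEra(ages[det$ec], width)
  detailed_by_era <- table(detailed = det$detailed,
                           era = factor(det$era,
                                        levels = seq_len(nEras(width))))
  list(general_by_venn = unclass(general_by_venn),
       detailed_by_era = unclass(detailed_by_era))
}

.DEFAULT_RESIDUE_GROUPS <- c(
  K = "basic", R = "basic", H = "basic",
  D = "acidic", E = "acidic",
  S = "polar_uncharged", T = "polar_uncharged", N = "polar_uncharged",
  Q = "polar_uncharged", C = "polar_uncharged", Y = "polar_uncharged",
  G = "polar_uncharged",
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar")

#' Chemical role group of amino acid residues
#'
#' Default grouping: basic (K, R, H), acidic (D, E), polar uncharged
#' (S, T, N, Q, C, Y and, by convention here, G) and nonpolar (the rest).
#' Glycine's placement is chemically contested; pass a custom grouping table
#' to move it.
#'
#' @param residue character vector of 1-letter residue codes.
#' @param grouping named character vector residue -> group.
#' @return Character vector of role groups.
#' @export
residueRoleGroup <- function(residue,
                             grouping = .DEFAULT_RESIDUE_GROUPS) {
  bad <- setdiff(unique(residue), names(grouping))
  if (length(bad) > 0L)
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(grouping[residue])
}

#' Catalytic residue distributions
#'
#' Cross-tabulates catalytic-site residues by chemical role group against
#' the parent enzyme's superkingdom Venn group and against its age era.
#'
#' @param catalysis data.frame with columns \code{ec}, \code{residue}
#'   (1-letter codes).
#' @param venn named EC -> Venn label vector (from
#'   \code{\link{vennAssign}}).
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param width era width (default 0.1).
#' @param grouping residue grouping table; see
#'   \code{\link{residueRoleGroup}}.
#' @return List with matrices \code{by_venn} (role group x Venn group) and
#'   \code{by_era} (role group x era).
#' @export
catalyticDistribution <- function(catalysis, venn, ages, width = 0.1,
                                  grouping = .DEFAULT_RESIDUE_GROUPS) {
  .check_columns(catalysis, c("ec", "residue"), "catalysis")
  cat_df <- catalysis
  cat_df$role <- residueRoleGroup(cat_df$residue, grouping)
  groups <- unique(unname(grouping))
  cv <- cat_df[cat_df$ec %in% names(venn), , drop = FALSE]
  cv$venn <- venn[cv$ec]
  by_venn <- table(role = factor(cv$role, levels = groups),
                   venn = factor(cv$venn, levels = vennGroups()))
  ce <- cat_df[cat_df$ec %in% names(ages), , drop = FALSE]
  ce$era <- binToEra(ages[ce$ec], width)
  by_era <- table(role = factor(ce$role, levels = groups),
                  era = factor(ce$era, levels = seq_len(nEras(width))))
  list(by_venn = unclass(by_venn), by_era = unclass(by_era))
}
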