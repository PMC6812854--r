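#' @import methods
NULL

#' The 11 mesonetwork codes
#'
#' Three-letter codes for the upper-level KEGG groupings of metabolic pathway
#' maps ("mesonetworks"): amino acid metabolism (AAC), secondary metabolites
#' (SEC), carbohydrate (CAR), energy (NRG), glycan biosynthesis (GLY), lipid
#' (LIP), cofactors and vitamins (COF), terpenoids and polyketides (POL),
#' nucleotide (NUC), other amino acids (AA2) and xenobiotics (XEN).
#'
#' @return Character vector of the 11 codes.
#' @export
#' @examples
#' mesoCodes()
mesoCodes <- function() {
  c("AAC", "SEC", "CAR", "NRG", "GLY", "LIP", "COF", "POL", "NUC", "AA2",
    "XEN")
}

.SCOP_CCS_PATTERN <- "^[a-z]\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("table '", what, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' An integrated enzyme / pathway / domain-age dataset
#'
#' Container for the three core tables of the analysis plus optional
#' annotation tables:
#' \describe{
#'   \item{domains}{one row per structural domain assignment:
#'     \code{ec} (EC number), \code{scop_ccs} (SCOP concise classification
#'     string at fold-family level, e.g. \code{"c.95.1.1"}), \code{nd}
#'     (phylogenomic age on [0, 1], 0 = most ancient).}
#'   \item{membership}{\code{ec}, \code{map_id}: which KEGG pathway maps
#'     ("subnetworks") each enzyme belongs to. Enzymes may belong to several
#'     maps; that co-membership is the sharing signal the networks encode.}
#'   \item{hierarchy}{\code{map_id}, \code{map_name}, \code{meso_code}: the
#'     subnetwork-to-mesonetwork classification; each map belongs to exactly
#'     one of the 11 codes in \code{\link{mesoCodes}}.}
#'   \item{annotations}{optional named list with elements \code{taxa}
#'     (\code{ec}, \code{species}, \code{superkingdom}), \code{functions}
#'     (\code{fsf_id}, \code{general}, \code{detailed}) and \code{catalysis}
#'     (\code{ec}, \code{residue}, \code{role_group}).}
#' }
#'
#' @slot domains data.frame of domain assignments.
#' @slot membership data.frame of enzyme-to-map memberships.
#' @slot hierarchy data.frame of the pathway hierarchy.
#' @slot annotations named list of optional annotation tables (possibly empty).
#'
#' @seealso \code{\link{readDataset}}, \code{\link{simulateStructure}},
#'   \code{\link{validateDataset}}
#' @export
setClass("MetabolicDataset",
  representation(
    domains = "data.frame",
    membership = "data.frame",
    hierarchy = "data.frame",
    annotations = "list"
  )
)

.GENERAL_CATEGORIES <- c("Metabolism", "Information", "Processes_IC",
                         "Processes_EC", "Regulation", "General", "Other")

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

setValidity("MetabolicDataset", function(object) {
  msgs <- character(0)
  d <- object@domains
  m <- object@membership
  h <- object@hierarchy
  ok <- try({
    .check_columns(d, c("ec", "scop_ccs", "nd"), "domains")
    .check_columns(m, c("ec", "map_id"), "membership")
    .check_columns(h, c("map_id", "map_name", "meso_code"), "hierarchy")
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    return(conditionMessage(attr(ok, "condition")))
  bad_nd <- which(!is.finite(d$nd) | d$nd < 0 | d$nd > 1)
  if (length(bad_nd) > 0L)
    msgs <- c(msgs, paste0("domains: nd outside [0,1] at row(s) ",
                           paste(utils::head(bad_nd, 5L), collapse = ", ")))
  bad_ccs <- which(!grepl(.SCOP_CCS_PATTERN, d$scop_ccs))
  if (length(bad_ccs) > 0L)
    msgs <- c(msgs, paste0("domains: malformed scop_ccs at row(s) ",
                           paste(utils::head(bad_ccs, 5L), collapse = ", ")))
  if (anyDuplicated(paste(d$ec, d$scop_ccs)))
    msgs <- c(msgs, "domains: duplicated (ec, scop_ccs) pairs after deduplication")
  if (anyDuplicated(h$map_id))
    msgs <- c(msgs, "hierarchy: map_id assigned to more than one row")
  bad_meso <- setdiff(unique(h$meso_code), mesoCodes())
  if (length(bad_meso) > 0L)
    msgs <- c(msgs, paste0("hierarchy: unknown meso_code(s): ",
                           paste(bad_meso, collapse = ", ")))
  extra <- names(object@annotations)
  bad_ann <- setdiff(extra, c("taxa", "functions", "catalysis"))
  if (length(bad_ann) > 0L)
    msgs <- c(msgs, paste0("annotations: unknown table(s): ",
                           paste(bad_ann, collapse = ", ")))
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a MetabolicDataset
#'
#' Canonicalizes the input tables: rows are deduplicated, sorted by (ec,
#' scop_ccs) / (ec, map_id) / map_id, and cross-references are checked.
#' Conflicting \code{nd} values for the same (ec, scop_ccs) pair are an error,
#' since a fold family carries a single age. Membership rows pointing at maps
#' absent from the hierarchy are dropped and reported via the
#' \code{"unresolved_map_ids"} attribute.
#'
#' @param domains data.frame with columns \code{ec}, \code{scop_ccs},
#'   \code{nd}.
#' @param membership data.frame with columns \code{ec}, \code{map_id}.
#' @param hierarchy data.frame with columns \code{map_id}, \code{map_name},
#'   \code{meso_code}.
#' @param annotations optional named list of annotation tables (\code{taxa},
#'   \code{functions}, \code{catalysis}).
#' @return A validated \code{\link{MetabolicDataset-class}} object.
#' @export
#' @examples
#' ds <- MetabolicDataset(
#'   domains = data.frame(ec = "1.1.1.1", scop_ccs = "c.2.1.1", nd = 0.1),
#'   membership = data.frame(ec = "1.1.1.1", map_id = "map00010"),
#'   hierarchy = data.frame(map_id = "map00010", map_name = "Glycolysis",
#'                          meso_code = "CAR"))
#' ds
MetabolicDataset <- function(domains, membership, hierarchy,
                             annotations = list()) {
  .check_columns(domains, c("ec", "scop_ccs", "nd"), "domains")
  .check_columns(membership, c("ec", "map_id"), "membership")
  .check_columns(hierarchy, c("map_id", "map_name", "meso_code"), "hierarchy")
  domains <- unique(domains[, c("ec", "scop_ccs", "nd")])
  key <- paste(domains$ec, domains$scop_ccs)
  if (anyDuplicated(key)) {
    clash <- unique(key[duplicated(key)])
    stop("conflicting nd values for (ec, scop_ccs) pair(s): ",
         paste(utils::head(clash, 5L), collapse = "; "), call. = FALSE)
  }
  bad_nd <- which(!is.finite(domains$nd) | domains$nd < 0 | domains$nd > 1)
  if (length(bad_nd) > 0L)
    stop("domains: nd outside [0,1] at row(s) ",
         paste(utils::head(bad_nd, 5L), collapse = ", "), call. = FALSE)
  membership <- unique(membership[, c("ec", "map_id")])
  hierarchy <- unique(hierarchy[, c("map_id", "map_name", "meso_code")])
  unresolved <- sort(setdiff(membership$map_id, hierarchy$map_id))
  if (length(unresolved) > 0L)
    membership <- membership[membership$map_id %in% hierarchy$map_id, ,
                             drop = FALSE]
  domains <- domains[order(domains$ec, domains$scop_ccs), , drop = FALSE]
  membership <- membership[order(membership$ec, membership$map_id), ,
                           drop = FALSE]
  hierarchy <- hierarchy[order(hierarchy$map_id), , drop = FALSE]
  rownames(domains) <- rownames(membership) <- rownames(hierarchy) <- NULL
  if (!is.null(annotations$taxa))
    annotations$taxa <- unique(annotations$taxa[
      order(annotations$taxa$ec, annotations$taxa$species), , drop = FALSE])
  if (!is.null(annotations$functions))
    annotations$functions <- unique(annotations$functions[
      order(annotations$functions$fsf_id), , drop = FALSE])
  if (!is.null(annotations$catalysis))
    annotations$catalysis <- unique(annotations$catalysis[
      order(annotations$catalysis$ec, annotations$catalysis$residue), ,
      drop = FALSE])
  annotations <- lapply(annotations, function(x) {
    rownames(x) <- NULL
    x
  })
  obj <- new("MetabolicDataset", domains = domains, membership = membership,
             hierarchy = hierarchy, annotations = annotations)
  attr(obj, "unresolved_map_ids") <- unresolved
  obj
}

#' A configuration for the synthetic-data generator
#'
#' Holds every tunable of \code{\link{simulateStructure}} and
#' \code{\link{simulateAnnotations}}. Defaults emulate the scale and age
#' structure of the real enzyme-pathway data: 11 mesonetworks, ~148
#' subnetworks, 1,900 enzymes, multidomain enzymes (1 + Poisson(0.8) domains,
#' capped at 6), and a biphasic domain-age distribution with peaks near the
#' start of the timeline and around nd = 0.6-0.7.
#'
#' @slot seed integer RNG seed; every draw is reproducible given it.
#' @slot nMeso number of mesonetworks (default 11).
#' @slot meanSubnetsPerMeso mean subnetworks per mesonetwork (default 13.5).
#' @slot nEnzymes number of enzymes (default 1900).
#' @slot pExtraMembership probability an enzyme joins subnetworks beyond its
#'   home subnetwork (default 0.4).
#' @slot pCrossMeso probability an extra membership crosses mesonetwork
#'   boundaries (default 0.25).
#' @slot domainPoissonMean mean of the Poisson part of the per-enzyme domain
#'   count 1 + Poisson(mean) (default 0.8).
#' @slot maxDomains cap on domains per enzyme (default 6).
#' @slot ageMixtureWeights weights of the 3-component age mixture
#'   (two Beta peaks + uniform background); must sum to 1.
#' @slot ageMixtureShapes 2x2 matrix of Beta shape parameters, one row per
#'   peak component.
#' @slot vennWeights named sampling weights over the 15 superkingdom Venn
#'   groups (BE-favouring by default).
#' @slot functionWeights named sampling weights over the 7 general functional
#'   categories (Metabolism-favouring by default).
#' @slot pChargedResidue total sampling weight given to the charged catalytic
#'   residues D, E, K, R, H (default 0.6).
#' @seealso \code{\link{simulationConfig}}
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nMeso = "integer",
    meanSubnetsPerMeso = "numeric",
    nEnzymes = "integer",
    pExtraMembership = "numeric",
    pCrossMeso = "numeric",
    domainPoissonMean = "numeric",
    maxDomains = "integer",
    ageMixtureWeights = "numeric",
    ageMixtureShapes = "matrix",
    vennWeights = "numeric",
    functionWeights = "numeric",
    pChargedResidue = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@nMeso < 2L)
    msgs <- c(msgs, "nMeso must be >= 2")
  if (object@nEnzymes < 10L)
    msgs <- c(msgs, "nEnzymes must be >= 10")
  if (object@meanSubnetsPerMeso < 1)
    msgs <- c(msgs, "meanSubnetsPerMeso must be >= 1")
  probs <- c(object@pExtraMembership, object@pCrossMeso,
             object@pChargedResidue)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "probabilities must lie in [0,1]")
  w <- object@ageMixtureWeights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msgs <- c(msgs, "ageMixtureWeights must be 3 non-negative weights summing to 1")
  if (!all(dim(object@ageMixtureShapes) == c(2L, 2L)) ||
      any(object@ageMixtureShapes <= 0))
    msgs <- c(msgs, "ageMixtureShapes must be a positive 2x2 matrix")
  if (length(msgs) > 0L) msgs else TRUE
})

#' Create a synthetic-data configuration
#'
#' @param seed integer seed controlling every random draw.
#' @param nMeso,meanSubnetsPerMeso,nEnzymes scale of the hierarchy.
#' @param pExtraMembership,pCrossMeso enzyme-sharing parameters.
#' @param domainPoissonMean,maxDomains per-enzyme domain-count law
#'   1 + Poisson(domainPoissonMean), capped at maxDomains.
#' @param ageMixtureWeights,ageMixtureShapes the biphasic age mixture:
#'   weights of (ancient peak, recent peak, uniform background) and the Beta
#'   shape parameters of the two peaks (rows of a 2x2 matrix). The default
#'   mixture 0.45 Beta(1.2, 12) + 0.35 Beta(8, 4) + 0.20 U(0, 1) places modes
#'   in the first age era and near nd = 0.7.
#' @param vennWeights,functionWeights,pChargedResidue annotation-sampling
#'   weights; see \code{\link{SimulationConfig-class}}.
#' @return A validated \code{SimulationConfig}.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1, nEnzymes = 200)
#' cfg
simulationConfig <- function(seed = 1L,
                             nMeso = 11L,
                             meanSubnetsPerMeso = 13.5,
                             nEnzymes = 1900L,
                             pExtraMembership = 0.4,
                             pCrossMeso = 0.25,
                             domainPoissonMean = 0.8,
                             maxDomains = 6L,
                             ageMixtureWeights = c(0.45, 0.35, 0.20),
                             ageMixtureShapes = matrix(c(1.2, 12, 8, 4),
                                                       nrow = 2,
                                                       byrow = TRUE),
                             vennWeights = NULL,
                             functionWeights = NULL,
                             pChargedResidue = 0.6) {
  if (is.null(vennWeights)) {
    vennWeights <- c(BE = 0.36, ABE = 0.18, ABEV = 0.10, B = 0.10, E = 0.07,
                     AB = 0.05, BEV = 0.04, A = 0.03, EV = 0.02, AE = 0.02,
                     ABV = 0.01, AEV = 0.005, BV = 0.005, V = 0.005,
                     AV = 0.005)
  }
  if (is.null(functionWeights)) {
    functionWeights <- c(Metabolism = 0.55, Information = 0.12,
                         Processes_IC = 0.10, Processes_EC = 0.04,
                         Regulation = 0.08, General = 0.08, Other = 0.03)
  }
  new("SimulationConfig",
      seed = as.integer(seed),
      nMeso = as.integer(nMeso),
      meanSubnetsPerMeso = as.numeric(meanSubnetsPerMeso),
      nEnzymes = as.integer(nEnzymes),
      pExtraMembership = as.numeric(pExtraMembership),
      pCrossMeso = as.numeric(pCrossMeso),
      domainPoissonMean = as.numeric(domainPoissonMean),
      maxDomains = as.integer(maxDomains),
      ageMixtureWeights = as.numeric(ageMixtureWeights),
      ageMixtureShapes = ageMixtureShapes,
      vennWeights = vennWeights,
      functionWeights = functionWeights,
      pChargedResidue = as.numeric(pChargedResidue))
}
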