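#' @rdname MetabolicDataset-class
#' @param object,x a \code{MetabolicDataset}.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname MetabolicDataset-class
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname MetabolicDataset-class
#' @export
setGeneric("hierarchy", function(x) standardGeneric("hierarchy"))

#' @rdname MetabolicDataset-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname MetabolicDataset-class
#' @export
setGeneric("enzymes", function(x) standardGeneric("enzymes"))

#' @rdname MetabolicDataset-class
#' @export
setMethod("domains", "MetabolicDataset", function(x) x@domains)

#' @rdname MetabolicDataset-class
#' @export
setMethod("memberships", "MetabolicDataset", function(x) x@membership)

#' @rdname MetabolicDataset-class
#' @export
setMethod("hierarchy", "MetabolicDataset", function(x) x@hierarchy)

#' @rdname MetabolicDataset-class
#' @export
setMethod("annotations", "MetabolicDataset", function(x) x@annotations)

#' @describeIn MetabolicDataset-class sorted union of enzymes appearing in
#'   the domain or membership tables.
#' @export
setMethod("enzymes", "MetabolicDataset", function(x) {
  sort(unique(c(x@domains$ec, x@membership$ec)))
})

setMethod("show", "MetabolicDataset", function(object) {
  n_ec <- length(enzymes(object))
  cat("MetabolicDataset\n")
  cat("  enzymes:           ", n_ec, "\n")
  cat("  subnetworks:       ", length(unique(object@hierarchy$map_id)), "\n")
  cat("  mesonetworks:      ",
      length(unique(object@hierarchy$meso_code)), "\n")
  cat("  domain assignments:", nrow(object@domains), "\n")
  cat("  membership links:  ", nrow(object@membership), "\n")
  ann <- names(object@annotations)
  cat("  annotations:       ",
      if (length(ann)) paste(ann, collapse = ", ") else "none", "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  hierarchy: ", object@nMeso, " mesonetworks x ~",
      object@meanSubnetsPerMeso, " subnetworks, ",
      object@nEnzymes, " enzymes\n", sep = "")
  cat("  sharing:   p(extra membership) = ", object@pExtraMembership,
      ", p(cross-meso) = ", object@pCrossMeso, "\n", sep = "")
  cat("  domains:   1 + Poisson(", object@domainPoissonMean,
      ") capped at ", object@maxDomains, "\n", sep = "")
  w <- object@ageMixtureWeights
  s <- object@ageMixtureShapes
  cat("  ages:      ", w[1], " Beta(", s[1, 1], ",", s[1, 2], ") + ",
      w[2], " Beta(", s[2, 1], ",", s[2, 2], ") + ", w[3],
      " U(0,1)\n", sep = "")
})
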