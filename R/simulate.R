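#' Draw domain ages from the biphasic mixture
#'
#' Samples fold-family ages from the three-component mixture configured in a
#' \code{\link{SimulationConfig-class}}: an ancient Beta peak, a late Beta
#' peak and a uniform background on [0, 1].
#'
#' @param n number of draws.
#' @param cfg a \code{SimulationConfig}.
#' @return Numeric vector in [0, 1].
#' @keywords internal
.sample_age_mixture <- function(n, cfg) {
  w <- cfg@ageMixtureWeights
  s <- cfg@ageMixtureShapes
  comp <- sample.int(3L, n, replace = TRUE, prob = w)
  out <- numeric(n)
  i1 <- comp == 1L
  i2 <- comp == 2L
  i3 <- comp == 3L
  out[i1] <- stats::rbeta(sum(i1), s[1, 1], s[1, 2])
  out[i2] <- stats::rbeta(sum(i2), s[2, 1], s[2, 2])
  out[i3] <- stats::runif(sum(i3))
  out
}

#' Analytic CDF of the configured age mixture
#'
#' @param q quantiles in [0, 1].
#' @param cfg a \code{SimulationConfig}.
#' @return Mixture CDF values at \code{q}.
#' @export
ageMixtureCDF <- function(q, cfg = simulationConfig()) {
  w <- cfg@ageMixtureWeights
  s <- cfg@ageMixtureShapes
  w[1] * stats::pbeta(q, s[1, 1], s[1, 2]) +
    w[2] * stats::pbeta(q, s[2, 1], s[2, 2]) +
    w[3] * stats::punif(q)
}

.make_ec_numbers <- function(n) {
  # unique, well-formed EC strings; classes cycle through 1..6
  c1 <- (seq_len(n) - 1L) %% 6L + 1L
  c2 <- ((seq_len(n) - 1L) %/% 6L) %% 15L + 1L
  c3 <- ((seq_len(n) - 1L) %/% 90L) %% 15L + 1L
  c4 <- (seq_len(n) - 1L) %/% 1350L + 1L
  serial <- stats::ave(seq_len(n), paste(c1, c2, c3, c4),
                       FUN = seq_along)
  sprintf("%d.%d.%d.%d", c1, c2, c3, (c4 - 1L) * 100L + serial)
}

.make_ccs <- function(n) {
  cls <- letters[((seq_len(n) - 1L) %% 7L) + 1L]
  fold <- ((seq_len(n) - 1L) %/% 7L) %% 120L + 1L
  sfam <- ((seq_len(n) - 1L) %/% 840L) %% 10L + 1L
  fam <- (seq_len(n) - 1L) %/% 8400L + 1L
  sprintf("%s.%d.%d.%d", cls, fold, sfam, fam)
}

#' Simulate the pathway hierarchy, memberships and domain ages
#'
#' Generates a seeded \code{\link{MetabolicDataset-class}} with the structure
#' the downstream analysis assumes: a fixed set of mesonetworks each holding
#' a Poisson number of subnetworks (at least one), enzymes placed in a home
#' subnetwork with size heterogeneity across subnetworks, extra memberships
#' (the sharing signal) drawn geometrically with configurable probabilities
#' of crossing mesonetwork boundaries, and fold-family domains whose ages
#' follow the biphasic mixture. Fold families are drawn from a shared pool so
#' the same family (and hence the same age) recurs across enzymes, and each
#' family has a single age.
#'
#' @param cfg a \code{\link{SimulationConfig-class}}; the output is
#'   deterministic given \code{cfg@seed}.
#' @return A \code{MetabolicDataset} in which every enzyme has at least one
#'   home subnetwork and at least one aged domain (coverage 1).
#' @seealso \code{\link{simulateAnnotations}}, \code{\link{simulateDataset}}
#' @export
#' @examples
#' ds <- simulateStructure(simulationConfig(seed = 7, nEnzymes = 100))
#' validateDataset(ds)
simulateStructure <- function(cfg = simulationConfig()) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  withr::with_seed(cfg@seed, {
    n_meso <- cfg@nMeso
    meso <- mesoCodes()
    if (n_meso <= length(meso)) {
      meso <- meso[seq_len(n_meso)]
    } else {
      meso <- c(meso, sprintf("M%02d", seq_len(n_meso - length(meso))))
    }
    n_sub <- pmax(1L, stats::rpois(n_meso, cfg@meanSubnetsPerMeso))
    S <- sum(n_sub)
    map_id <- sprintf("map%05d", 10L * seq_len(S))
    map_meso <- rep(meso, times = n_sub)
    hier <- data.frame(map_id = map_id,
                       map_name = sprintf("Synthetic pathway %03d",
                                          seq_len(S)),
                       meso_code = map_meso,
                       stringsAsFactors = FALSE)

    ec <- .make_ec_numbers(cfg@nEnzymes)
    n_fam <- max(20L, round(0.45 * cfg@nEnzymes))
    fam_ccs <- .make_ccs(n_fam)
    fam_nd <- .sample_age_mixture(n_fam, cfg)
    n_dom <- 1L + pmin(stats::rpois(cfg@nEnzymes, cfg@domainPoissonMean),
                       cfg@maxDomains - 1L)
    dom_ec <- rep(ec, times = n_dom)
    dom_fam <- unlist(lapply(n_dom, function(d)
      sample.int(n_fam, d, replace = FALSE)), use.names = FALSE)
    domains <- data.frame(ec = dom_ec,
                          scop_ccs = fam_ccs[dom_fam],
                          nd = fam_nd[dom_fam],
                          stringsAsFactors = FALSE)
    # oldest-domain age drives recruitment: ancient enzymes spread across
    # many pathways, late-appearing ones stay specialized
    enz_age <- vapply(split(domains$nd, domains$ec), min, numeric(1))[ec]

    # heterogeneous subnetwork attractiveness (some maps much larger)
    sub_w <- stats::rgamma(S, shape = 0.8)
    home <- sample.int(S, cfg@nEnzymes, replace = TRUE, prob = sub_w)
    mem_ec <- ec
    mem_map <- map_id[home]
    # sharing propensity proportional to (1 - age), rescaled so its mean
    # over the age distribution equals pExtraMembership
    p_share <- pmin(1, cfg@pExtraMembership * (1 - enz_age) /
                      max(1e-9, mean(1 - enz_age)))
    shared <- stats::runif(cfg@nEnzymes) < p_share
    for (i in which(shared)) {
      n_extra <- 1L + stats::rgeom(1L, 0.5)
      pool_cross <- which(map_meso != map_meso[home[i]])
      pool_within <- setdiff(which(map_meso == map_meso[home[i]]), home[i])
      for (k in seq_len(n_extra)) {
        cross <- stats::runif(1L) < cfg@pCrossMeso
        pool <- if (cross || length(pool_within) == 0L) pool_cross
                else pool_within
        if (length(pool) == 0L) next
        j <- pool[sample.int(length(pool), 1L)]
        mem_ec <- c(mem_ec, ec[i])
        mem_map <- c(mem_map, map_id[j])
      }
    }
    membership <- unique(data.frame(ec = mem_ec, map_id = mem_map,
                                    stringsAsFactors = FALSE))
    MetabolicDataset(domains, membership, hier)
  })
}

.VENN_SPECIES <- c(A = "synthetic_archaeon", B = "synthetic_bacterium",
                   E = "synthetic_eukaryote", V = "synthetic_virus")

#' Simulate annotation tables for a dataset
#'
#' Adds seeded taxa, functional-category and catalytic-site tables whose
#' marginals emulate the real data: superkingdom Venn groups favour BE,
#' functional categories favour Metabolism, and catalytic residues favour the
#' charged amino acids D, E, K, R, H.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param cfg a \code{\link{SimulationConfig-class}}; the annotation draws
#'   use \code{cfg@seed + 1} so they are independent of the structure draws
#'   but still fully determined by the configuration.
#' @return The dataset with \code{annotations} filled in.
#' @export
simulateAnnotations <- function(ds, cfg = simulationConfig()) {
  stopifnot(is(ds, "MetabolicDataset"), is(cfg, "SimulationConfig"))
  ecs <- enzymes(ds)
  if (length(ecs) == 0L)
    stop("dataset has no enzymes", call. = FALSE)
  withr::with_seed(cfg@seed + 1L, {
    groups <- sample(names(cfg@vennWeights), length(ecs), replace = TRUE,
                     prob = cfg@vennWeights)
    letters_per_ec <- strsplit(groups, "")
    taxa <- data.frame(
      ec = rep(ecs, lengths(letters_per_ec)),
      superkingdom = unlist(letters_per_ec, use.names = FALSE),
      stringsAsFactors = FALSE)
    taxa$species <- paste0(.VENN_SPECIES[taxa$superkingdom], "_",
                           match(taxa$ec, ecs))
    taxa <- taxa[, c("ec", "species", "superkingdom")]

    fsf <- sort(unique(sub("\\.[0-9]+$", "", domains(ds)$scop_ccs)))
    gen <- sample(names(cfg@functionWeights), length(fsf), replace = TRUE,
                  prob = cfg@functionWeights)
    detailed <- paste0(gen, "_detail_",
                       sample.int(7L, length(fsf), replace = TRUE))
    functions <- data.frame(fsf_id = fsf, general = gen,
                            detailed = detailed, stringsAsFactors = FALSE)

    charged <- c("D", "E", "K", "R", "H")
    others <- setdiff(.AA_CODES, charged)
    p <- c(rep(cfg@pChargedResidue / length(charged), length(charged)),
           rep((1 - cfg@pChargedResidue) / length(others), length(others)))
    cat_ec <- ecs[stats::runif(length(ecs)) < 0.3]
    n_res <- 1L + stats::rpois(length(cat_ec), 1.2)
    res <- sample(c(charged, others), sum(n_res), replace = TRUE, prob = p)
    catalysis <- data.frame(ec = rep(cat_ec, times = n_res),
                            residue = res,
                            role_group = residueRoleGroup(res),
                            stringsAsFactors = FALSE)
    MetabolicDataset(domains(ds), memberships(ds), hierarchy(ds),
                     list(taxa = taxa, functions = functions,
                          catalysis = catalysis))
  })
}

#' Simulate a complete annotated dataset
#'
#' Convenience wrapper running \code{\link{simulateStructure}} then
#' \code{\link{simulateAnnotations}}.
#'
#' @param cfg a \code{\link{SimulationConfig-class}}.
#' @return An annotated \code{MetabolicDataset}.
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  simulateAnnotations(simulateStructure(cfg), cfg)
}
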