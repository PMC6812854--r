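#' Assign an evolutionary age to an enzyme from its domain ages
#'
#' Multidomain enzymes are dated by the age of their second oldest structural
#' domain (default), reflecting that a cooption event needs both an old donor
#' domain and an acceptor; the alternative rule dates the enzyme by its
#' oldest domain. Ages are nd values on [0, 1], smaller = more ancient.
#' Duplicated ages are kept as multiset entries, so the second oldest of
#' \{a, a, b\} is a. A single-domain enzyme takes its only domain's age under
#' either rule.
#'
#' @param domainAges numeric vector (multiset) of domain nd values.
#' @param rule \code{"second_oldest"} (default) or \code{"oldest"}.
#' @return A single nd value.
#' @export
#' @examples
#' assignEnzymeAge(c(0.791971, 0.0912409, 0.080292, 0.0912409, 0.813869))
#' assignEnzymeAge(c(0.781022, 0.0291971), rule = "oldest")
assignEnzymeAge <- function(domainAges,
                            rule = c("second_oldest", "oldest")) {
  rule <- match.arg(rule)
  if (length(domainAges) == 0L || all(is.na(domainAges)))
    stop("enzyme has no domain ages (unpainted)", call. = FALSE)
  x <- sort(domainAges[!is.na(domainAges)])
  if (any(x < 0 | x > 1))
    stop("domain ages must lie in [0,1]", call. = FALSE)
  if (rule == "oldest" || length(x) == 1L) x[1] else x[2]
}

#' Enzyme ages for a whole dataset
#'
#' Applies \code{\link{assignEnzymeAge}} to every enzyme with at least one
#' aged domain. Enzymes without any domain assignment ("unpainted") are
#' omitted, mirroring their exclusion from network construction.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param rule age rule; see \code{\link{assignEnzymeAge}}.
#' @return Named numeric vector of nd values, names = EC numbers, sorted by
#'   EC.
#' @export
enzymeAges <- function(ds, rule = c("second_oldest", "oldest")) {
  rule <- match.arg(rule)
  d <- domains(ds)
  if (nrow(d) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  byec <- split(d$nd, d$ec)
  ages <- vapply(byec, assignEnzymeAge, numeric(1), rule = rule)
  ages[order(names(ages))]
}

#' Bin nd ages into eras of the evolutionary timeline
#'
#' Eras are width-\code{width} bins of [0, 1]; era 1 covers [0, width] and
#' era i covers (width (i-1), width i]. With the default width 0.1 there are
#' 10 eras and nd = 0.1 falls in era 1 (bins are right-closed, the first one
#' additionally contains 0).
#'
#' @param nd numeric vector of ages in [0, 1].
#' @param width era width (default 0.1).
#' @return Integer vector of era indices in 1..ceiling(1/width).
#' @export
#' @examples
#' binToEra(c(0, 0.05, 0.1, 0.1000001, 1))
binToEra <- function(nd, width = 0.1) {
  if (any(!is.finite(nd) | nd < 0 | nd > 1))
    stop("nd values must lie in [0,1]", call. = FALSE)
  stopifnot(width > 0, width <= 1)
  # small tolerance keeps exact multiples of width in their right-closed bin
  era <- as.integer(ceiling(nd / width - 1e-9))
  era[era < 1L] <- 1L
  n_era <- as.integer(ceiling(1 / width - 1e-9))
  era[era > n_era] <- n_era
  era
}

#' Number of eras for a given width
#' @param width era width.
#' @return Integer count of eras tiling [0, 1].
#' @export
nEras <- function(width = 0.1) as.integer(ceiling(1 / width - 1e-9))

#' Enzyme first-appearance counts per mesonetwork and era
#'
#' Counts, for each mesonetwork, the enzymes whose assigned age falls in each
#' era. An enzyme is counted once per mesonetwork it belongs to (through any
#' of that mesonetwork's subnetworks) and in exactly one era, the era of its
#' age, so each row sums to the number of distinct member enzymes.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param width era width (default 0.1).
#' @return Integer matrix, rows = mesonetwork codes (hierarchy order),
#'   columns = \code{era_1..era_n}.
#' @export
eraCounts <- function(ds, ages, width = 0.1) {
  h <- hierarchy(ds)
  m <- memberships(ds)
  m <- m[m$ec %in% names(ages), , drop = FALSE]
  meso <- h$meso_code[match(m$map_id, h$map_id)]
  pairs <- unique(data.frame(ec = m$ec, meso = meso,
                             stringsAsFactors = FALSE))
  k <- nEras(width)
  codes <- unique(h$meso_code)
  out <- matrix(0L, nrow = length(codes), ncol = k,
                dimnames = list(codes, paste0("era_", seq_len(k))))
  if (nrow(pairs) > 0L) {
    era <- binToEra(ages[pairs$ec], width)
    tab <- table(factor(pairs$meso, levels = codes),
                 factor(era, levels = seq_len(k)))
    out[] <- as.integer(tab)
  }
  out
}

#' Map an age onto a discrete ancient-to-recent color scale
#'
#' Equal-width binning of [0, 1] into \code{nBins} bins; bin 1 is the most
#' ancient (red) end of the scale, bin \code{nBins} the most recent (blue).
#'
#' @param nd numeric vector of ages in [0, 1].
#' @param nBins number of color bins (>= 2).
#' @return Integer vector of bin indices in 1..nBins.
#' @export
#' @examples
#' colorBin(c(0, 0.55, 1), nBins = 10)
colorBin <- function(nd, nBins) {
  if (any(!is.finite(nd) | nd < 0 | nd > 1))
    stop("nd values must lie in [0,1]", call. = FALSE)
  stopifnot(nBins >= 2)
  bin <- as.integer(ceiling(nd * nBins - 1e-9))
  bin[bin < 1L] <- 1L
  bin[bin > nBins] <- as.integer(nBins)
  bin
}
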