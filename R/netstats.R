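#' Average degree and diameter
#'
#' @param G an igraph.
#' @return List with \code{avg_degree} (2|E|/|V| on the full graph, weights
#'   ignored) and \code{diameter} (maximum unweighted eccentricity on the
#'   largest connected component).
#' @export
degreeDiameter <- function(G) {
  if (igraph::vcount(G) == 0L)
    stop("graph is empty", call. = FALSE)
  lcc <- largestComponent(G)
  list(avg_degree = 2 * igraph::ecount(G) / igraph::vcount(G),
       diameter = igraph::diameter(lcc, weights = NA))
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling from the zeta-normalized discrete power law
#' P(X = k) proportional to k^(-alpha) for k >= xmin, truncated at a large
#' support bound (the truncated tail mass is negligible for alpha > 2).
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin lower bound (default 1).
#' @param maxSupport truncation bound of the support (default 1e6).
#' @param seed optional integer seed.
#' @return Integer-valued numeric vector.
#' @export
rPowerLaw <- function(n, alpha, xmin = 1, maxSupport = 1e6, seed = NULL) {
  stopifnot(alpha > 1, xmin >= 1)
  sampler <- .discrete_pl_sampler(alpha, xmin, maxSupport)
  if (is.null(seed)) sampler(n)
  else withr::with_seed(as.integer(seed), sampler(n))
}

# inverse-CDF sampler for the truncated zeta pmf; the CDF is built once and
# the returned closure inverts it per draw
.discrete_pl_sampler <- function(alpha, xmin, maxSupport = 1e6) {
  k <- seq.int(xmin, maxSupport)
  cdf <- cumsum(k^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  function(n) xmin + findInterval(stats::runif(n), cdf)
}

.ks_p_asymptotic <- function(d, n) {
  # P(sqrt(n) D > sqrt(n) d) for the one-sample KS statistic
  lam <- sqrt(n) * d
  if (lam < 1e-8) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  min(max(p, 0), 1)
}

#' Fit a discrete power law with KS model selection
#'
#' Maximum-likelihood fit of the zeta-normalized discrete power law to a
#' positive integer sequence (typically node degrees), with the lower bound
#' xmin chosen over the observed values to minimize the Kolmogorov-Smirnov
#' distance between fitted and empirical distributions (the plfit recipe,
#' computed by \code{igraph::fit_power_law}). The goodness-of-fit p-value for
#' the null hypothesis "the data were drawn from the fitted power law" is
#' obtained by a seeded semi-parametric bootstrap (each replicate resamples
#' the body below xmin and draws the tail from the fitted law, then is
#' refitted by the same procedure), or by the asymptotic Kolmogorov
#' approximation when \code{pMethod = "analytic"}. The null is rejected at
#' \code{ks_p < 0.05}; an exponent between 2 and 3 is the conventional
#' scale-free band.
#'
#' @param degrees positive integer-valued sequence (a warning is raised
#'   below 50 observations).
#' @param xmin optional forced lower bound; by default searched.
#' @param pMethod \code{"bootstrap"} (default) or \code{"analytic"}.
#' @param reps bootstrap replicates (default 100).
#' @param seed integer seed for the bootstrap.
#' @return Object of class \code{"powerLawFit"}: list with \code{alpha},
#'   \code{xmin}, \code{logLik}, \code{ks_stat}, \code{ks_p}, \code{n},
#'   \code{n_tail}, \code{p_method}.
#' @export
#' @examples
#' x <- rPowerLaw(500, alpha = 2.5, seed = 1)
#' fitPowerLaw(x, reps = 20, seed = 1)
fitPowerLaw <- function(degrees, xmin = NULL,
                        pMethod = c("bootstrap", "analytic"),
                        reps = 100, seed = 1) {
  pMethod <- match.arg(pMethod)
  x <- degrees[!is.na(degrees)]
  if (length(x) == 0L)
    stop("no observations", call. = FALSE)
  if (any(x <= 0))
    stop("degrees must be positive", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("degenerate distribution: all values equal", call. = FALSE)
  if (length(x) < 50L)
    warning("fewer than 50 observations; power-law fit is unreliable",
            call. = FALSE)
  forced <- !is.null(xmin)
  fit <- if (forced)
    igraph::fit_power_law(x, xmin = xmin, implementation = "plfit")
  else
    igraph::fit_power_law(x, implementation = "plfit")
  n <- length(x)
  n_tail <- sum(x >= fit$xmin)
  ks_p <- if (pMethod == "analytic") {
    .ks_p_asymptotic(fit$KS.stat, n_tail)
  } else {
    body <- x[x < fit$xmin]
    p_tail <- n_tail / n
    draw_tail <- .discrete_pl_sampler(fit$alpha, fit$xmin,
                                      maxSupport = max(1e5, 10 * max(x)))
    ks_boot <- withr::with_seed(as.integer(seed), vapply(seq_len(reps),
      function(i) {
        tail_n <- stats::rbinom(1L, n, p_tail)
        xs <- c(draw_tail(tail_n),
                if (n - tail_n > 0L)
                  sample(body, n - tail_n, replace = TRUE))
        f <- if (forced)
          igraph::fit_power_law(xs, xmin = xmin, implementation = "plfit")
        else
          igraph::fit_power_law(xs, implementation = "plfit")
        f$KS.stat
      }, numeric(1)))
    (1 + sum(ks_boot >= fit$KS.stat)) / (1 + reps)
  }
  structure(list(alpha = fit$alpha, xmin = fit$xmin, logLik = fit$logLik,
                 ks_stat = fit$KS.stat, ks_p = ks_p, n = n,
                 n_tail = n_tail, p_method = pMethod),
            class = "powerLawFit")
}

#' @export
print.powerLawFit <- function(x, ...) {
  cat(sprintf(
    "Discrete power-law fit: alpha = %.4f, xmin = %g (n = %d, tail = %d)\n",
    x$alpha, x$xmin, x$n, x$n_tail))
  cat(sprintf("  KS = %.5f, p = %.4g (%s); logLik = %.2f\n",
              x$ks_stat, x$ks_p, x$p_method, x$logLik))
  invisible(x)
}

#' Bartels rank von Neumann test of randomness
#'
#' Rank-based test of the null hypothesis that a sequence is exchangeable
#' (random) against serial dependence. With midranks R_i, the rank von
#' Neumann ratio is RVN = sum (R_i - R_{i+1})^2 / sum (R_i - (n+1)/2)^2,
#' which has expectation 2 under the null; the standardized statistic is
#' (RVN - 2)/sigma with sigma^2 = 4(n-2)(5n^2-2n-9) / (5n(n+1)(n-1)^2).
#' Two-sided p-values come from the symmetric Beta approximation of RVN/4
#' (default) or the normal approximation.
#'
#' @param series numeric sequence, length >= 10, not constant.
#' @param pMethod \code{"beta"} (default) or \code{"normal"}.
#' @return Object of class \code{"bartelsTest"}: list with \code{rvn},
#'   \code{statistic}, \code{p_value}, \code{n}, \code{p_method}.
#' @export
#' @examples
#' bartelsRankTest(c(5, 1, 4, 2, 6, 3, 8, 7, 10, 9))
bartelsRankTest <- function(series, pMethod = c("beta", "normal")) {
  pMethod <- match.arg(pMethod)
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 10L)
    stop("need at least 10 observations", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("constant series: rank variance is zero", call. = FALSE)
  r <- rank(x, ties.method = "average")
  num <- sum(diff(r)^2)
  den <- sum((r - (n + 1) / 2)^2)
  rvn <- num / den
  sigma2 <- 4 * (n - 2) * (5 * n^2 - 2 * n - 9) /
    (5 * n * (n + 1) * (n - 1)^2)
  statistic <- (rvn - 2) / sqrt(sigma2)
  p <- if (pMethod == "normal") {
    2 * stats::pnorm(-abs(statistic))
  } else {
    a <- 5 * n * (n + 1) * (n - 1)^2 /
      (2 * (n - 2) * (5 * n^2 - 2 * n - 9)) - 0.5
    lo <- stats::pbeta(rvn / 4, a, a)
    min(1, 2 * min(lo, 1 - lo))
  }
  structure(list(rvn = rvn, statistic = statistic, p_value = p, n = n,
                 p_method = pMethod),
            class = "bartelsTest")
}

#' @export
print.bartelsTest <- function(x, ...) {
  cat(sprintf(
    "Bartels rank von Neumann test (n = %d): RVN = %.4f, z = %.4f, p = %.4g (%s)\n",
    x$n, x$rvn, x$statistic, x$p_value, x$p_method))
  invisible(x)
}

#' Seeded Erdos-Renyi G(n, m) random graph
#'
#' Uniform simple undirected graph with exactly \code{n} vertices and
#' \code{m} edges; the null model used for randomness and small-world
#' comparisons.
#'
#' @param n number of vertices.
#' @param m number of edges (0 <= m <= n(n-1)/2).
#' @param seed integer seed.
#' @return An igraph.
#' @export
erRandomGraph <- function(n, m, seed = 1) {
  if (m < 0 || m > n * (n - 1) / 2)
    stop("m must lie in [0, n(n-1)/2]", call. = FALSE)
  withr::with_seed(as.integer(seed), igraph::sample_gnm(n, m))
}

.mean_local_clustering <- function(g) {
  deg <- igraph::degree(g)
  if (!any(deg >= 2L)) return(NaN)
  tr <- igraph::transitivity(g, type = "local", isolates = "NaN")
  mean(tr[deg >= 2L])
}

#' Small-world coefficient against an Erdos-Renyi ensemble
#'
#' Computes, on the largest connected component of a unipartite graph, the
#' mean local clustering coefficient C_g (over nodes of degree >= 2, where
#' local clustering is defined) and the mean shortest-path length L_g, and
#' compares them with the means C_rand, L_rand over \code{nRand} seeded
#' G(n, m) random graphs matched to the component. The small-world
#' coefficient is S = gamma / lambda with gamma = C_g / C_rand and
#' lambda = L_g / L_rand; S >> 1 indicates small-world structure. Bipartite
#' input is refused, since local clustering is trivially zero in a two-mode
#' graph.
#'
#' @param G unipartite igraph; its largest component must have >= 4 nodes.
#' @param nRand size of the random ensemble (default 20).
#' @param seed integer seed.
#' @return Object of class \code{"smallWorldResult"}: list with \code{c_g},
#'   \code{l_g}, \code{c_rand}, \code{l_rand}, \code{gamma}, \code{lambda},
#'   \code{s}, \code{n}, \code{m}, \code{n_rand}.
#' @export
smallWorld <- function(G, nRand = 20, seed = 1) {
  if (!is.null(igraph::V(G)$type))
    stop("small-world statistics are undefined for bipartite graphs; ",
         "project to one mode first", call. = FALSE)
  lcc <- largestComponent(G)
  n <- igraph::vcount(lcc)
  m <- igraph::ecount(lcc)
  if (n < 4L)
    stop("largest component has fewer than 4 nodes", call. = FALSE)
  c_g <- .mean_local_clustering(lcc)
  l_g <- igraph::mean_distance(lcc, directed = FALSE)
  sims <- withr::with_seed(as.integer(seed), lapply(seq_len(nRand),
    function(i) {
      g <- igraph::sample_gnm(n, m)
      c(.mean_local_clustering(g),
        igraph::mean_distance(g, directed = FALSE))
    }))
  sims <- do.call(rbind, sims)
  c_rand <- mean(sims[, 1], na.rm = TRUE)
  l_rand <- mean(sims[, 2], na.rm = TRUE)
  if (!is.finite(c_rand) || c_rand == 0)
    stop("random ensemble has zero clustering; graph too sparse for the ",
         "comparison (increase nRand or use a denser graph)", call. = FALSE)
  gamma <- c_g / c_rand
  lambda <- l_g / l_rand
  structure(list(c_g = c_g, l_g = l_g, c_rand = c_rand, l_rand = l_rand,
                 gamma = gamma, lambda = lambda, s = gamma / lambda,
                 n = n, m = m, n_rand = nRand),
            class = "smallWorldResult")
}

#' @export
print.smallWorldResult <- function(x, ...) {
  cat(sprintf(
    "Small-world comparison (LCC n = %d, m = %d, %d ER replicates)\n",
    x$n, x$m, x$n_rand))
  cat(sprintf("  C_g = %.4f  C_rand = %.4f  gamma = %.3f\n",
              x$c_g, x$c_rand, x$gamma))
  cat(sprintf("  L_g = %.4f  L_rand = %.4f  lambda = %.3f\n",
              x$l_g, x$l_rand, x$lambda))
  cat(sprintf("  S = %.3f\n", x$s))
  invisible(x)
}

#' Fast-greedy modularity maximization
#'
#' Agglomerative greedy modularity optimization (Clauset-Newman-Moore),
#' returning the cut of the merge tree with maximum modularity Q. Edge
#' weights are used when present unless \code{weighted = FALSE}.
#'
#' @param G igraph with at least one edge (run it on a connected component).
#' @param weighted use the \code{weight} edge attribute if available.
#' @return Object of class \code{"modularityResult"}: list with
#'   \code{membership} (named integer vector) and \code{q} (maximum
#'   modularity).
#' @export
fastGreedyModularity <- function(G, weighted = TRUE) {
  if (igraph::ecount(G) == 0L)
    stop("graph has no edges", call. = FALSE)
  w <- if (weighted && !is.null(igraph::E(G)$weight))
    igraph::E(G)$weight else NULL
  cl <- igraph::cluster_fast_greedy(G, weights = w)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(G, memb, weights = w)
  structure(list(membership = memb, q = q), class = "modularityResult")
}

#' @export
print.modularityResult <- function(x, ...) {
  cat(sprintf("Fast-greedy communities: %d, max modularity Q = %.4f\n",
              length(unique(x$membership)), x$q))
  invisible(x)
}

#' Modularity Q from a membership vector
#'
#' Direct evaluation of the (weighted) Newman modularity of a partition,
#' used as the definitional cross-check of community detection output.
#'
#' @param G igraph.
#' @param membership community labels aligned with \code{V(G)}.
#' @param weighted use edge weights if present.
#' @return Scalar Q.
#' @export
modularityScore <- function(G, membership, weighted = TRUE) {
  w <- if (weighted && !is.null(igraph::E(G)$weight))
    igraph::E(G)$weight else NULL
  igraph::modularity(G, membership, weights = w)
}

#' Degree-dependent clustering C(k) scaling fit
#'
#' Hierarchical modularity predicts that the mean local clustering of
#' degree-k nodes scales as C(k) ~ k^-1. This computes mean local clustering
#' per degree class (k >= 2 only; smaller degrees have undefined clustering),
#' drops classes with zero mean (log-undefined), and fits ordinary least
#' squares to log10 C(k) vs log10 k. The r-squared is reported as the
#' strength of the scaling relationship.
#'
#' @param G unipartite igraph.
#' @return Object of class \code{"ckScalingFit"}: list with \code{slope},
#'   \code{intercept}, \code{r2}, \code{n_classes} and the per-class table
#'   \code{ck} (columns \code{k}, \code{mean_c}).
#' @export
ckScaling <- function(G) {
  deg <- igraph::degree(G)
  tr <- igraph::transitivity(G, type = "local", isolates = "NaN")
  keep <- deg >= 2L & is.finite(tr)
  if (!any(keep))
    stop("no degree classes with defined clustering", call. = FALSE)
  mean_c <- tapply(tr[keep], deg[keep], mean)
  k <- as.numeric(names(mean_c))
  nz <- mean_c > 0
  if (sum(nz) < 3L) {
    # a flat profile (e.g. a complete graph: every class at C = 1) has a
    # well-defined zero slope even with a single degree class
    if (sum(nz) >= 1L && diff(range(mean_c[nz])) < 1e-12) {
      return(structure(list(slope = 0, intercept = log10(mean_c[nz][1]),
                            r2 = 0, n_classes = sum(nz),
                            ck = data.frame(k = k[nz],
                                            mean_c = as.numeric(mean_c[nz]))),
                       class = "ckScalingFit"))
    }
    stop("fewer than 3 degree classes with nonzero mean clustering",
         call. = FALSE)
  }
  fit <- stats::lm(log10(mean_c[nz]) ~ log10(k[nz]))
  # a perfect 3-point fit makes summary.lm warn; the r2 itself is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 n_classes = sum(nz),
                 ck = data.frame(k = k[nz], mean_c = as.numeric(mean_c[nz]))),
            class = "ckScalingFit")
}

#' @export
print.ckScalingFit <- function(x, ...) {
  cat(sprintf(
    "C(k) scaling: slope = %.3f, intercept = %.3f, r2 = %.3f (%d classes)\n",
    x$slope, x$intercept, x$r2, x$n_classes))
  invisible(x)
}

#' Degree, betweenness and closeness centralities with top-k lists
#'
#' Computed on the largest connected component with unweighted shortest
#' paths. Betweenness is the unnormalized shortest-path pair count; closeness
#' is the inverse mean distance to the other component members. Ties in the
#' rankings are broken lexicographically by node id.
#'
#' @param G igraph.
#' @param k top-list size per metric (default 10).
#' @return Object of class \code{"centralityTable"}: list with
#'   \code{metrics} (per-node data.frame: node, degree, betweenness,
#'   closeness) and \code{top} (data.frame: metric, rank, node, value).
#' @export
centralityTable <- function(G, k = 10) {
  if (igraph::vcount(G) == 0L)
    stop("graph is empty", call. = FALSE)
  lcc <- largestComponent(G)
  nm <- igraph::V(lcc)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(lcc)))
  deg <- as.numeric(igraph::degree(lcc))
  btw <- as.numeric(igraph::betweenness(lcc, weights = NA))
  clo <- as.numeric(igraph::closeness(lcc, weights = NA,
                                      normalized = TRUE))
  metrics <- data.frame(node = nm, degree = deg, betweenness = btw,
                        closeness = clo, stringsAsFactors = FALSE)
  metrics <- metrics[order(metrics$node), , drop = FALSE]
  rownames(metrics) <- NULL
  top_one <- function(metric, val) {
    o <- order(-val, nm)
    kk <- min(k, length(o))
    data.frame(metric = metric, rank = seq_len(kk), node = nm[o[seq_len(kk)]],
               value = val[o[seq_len(kk)]], stringsAsFactors = FALSE)
  }
  top <- rbind(top_one("degree", deg), top_one("betweenness", btw),
               top_one("closeness", clo))
  structure(list(metrics = metrics, top = top), class = "centralityTable")
}

#' @export
print.centralityTable <- function(x, ...) {
  cat("Centralities on the largest component (", nrow(x$metrics),
      " nodes); top nodes:\n", sep = "")
  print(utils::head(x$top, 12), row.names = FALSE)
  invisible(x)
}

.lcc_degree_sequence <- function(g) {
  # degree sequence of the LCC ordered by lexicographic node id: the fixed,
  # reproducible series fed to the randomness test
  lcc <- largestComponent(g)
  nm <- igraph::V(lcc)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(lcc)))
  as.numeric(igraph::degree(lcc)[order(nm)])
}

.na_row <- function() {
  list(q_max = NA_real_, alpha = NA_real_, xmin = NA_real_,
       logLik = NA_real_, ks_stat = NA_real_, ks_p = NA_real_,
       bartels_stat = NA_real_, bartels_p = NA_real_,
       er_bartels_stat = NA_real_, er_bartels_p = NA_real_,
       c_g = NA_real_, l_g = NA_real_, c_rand = NA_real_,
       l_rand = NA_real_, gamma = NA_real_, lambda = NA_real_,
       s = NA_real_, ck_slope = NA_real_, ck_r2 = NA_real_)
}

#' Per-era statistical battery over the evolving networks
#'
#' For each threshold t (default 0.1, ..., 1.0) the subnetwork-enzyme
#' bipartite slice and its two one-mode projections are built and the full
#' battery is computed per graph: sizes, average degree (full graph and
#' largest component), diameter, maximum fast-greedy modularity, discrete
#' power-law fit of the component degree sequence, the Bartels randomness
#' test of that sequence and of a matched Erdos-Renyi graph's sequence, and
#' (projections only, clustering being undefined on two-mode graphs) the
#' small-world decomposition and the C(k) scaling fit. Statistics that
#' cannot be computed on a degenerate slice are reported as NA, with the
#' reason kept in the \code{"log"} attribute.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param ages named nd vector from \code{\link{enzymeAges}}.
#' @param ts age thresholds (default \code{seq(0.1, 1, 0.1)}).
#' @param nRand ER ensemble size for the small-world comparison.
#' @param reps bootstrap replicates for the power-law p-value.
#' @param pMethod power-law p-value method; see \code{\link{fitPowerLaw}}.
#' @param seed base seed; each row derives its own sub-seed.
#' @param weighted use projection edge weights in modularity.
#' @return data.frame with one row per (graph type, t); columns as in the
#'   description. The \code{"log"} attribute collects per-cell failures.
#' @export
metricsTimeline <- function(ds, ages, ts = seq(0.1, 1, 0.1), nRand = 20,
                            reps = 100, pMethod = c("bootstrap", "analytic"),
                            seed = 1, weighted = TRUE) {
  pMethod <- match.arg(pMethod)
  B <- buildBipartite(ds, ages, "subnetwork")
  rows <- list()
  log <- character(0)
  note <- function(type, t, stat, e) {
    log <<- c(log, sprintf("%s t=%.1f %s: %s", type, t, stat,
                           conditionMessage(e)))
    NULL
  }
  irow <- 0L
  for (t in ts) {
    slice <- sliceByAge(B, t)
    graphs <- list(bipartite = slice)
    if (igraph::vcount(slice) > 0L) {
      graphs$subnetwork_projection <- projectOneMode(slice, "category")
      graphs$enzyme_projection <- projectOneMode(slice, "enzyme")
    }
    for (type in names(graphs)) {
      irow <- irow + 1L
      g <- graphs[[type]]
      row_seed <- as.integer(seed) + irow
      out <- c(list(graph_type = type, nd = t,
                    n_nodes = igraph::vcount(g),
                    n_nodes_lcc = NA_integer_,
                    n_edges = igraph::ecount(g),
                    avg_degree = NA_real_, avg_degree_lcc = NA_real_,
                    diameter = NA_real_),
               .na_row())
      if (igraph::vcount(g) == 0L) {
        rows[[irow]] <- out
        next
      }
      lcc <- largestComponent(g)
      out$n_nodes_lcc <- igraph::vcount(lcc)
      out$avg_degree <- 2 * igraph::ecount(g) / igraph::vcount(g)
      out$avg_degree_lcc <- 2 * igraph::ecount(lcc) / igraph::vcount(lcc)
      out$diameter <- igraph::diameter(lcc, weights = NA)
      degseq <- .lcc_degree_sequence(g)

      pl <- tryCatch(suppressWarnings(
        fitPowerLaw(degseq[degseq > 0], pMethod = pMethod,
                    reps = reps, seed = row_seed)),
        error = function(e) note(type, t, "power_law", e))
      if (!is.null(pl)) {
        out$alpha <- pl$alpha; out$xmin <- pl$xmin; out$logLik <- pl$logLik
        out$ks_stat <- pl$ks_stat; out$ks_p <- pl$ks_p
      }
      bt <- tryCatch(bartelsRankTest(degseq),
                     error = function(e) note(type, t, "bartels", e))
      if (!is.null(bt)) {
        out$bartels_stat <- bt$statistic; out$bartels_p <- bt$p_value
      }
      er <- erRandomGraph(igraph::vcount(lcc), igraph::ecount(lcc),
                          seed = row_seed)
      ebt <- tryCatch(bartelsRankTest(as.numeric(igraph::degree(er))),
                      error = function(e) note(type, t, "er_bartels", e))
      if (!is.null(ebt)) {
        out$er_bartels_stat <- ebt$statistic
        out$er_bartels_p <- ebt$p_value
      }
      md <- tryCatch(fastGreedyModularity(lcc, weighted = weighted),
                     error = function(e) note(type, t, "modularity", e))
      if (!is.null(md)) out$q_max <- md$q
      if (type != "bipartite") {
        sw <- tryCatch(smallWorld(g, nRand = nRand, seed = row_seed),
                       error = function(e) note(type, t, "small_world", e))
        if (!is.null(sw)) {
          out$c_g <- sw$c_g; out$l_g <- sw$l_g
          out$c_rand <- sw$c_rand; out$l_rand <- sw$l_rand
          out$gamma <- sw$gamma; out$lambda <- sw$lambda; out$s <- sw$s
        }
        ck <- tryCatch(ckScaling(lcc),
                       error = function(e) note(type, t, "ck_scaling", e))
        if (!is.null(ck)) {
          out$ck_slope <- ck$slope; out$ck_r2 <- ck$r2
        }
      }
      rows[[irow]] <- out
    }
  }
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(res) <- NULL
  attr(res, "log") <- log
  res
}
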