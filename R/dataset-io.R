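.read_tsv <- function(path, cols) {
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, cols, drop = FALSE]
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  path
}

#' Read an integrated dataset from TSV tables
#'
#' Expects \code{domains.tsv} (ec, scop_ccs, nd), \code{membership.tsv}
#' (ec, map_id) and \code{hierarchy.tsv} (map_id, map_name, meso_code) in
#' \code{dir}; the optional annotation tables \code{taxa.tsv} (ec, species,
#' superkingdom), \code{functions.tsv} (fsf_id, general, detailed) and
#' \code{catalysis.tsv} (ec, residue, role_group) are read when present.
#' Rows are deduplicated and membership rows referring to maps absent from
#' the hierarchy are dropped (reported via the \code{"unresolved_map_ids"}
#' attribute of the result).
#'
#' All tables are single-header UTF-8 TSV with '.' as decimal separator.
#'
#' @param dir directory containing the tables, or a named character vector of
#'   file paths with names \code{domains}, \code{membership},
#'   \code{hierarchy} (and optionally \code{taxa}, \code{functions},
#'   \code{catalysis}).
#' @return A \code{\link{MetabolicDataset-class}}.
#' @seealso \code{\link{writeDataset}}, \code{\link{validateDataset}}
#' @export
readDataset <- function(dir) {
  if (length(dir) == 1L && is.null(names(dir))) {
    paths <- c(domains = file.path(dir, "domains.tsv"),
               membership = file.path(dir, "membership.tsv"),
               hierarchy = file.path(dir, "hierarchy.tsv"),
               taxa = file.path(dir, "taxa.tsv"),
               functions = file.path(dir, "functions.tsv"),
               catalysis = file.path(dir, "catalysis.tsv"))
  } else {
    paths <- dir
  }
  req <- c("domains", "membership", "hierarchy")
  if (!all(req %in% names(paths)))
    stop("paths must name at least: ", paste(req, collapse = ", "),
         call. = FALSE)
  domains <- .read_tsv(paths[["domains"]], c("ec", "scop_ccs", "nd"))
  nd <- suppressWarnings(as.numeric(domains$nd))
  bad <- which(!is.finite(nd) | nd < 0 | nd > 1)
  if (length(bad) > 0L)
    stop("validation error in ", basename(paths[["domains"]]),
         ": nd outside [0,1] (or non-numeric) at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  domains$nd <- nd
  membership <- .read_tsv(paths[["membership"]], c("ec", "map_id"))
  hier <- .read_tsv(paths[["hierarchy"]],
                    c("map_id", "map_name", "meso_code"))
  ann <- list()
  if (!is.na(paths["taxa"]) && file.exists(paths[["taxa"]]))
    ann$taxa <- .read_tsv(paths[["taxa"]], c("ec", "species", "superkingdom"))
  if (!is.na(paths["functions"]) && file.exists(paths[["functions"]]))
    ann$functions <- .read_tsv(paths[["functions"]],
                               c("fsf_id", "general", "detailed"))
  if (!is.na(paths["catalysis"]) && file.exists(paths[["catalysis"]]))
    ann$catalysis <- .read_tsv(paths[["catalysis"]],
                               c("ec", "residue", "role_group"))
  MetabolicDataset(domains, membership, hier, ann)
}

#' Write a dataset as canonical TSV tables
#'
#' Writes \code{domains.tsv}, \code{membership.tsv}, \code{hierarchy.tsv}
#' and any annotation tables present, with deterministic column order and row
#' sort so outputs are diffable; two writes of the same dataset are
#' byte-identical.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "MetabolicDataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  d <- domains(ds)
  # fixed-format ages so round-trips are exact on printed precision
  d$nd <- formatC(d$nd, format = "g", digits = 15)
  files <- c(.write_tsv(d, file.path(dir, "domains.tsv")),
             .write_tsv(memberships(ds), file.path(dir, "membership.tsv")),
             .write_tsv(hierarchy(ds), file.path(dir, "hierarchy.tsv")))
  ann <- annotations(ds)
  if (!is.null(ann$taxa))
    files <- c(files, .write_tsv(ann$taxa, file.path(dir, "taxa.tsv")))
  if (!is.null(ann$functions))
    files <- c(files, .write_tsv(ann$functions,
                                 file.path(dir, "functions.tsv")))
  if (!is.null(ann$catalysis))
    files <- c(files, .write_tsv(ann$catalysis,
                                 file.path(dir, "catalysis.tsv")))
  invisible(files)
}

#' Summarize a dataset (counts, orphans, coverage)
#'
#' Report-only validation in the style of a database statistics table:
#' entity counts, enzymes lacking any aged domain ("unpainted"), the fraction
#' of enzymes with at least one domain age (the painting-coverage analog),
#' and orphan lists (maps with no enzymes, memberships of unknown enzymes).
#' Degenerate inputs (e.g. an empty membership table) are flagged, never an
#' error.
#'
#' @param ds a \code{\link{MetabolicDataset-class}}.
#' @return A list of class \code{"metanet_validation"} with elements
#'   \code{n_enzymes}, \code{n_subnetworks}, \code{n_mesonetworks},
#'   \code{n_domain_assignments}, \code{n_membership_links},
#'   \code{coverage} (fraction of enzymes with >= 1 domain age),
#'   \code{unpainted} (ECs without domains), \code{empty_maps} (map_ids with
#'   no member enzymes) and \code{flags} (character vector of warnings).
#' @export
validateDataset <- function(ds) {
  stopifnot(is(ds, "MetabolicDataset"))
  ecs <- enzymes(ds)
  with_dom <- unique(domains(ds)$ec)
  unpainted <- sort(setdiff(ecs, with_dom))
  empty_maps <- sort(setdiff(hierarchy(ds)$map_id, memberships(ds)$map_id))
  flags <- character(0)
  if (nrow(memberships(ds)) == 0L)
    flags <- c(flags, "membership table is empty: 0 subnetwork links")
  if (length(unpainted) > 0L)
    flags <- c(flags, paste0(length(unpainted),
                             " enzyme(s) have no domain age"))
  res <- list(
    n_enzymes = length(ecs),
    n_subnetworks = length(unique(hierarchy(ds)$map_id)),
    n_mesonetworks = length(unique(hierarchy(ds)$meso_code)),
    n_domain_assignments = nrow(domains(ds)),
    n_membership_links = nrow(memberships(ds)),
    coverage = if (length(ecs) == 0L) NA_real_ else
      length(intersect(ecs, with_dom)) / length(ecs),
    unpainted = unpainted,
    empty_maps = empty_maps,
    flags = flags
  )
  class(res) <- "metanet_validation"
  res
}

#' @export
print.metanet_validation <- function(x, ...) {
  cat("Dataset validation report\n")
  cat(sprintf("  enzymes: %d  subnetworks: %d  mesonetworks: %d\n",
              x$n_enzymes, x$n_subnetworks, x$n_mesonetworks))
  cat(sprintf("  domain assignments: %d  membership links: %d\n",
              x$n_domain_assignments, x$n_membership_links))
  cat(sprintf("  domain-age coverage: %s\n",
              ifelse(is.na(x$coverage), "NA",
                     sprintf("%.3f", x$coverage))))
  for (f in x$flags) cat("  ! ", f, "\n", sep = "")
  invisible(x)
}
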