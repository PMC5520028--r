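#' Build a lineage from a semicolon-separated string or vector
#'
#' Lineages run coarse to fine (domain downward). Empty taxon names are
#' rejected.
#'
#' @param x character vector of taxon names, or a single
#'   \code{";"}-separated string.
#' @return character vector of class \code{gp_lineage}.
#' @examples
#' lineage("Bacteria;Firmicutes;Clostridia")
#' @export
lineage <- function(x) {
  if (length(x) == 1 && grepl(";", x)) x <- strsplit(x, ";")[[1]]
  x <- trimws(as.character(x))
  if (length(x) == 0 || any(x == "" | is.na(x)))
    stop("lineage must be a non-empty list of non-empty taxon names",
         call. = FALSE)
  structure(x, class = "gp_lineage")
}

#' @export
#' @method format gp_lineage
format.gp_lineage <- function(x, ...) paste(unclass(x), collapse = ";")

#' @export
print.gp_lineage <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Consensus taxonomy across up to three assignment methods
#'
#' Bins are typically assigned taxonomy independently from 16S rRNA genes,
#' from concatenated ribosomal proteins, and from a per-gene best-hit vote.
#' Where the methods disagree the bin is placed at the most specific rank on
#' which all available methods still agree: the longest shared lineage
#' prefix. Absent methods (\code{NULL}) are skipped, with a warning when
#' fewer than three are available. If even the domain is contested the
#' consensus is the single rank \code{"unassigned"}.
#'
#' @param l16s,lrib,lvote lineages (see \code{\link{lineage}}) or \code{NULL}.
#' @return A \code{gp_lineage}.
#' @examples
#' consensus_taxonomy(lineage("Bacteria;Firmicutes;Clostridia"),
#'                    lineage("Bacteria;Firmicutes;Bacilli"),
#'                    lineage("Bacteria;Firmicutes;Clostridia"))
#' @export
consensus_taxonomy <- function(l16s = NULL, lrib = NULL, lvote = NULL) {
  ls <- Filter(Negate(is.null), list(l16s, lrib, lvote))
  if (length(ls) == 0)
    stop("no taxonomy evidence", call. = FALSE)
  if (length(ls) < 3)
    warning("consensus over ", length(ls), " of 3 taxonomy methods",
            call. = FALSE)
  ls <- lapply(ls, function(l) unclass(lineage(l)))
  n <- min(lengths(ls))
  shared <- 0L
  for (i in seq_len(n)) {
    taxa <- vapply(ls, `[[`, character(1), i)
    if (length(unique(taxa)) == 1L) shared <- i else break
  }
  if (shared == 0L) return(lineage("unassigned"))
  lineage(ls[[1]][seq_len(shared)])
}
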