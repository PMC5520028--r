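#' Count CXXCH heme-binding motifs in a protein
#'
#' The c-type cytochrome heme attachment site is the pattern
#' cysteine - any - any - cysteine - histidine. Every qualifying start
#' position is counted, including overlapping occurrences, since heme-binding
#' sites can tile closely in multiheme cytochromes. The two wildcard
#' positions accept any residue; the constrained positions accept only the
#' exact letters, so ambiguity codes (\code{X}) never create a motif.
#'
#' @param protein a single uppercased amino-acid string (may contain
#'   \code{X}, \code{U}, \code{*}).
#' @return list with \code{count} (integer) and \code{starts} (1-based
#'   motif start positions, strictly increasing).
#' @examples
#' count_cxxch("CAACH")        # one motif at position 1
#' count_cxxch("CAACHACH")     # overlapping motifs at 1 and 4
#' @export
count_cxxch <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1)
  if (is.na(protein) || nchar(protein) < 5)
    return(list(count = 0L, starts = integer(0)))
  m <- gregexpr("(?=C..CH)", protein, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  list(count = length(starts), starts = starts)
}

#' Call multiheme cytochromes across a proteome
#'
#' Scans every protein for CXXCH motifs and labels it an MHC when the motif
#' count reaches \code{thresholds$mhc_min_motifs} (default 10).
#'
#' @param proteome named character vector (gene_id -> protein), as returned
#'   by \code{\link{parse_protein_fasta}}.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return data.frame with columns gene_id, motif_count, is_mhc, and a list
#'   column motif_starts.
#' @export
call_mhcs <- function(proteome, thresholds = gp_thresholds()) {
  if (length(proteome) == 0)
    stop("proteome is empty", call. = FALSE)
  scans <- lapply(unname(proteome), count_cxxch)
  counts <- vapply(scans, `[[`, integer(1), "count")
  data.frame(
    gene_id = names(proteome),
    motif_count = counts,
    is_mhc = counts >= thresholds$mhc_min_motifs,
    motif_starts = I(lapply(scans, `[[`, "starts")),
    stringsAsFactors = FALSE
  )
}

#' Predict dissimilatory iron reducers from per-bin MHC content
#'
#' A genome carrying several multiheme cytochromes is a candidate
#' dissimilatory iron reducer; the default threshold flags bins with 4 or
#' more MHC proteins. The maximum motif count in any single protein is also
#' reported, since exceptionally heme-rich cytochromes (50+ motifs) are of
#' interest in their own right.
#'
#' @param mhc_records output of \code{\link{call_mhcs}}.
#' @param gene_bins data.frame with columns gene_id, bin_id mapping scanned
#'   genes to bins; a gene mapped to two bins is an error.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @param bin_ids optional character vector of bins to report even when none
#'   of their genes were scanned (reported with n_mhcs 0).
#' @return data.frame with columns bin_id, n_mhcs, max_motifs_single_protein,
#'   predicted_iron_reducer.
#' @export
predict_iron_reducers <- function(mhc_records, gene_bins,
                                  thresholds = gp_thresholds(),
                                  bin_ids = NULL) {
  map <- unique(gene_bins[, c("gene_id", "bin_id")])
  if (anyDuplicated(map$gene_id))
    stop("gene(s) assigned to more than one bin: ",
         paste(unique(map$gene_id[duplicated(map$gene_id)]), collapse = ", "),
         call. = FALSE)
  rec <- merge(mhc_records[, c("gene_id", "motif_count", "is_mhc")], map,
               by = "gene_id")
  bins <- sort(unique(c(map$bin_id, bin_ids)))
  n_mhcs <- vapply(bins, function(b)
    sum(rec$is_mhc[rec$bin_id == b]), integer(1))
  max_m <- vapply(bins, function(b) {
    mc <- rec$motif_count[rec$bin_id == b]
    if (length(mc) == 0) 0L else max(mc)
  }, integer(1))
  data.frame(
    bin_id = bins,
    n_mhcs = n_mhcs,
    max_motifs_single_protein = max_m,
    predicted_iron_reducer = n_mhcs >= thresholds$iron_min_mhcs,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Evaluate the MHC-based iron-reduction predictor against known labels
#'
#' Computes the two numbers that summarise a reference-database validation
#' of the predictor: the prevalence of flagged genomes among all genomes
#' screened, and the precision of the flag against genomes already known (or
#' predicted) to respire iron. Flagged genomes without a label are excluded
#' from the precision denominator, with a warning.
#'
#' @param predictions output of \code{\link{predict_iron_reducers}}.
#' @param labels named logical vector: bin_id -> known iron reducer.
#' @return list with \code{prevalence} and \code{precision} (precision is
#'   \code{NA} when no bin is flagged or no flagged bin is labelled).
#' @examples
#' preds <- data.frame(bin_id = c("a", "b", "c"), n_mhcs = c(5, 4, 0),
#'                     max_motifs_single_protein = c(50, 12, 0),
#'                     predicted_iron_reducer = c(TRUE, TRUE, FALSE))
#' evaluate_predictor(preds, c(a = TRUE, b = FALSE, c = FALSE))
#' @export
evaluate_predictor <- function(predictions, labels) {
  flagged <- predictions$bin_id[predictions$predicted_iron_reducer]
  prevalence <- length(flagged) / nrow(predictions)
  unlabeled <- setdiff(flagged, names(labels))
  if (length(unlabeled) > 0)
    warning(length(unlabeled),
            " flagged bin(s) without a label excluded from precision",
            call. = FALSE)
  lab_flagged <- intersect(flagged, names(labels))
  precision <- if (length(lab_flagged) == 0) NA_real_ else
    sum(labels[lab_flagged]) / length(lab_flagged)
  list(prevalence = prevalence, precision = precision)
}
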