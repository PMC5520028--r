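#' Analysis thresholds
#'
#' Bundles every tunable cutoff used across the pipeline into one validated
#' list, so that any number appearing in an output can be traced to a single
#' configuration object. Defaults reproduce the operational definitions used
#' throughout the package: a protein is a multiheme cytochrome (MHC) at 10 or
#' more CXXCH motifs; a genome is flagged as a candidate iron reducer at 4 or
#' more MHCs; a bin is a high-quality draft above 70% completeness and below
#' 10% contamination; alignment columns are dropped above 90% gaps, sequences
#' below 50% aligned positions, and taxa need at least 450 aligned positions
#' to be tree-eligible; organisms below 0.1% of community depth are "rare".
#'
#' @param mhc_min_motifs minimum CXXCH motif count for a protein to be called
#'   an MHC (count, default 10).
#' @param iron_min_mhcs minimum number of MHC proteins in a bin to predict
#'   dissimilatory iron reduction (count, default 4).
#' @param hq_min_completeness completeness a bin must exceed (strictly) to be
#'   high quality (percent, default 70).
#' @param hq_max_contamination contamination a bin must stay (strictly) below
#'   (percent, default 10).
#' @param gap_col_max_frac alignment columns with a gap fraction above this
#'   are removed (fraction, default 0.90).
#' @param seq_min_aligned_frac concatenated sequences with a non-gap fraction
#'   below this are dropped (fraction, default 0.50).
#' @param tree_min_positions minimum non-gap columns for tree eligibility
#'   (count, default 450).
#' @param rare_abundance_frac relative-abundance cutoff separating rare
#'   organisms (fraction, default 0.001, i.e. 0.1%).
#' @param cooccur_ratio maximum fold-difference in mean abundance for two
#'   genomes to enter the optional abundance-correlation screen (default 10).
#' @param operon_window genes examined downstream of a catalytic hydrogenase
#'   subunit when resolving [FeFe] Group A subgroups (count, default 3).
#' @param derep_identity nucleotide identity at or above which two bins are
#'   considered replicates (fraction, default 0.98).
#' @param derep_aligned_frac minimum aligned fraction (of the shorter genome)
#'   for a dereplication edge (fraction, default 0.50).
#' @param rps3_cluster_identity amino-acid identity for collapsing rpS3
#'   sequences into one organism (fraction, default 0.99).
#'
#' @return An object of class \code{gp_thresholds} (a named list).
#' @examples
#' th <- gp_thresholds()
#' th$mhc_min_motifs
#' gp_thresholds(operon_window = 4)$operon_window
#' @export
gp_thresholds <- function(mhc_min_motifs = 10L,
                          iron_min_mhcs = 4L,
                          hq_min_completeness = 70,
                          hq_max_contamination = 10,
                          gap_col_max_frac = 0.90,
                          seq_min_aligned_frac = 0.50,
                          tree_min_positions = 450L,
                          rare_abundance_frac = 0.001,
                          cooccur_ratio = 10,
                          operon_window = 3L,
                          derep_identity = 0.98,
                          derep_aligned_frac = 0.50,
                          rps3_cluster_identity = 0.99) {
  th <- list(
    mhc_min_motifs = as.integer(mhc_min_motifs),
    iron_min_mhcs = as.integer(iron_min_mhcs),
    hq_min_completeness = as.numeric(hq_min_completeness),
    hq_max_contamination = as.numeric(hq_max_contamination),
    gap_col_max_frac = as.numeric(gap_col_max_frac),
    seq_min_aligned_frac = as.numeric(seq_min_aligned_frac),
    tree_min_positions = as.integer(tree_min_positions),
    rare_abundance_frac = as.numeric(rare_abundance_frac),
    cooccur_ratio = as.numeric(cooccur_ratio),
    operon_window = as.integer(operon_window),
    derep_identity = as.numeric(derep_identity),
    derep_aligned_frac = as.numeric(derep_aligned_frac),
    rps3_cluster_identity = as.numeric(rps3_cluster_identity)
  )
  validate_thresholds(th)
  structure(th, class = "gp_thresholds")
}

validate_thresholds <- function(th) {
  counts <- c("mhc_min_motifs", "iron_min_mhcs", "tree_min_positions",
              "operon_window")
  fracs <- c("gap_col_max_frac", "seq_min_aligned_frac",
             "rare_abundance_frac", "derep_identity", "derep_aligned_frac",
             "rps3_cluster_identity")
  pcts <- c("hq_min_completeness", "hq_max_contamination")
  for (f in counts) {
    if (is.na(th[[f]]) || th[[f]] < 1L)
      stop("threshold '", f, "' must be a count >= 1", call. = FALSE)
  }
  for (f in fracs) {
    if (is.na(th[[f]]) || th[[f]] < 0 || th[[f]] > 1)
      stop("threshold '", f, "' must be a fraction in [0, 1]", call. = FALSE)
  }
  for (f in pcts) {
    if (is.na(th[[f]]) || th[[f]] < 0 || th[[f]] > 100)
      stop("threshold '", f, "' must be a percent in [0, 100]", call. = FALSE)
  }
  if (is.na(th$cooccur_ratio) || th$cooccur_ratio < 1)
    stop("threshold 'cooccur_ratio' must be a fold-ratio >= 1", call. = FALSE)
  invisible(th)
}

#' Read threshold overrides from a JSON file
#'
#' The file holds a flat JSON object whose keys are \code{gp_thresholds()}
#' argument names; unknown keys are rejected. Values not mentioned keep
#' their defaults.
#'
#' @param path path to a JSON file.
#' @return A \code{gp_thresholds} object.
#' @export
read_thresholds_json <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(gp_thresholds))
  bad <- setdiff(names(ov), known)
  if (length(bad) > 0)
    stop("unknown threshold key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(gp_thresholds, as.list(ov))
}

#' @export
print.gp_thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
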