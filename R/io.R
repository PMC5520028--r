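#' Read a protein FASTA into a gene -> sequence map
#'
#' Header tokens up to the first whitespace become gene ids. Sequences are
#' uppercased and a terminal stop character \code{*} is stripped, so that
#' downstream motif scanning sees a uniform alphabet. Selenocysteine
#' (\code{U}) and ambiguity (\code{X}) are tolerated residues.
#'
#' @param path path to a FASTA file of protein sequences.
#' @return Named character vector: gene_id -> protein string.
#' @export
parse_protein_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0)
    stop("empty sequence(s) in ", path, ": ",
         paste(empty, collapse = ", "), call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write a gene -> sequence map as FASTA
#'
#' @param proteome named character vector (gene_id -> sequence).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(proteome, path) {
  stopifnot(!is.null(names(proteome)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(proteome), path)
  invisible(path)
}

#' Parse a profile-search hit table
#'
#' Ingests the whitespace-delimited domain-table dialect written by profile
#' searches (\code{hmmsearch --domtblout}): comment lines start with
#' \code{#}; for full-width rows the target (gene) is column 1, the query
#' (profile) column 4, the full-sequence E-value column 7 and the
#' full-sequence bit score column 8. Compact 3- or 4-column tables
#' (gene, profile, bit_score[, e_value]) are accepted for the same fields.
#'
#' Hits scoring below their profile's cutoff are dropped. Profiles with no
#' entry in \code{cutoffs} are kept unfiltered, with one warning naming them.
#'
#' @param path path to the hit table.
#' @param cutoffs named numeric vector of per-profile minimum bit scores
#'   (may be empty; profiles absent from it are "unknown" and kept).
#' @return data.frame with columns gene_id, profile, bit_score, e_value.
#' @export
parse_profile_hits <- function(path, cutoffs = numeric(0)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), profile = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE))
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 8) {
      out <- c(f[1], f[4], f[8], f[7])
    } else if (length(f) %in% c(3L, 4L)) {
      out <- c(f[1], f[2], f[3], if (length(f) == 4L) f[4] else "NA")
    } else {
      stop("unparseable hit row at line ", i, " of ", path, call. = FALSE)
    }
    score <- suppressWarnings(as.numeric(out[3]))
    evalue <- suppressWarnings(as.numeric(out[4]))
    if (is.na(score))
      stop("non-numeric bit score at line ", i, " of ", path, call. = FALSE)
    if (!is.na(evalue) && evalue < 0)
      stop("negative E-value at line ", i, " of ", path, call. = FALSE)
    list(gene_id = out[1], profile = out[2], bit_score = score,
         e_value = evalue)
  }
  parsed <- lapply(rows, parse_row)
  hits <- data.frame(
    gene_id = vapply(parsed, `[[`, character(1), "gene_id"),
    profile = vapply(parsed, `[[`, character(1), "profile"),
    bit_score = vapply(parsed, `[[`, numeric(1), "bit_score"),
    e_value = vapply(parsed, `[[`, numeric(1), "e_value"),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(hits$profile), names(cutoffs))
  if (length(cutoffs) > 0 && length(unknown) > 0)
    warning("no score cutoff for profile(s): ",
            paste(unknown, collapse = ", "), "; hits kept unfiltered",
            call. = FALSE)
  has_cut <- hits$profile %in% names(cutoffs)
  drop <- has_cut & hits$bit_score < cutoffs[hits$profile]
  hits[!drop, , drop = FALSE]
}

#' Build a uniform per-profile cutoff table
#'
#' @param profiles character vector of profile names.
#' @param bit_score the bit-score cutoff applied to each (default 50).
#' @return named numeric vector usable as \code{cutoffs} in
#'   \code{\link{parse_profile_hits}}.
#' @export
uniform_cutoffs <- function(profiles, bit_score = 50) {
  stats::setNames(rep(as.numeric(bit_score), length(profiles)), profiles)
}

#' Read a per-scaffold, per-sample coverage table
#'
#' TSV with a header row; the first column holds scaffold ids, remaining
#' columns one mean read depth per sample. Blank cells become 0 with a
#' warning; negative depths and duplicated scaffold rows are errors.
#'
#' @param path path to the TSV.
#' @return numeric matrix, rows = scaffolds, columns = samples.
#' @export
parse_coverage_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("coverage table needs a scaffold column plus >=1 sample column",
         call. = FALSE)
  scafs <- as.character(df[[1]])
  if (anyDuplicated(scafs))
    stop("duplicated scaffold row(s) in ", path, ": ",
         paste(unique(scafs[duplicated(scafs)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- scafs
  if (anyNA(m)) {
    warning(sum(is.na(m)), " missing coverage cell(s) set to 0",
            call. = FALSE)
    m[is.na(m)] <- 0
  }
  if (any(m < 0))
    stop("negative depth value(s) in ", path, call. = FALSE)
  if (any(!is.finite(m)))
    stop("non-finite depth value(s) in ", path, call. = FALSE)
  m
}

#' Write a coverage matrix as TSV
#' @param coverage numeric matrix (scaffold x sample).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_coverage_table <- function(coverage, path) {
  # 17 significant digits so the double -> text -> double round trip is exact
  cells <- formatC(coverage, digits = 17, format = "g")
  df <- data.frame(scaffold_id = rownames(coverage), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("scaffold_id", colnames(coverage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene calls from GFF3
#'
#' CDS (or gene) features are read; the \code{ID} attribute is the gene id.
#' Ordinals number the genes of each scaffold by ascending start coordinate,
#' irrespective of strand, so "downstream" can be defined per strand.
#'
#' @param path path to a GFF3 file.
#' @param proteome optional named character vector (from
#'   \code{\link{parse_protein_fasta}}); when given, a \code{protein} column
#'   is attached and genes without a sequence raise an error.
#' @return data.frame with columns gene_id, scaffold_id, start, end, strand,
#'   ordinal (and protein when \code{proteome} is given).
#' @export
read_gene_calls <- function(path, proteome = NULL) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene"), , drop = FALSE]
  if (nrow(gr) == 0)
    stop("no CDS/gene features in ", path, call. = FALSE)
  df <- data.frame(
    gene_id = as.character(gr$ID),
    scaffold_id = as.character(gr$seqnames),
    start = as.integer(gr$start),
    end = as.integer(gr$end),
    strand = as.character(gr$strand),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$gene_id) | df$gene_id == ""))
    stop("gene call without ID attribute in ", path, call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s) in ", path, call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene calls must carry explicit +/- strand", call. = FALSE)
  df <- df[order(df$scaffold_id, df$start), , drop = FALSE]
  df$ordinal <- stats::ave(df$start, df$scaffold_id,
                           FUN = seq_along)
  df$ordinal <- as.integer(df$ordinal)
  rownames(df) <- NULL
  if (!is.null(proteome)) {
    miss <- setdiff(df$gene_id, names(proteome))
    if (length(miss) > 0)
      stop("gene call(s) without protein sequence: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    df$protein <- unname(proteome[df$gene_id])
  }
  df
}

#' Write gene calls as GFF3
#' @param genes data.frame as returned by \code{\link{read_gene_calls}}.
#' @param path output path.
#' @param source string for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_gene_calls_gff3 <- function(genes, path, source = "genopotential") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$scaffold_id, source, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bin membership table
#'
#' TSV with columns \code{bin_id} and \code{scaffold_id}. Each scaffold may
#' belong to at most one bin.
#'
#' @param path path to the TSV.
#' @return data.frame with columns bin_id, scaffold_id.
#' @export
read_bin_membership <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("bin_id", "scaffold_id") %in% names(df)))
    stop("bin membership table needs columns bin_id, scaffold_id",
         call. = FALSE)
  dup <- df$scaffold_id[duplicated(df$scaffold_id)]
  if (length(dup) > 0)
    stop("scaffold(s) assigned to more than one bin: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  df[, c("bin_id", "scaffold_id")]
}

#' Write a bin membership table
#' @param membership data.frame with columns bin_id, scaffold_id.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bin_membership <- function(membership, path) {
  utils::write.table(membership[, c("bin_id", "scaffold_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write profile hits in compact 4-column form
#' @param hits data.frame with gene_id, profile, bit_score, e_value.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_hits <- function(hits, path) {
  lines <- c("# gene_id profile bit_score e_value",
             sprintf("%s %s %g %g", hits$gene_id, hits$profile,
                     hits$bit_score,
                     ifelse(is.na(hits$e_value), 1e-30, hits$e_value)))
  writeLines(lines, path)
  invisible(path)
}
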