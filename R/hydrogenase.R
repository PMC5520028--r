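#' Hydrogenase family profile vocabulary
#'
#' Maps profile labels to (cofactor, group): \code{NiFe_G1}..\code{NiFe_G4}
#' for the four [NiFe] groups, \code{FeFe_GA}/\code{FeFe_GB}/\code{FeFe_GC}
#' for [FeFe] groups A-C, and \code{Fe_hmd} for the [Fe] (Hmd) enzymes.
#'
#' @return data.frame with columns profile, cofactor, group.
#' @export
hydrogenase_profiles <- function() {
  data.frame(
    profile = c("NiFe_G1", "NiFe_G2", "NiFe_G3", "NiFe_G4",
                "FeFe_GA", "FeFe_GB", "FeFe_GC", "Fe_hmd"),
    cofactor = c(rep("NiFe", 4), rep("FeFe", 3), "Fe"),
    group = c("1", "2", "3", "4", "A", "B", "C", "Fe"),
    stringsAsFactors = FALSE
  )
}

#' Assign hydrogenase cofactor and group for one gene
#'
#' The best-scoring hydrogenase-family hit wins. Exact score ties are broken
#' by lexicographic profile name and flagged ambiguous. Genes with no
#' hydrogenase-family hit give a no-call (\code{NULL}).
#'
#' @param hits_for_gene data.frame of already cutoff-filtered profile hits
#'   for a single gene (columns profile, bit_score).
#' @return list(cofactor, group, profile, bit_score, ambiguous) or
#'   \code{NULL}.
#' @export
assign_group <- function(hits_for_gene) {
  fam <- hydrogenase_profiles()
  h <- hits_for_gene[hits_for_gene$profile %in% fam$profile, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  top <- h[h$bit_score == max(h$bit_score), , drop = FALSE]
  ambiguous <- length(unique(top$profile)) > 1
  best <- sort(top$profile)[1]
  i <- match(best, fam$profile)
  list(cofactor = fam$cofactor[i], group = fam$group[i], profile = best,
       bit_score = max(h$bit_score), ambiguous = ambiguous)
}

# Downstream ordinals for a gene given its strand: increasing ordinal on +,
# decreasing on -. Returns the gene rows in walking order, plus whether the
# window ran into the scaffold end before filling.
downstream_window <- function(gene_row, scaffold_genes, window) {
  ord <- scaffold_genes$ordinal
  if (gene_row$strand == "+") {
    idx <- which(ord > gene_row$ordinal)
    idx <- idx[order(ord[idx])]
  } else {
    idx <- which(ord < gene_row$ordinal)
    idx <- idx[order(ord[idx], decreasing = TRUE)]
  }
  truncated <- length(idx) < window
  idx <- utils::head(idx, window)
  list(genes = scaffold_genes[idx, , drop = FALSE], truncated = truncated)
}

#' Resolve a [FeFe] Group A hydrogenase into subgroup A1 or A3
#'
#' Electron-bifurcating Group A3 enzymes are heterotrimeric: the catalytic
#' subunit is encoded with a diaphorase subunit (hydB, multiple [4Fe-4S]
#' clusters) and a small [2Fe-2S] subunit (hydC) immediately downstream.
#' Monomeric Group A1 enzymes lack both. The classifier walks up to
#' \code{thresholds$operon_window} genes downstream of the catalytic gene in
#' its strand's reading direction; finding co-oriented hydB AND hydC genes
#' there gives A3. If the window is cut short by the scaffold end and the A3
#' evidence is incomplete, the call is A_unresolved (the operon may continue
#' on an unassembled fragment); otherwise A1.
#'
#' @param gene_id the catalytic [FeFe] Group A gene.
#' @param genes gene-call data.frame (see \code{\link{read_gene_calls}})
#'   covering at least the gene's scaffold.
#' @param hits cutoff-filtered profile hits (for hydB/hydC role labels).
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return list(subgroup, evidence) where evidence is a data.frame
#'   (gene_id, role) of the supporting neighbors.
#' @export
resolve_groupA <- function(gene_id, genes, hits,
                           thresholds = gp_thresholds()) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i))
    stop("gene ", gene_id, " not present in the gene calls", call. = FALSE)
  gene_row <- genes[i, ]
  sg <- genes[genes$scaffold_id == gene_row$scaffold_id, , drop = FALSE]
  win <- downstream_window(gene_row, sg, thresholds$operon_window)
  nb <- win$genes[win$genes$strand == gene_row$strand, , drop = FALSE]
  role_of <- function(g) {
    p <- hits$profile[hits$gene_id == g]
    if ("hydB" %in% p) "hydB" else if ("hydC" %in% p) "hydC" else NA_character_
  }
  roles <- if (nrow(nb) > 0)
    vapply(nb$gene_id, role_of, character(1)) else character(0)
  ev <- data.frame(gene_id = nb$gene_id[!is.na(roles)],
                   role = roles[!is.na(roles)],
                   stringsAsFactors = FALSE)
  has_b <- "hydB" %in% ev$role
  has_c <- "hydC" %in% ev$role
  subgroup <- if (has_b && has_c) "A3"
              else if (win$truncated) "A_unresolved"
              else "A1"
  list(subgroup = subgroup, evidence = ev)
}

#' Call all hydrogenases in a gene set
#'
#' Runs \code{\link{assign_group}} on every gene with a hydrogenase-family
#' hit and \code{\link{resolve_groupA}} on the [FeFe] Group A calls. Calls
#' are returned sorted by gene id, so the result is independent of input
#' order.
#'
#' @param genes gene-call data.frame.
#' @param hits cutoff-filtered profile hits.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return data.frame with columns gene_id, scaffold_id, cofactor, group,
#'   subgroup, ambiguous, best_profile, best_score, and a list column
#'   evidence.
#' @export
call_hydrogenases <- function(genes, hits, thresholds = gp_thresholds()) {
  fam <- hydrogenase_profiles()
  cand <- intersect(unique(hits$gene_id[hits$profile %in% fam$profile]),
                    genes$gene_id)
  cand <- sort(cand)
  rows <- lapply(cand, function(g) {
    a <- assign_group(hits[hits$gene_id == g, , drop = FALSE])
    sub <- "n/a"
    ev <- data.frame(gene_id = character(0), role = character(0))
    if (a$cofactor == "FeFe" && a$group == "A") {
      r <- resolve_groupA(g, genes, hits, thresholds)
      sub <- r$subgroup
      ev <- r$evidence
    }
    data.frame(
      gene_id = g,
      scaffold_id = genes$scaffold_id[match(g, genes$gene_id)],
      cofactor = a$cofactor, group = a$group, subgroup = sub,
      ambiguous = a$ambiguous, best_profile = a$profile,
      best_score = a$bit_score,
      evidence = I(list(ev)), stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), scaffold_id = character(0),
                      cofactor = character(0), group = character(0),
                      subgroup = character(0), ambiguous = logical(0),
                      best_profile = character(0), best_score = numeric(0),
                      evidence = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarise hydrogenase content per bin
#'
#' Produces the per-bin count matrix keyed by cofactor-group-subgroup (for
#' example \code{FeFe-A-A3}, \code{NiFe-1}) plus per-bin booleans: has_A1,
#' has_A3, has_B, has_bifurcating (at least one A3 enzyme) and has_rnf (at
#' least one Rnf-complex marker hit, profiles named \code{rnf*}).
#'
#' @param calls output of \code{\link{call_hydrogenases}}.
#' @param gene_bins data.frame (gene_id, bin_id) mapping genes to bins.
#' @param hits cutoff-filtered profile hits (used for Rnf markers); may be
#'   \code{NULL}.
#' @param bin_ids bins to report even if empty.
#' @return list with \code{counts} (bin x type integer matrix) and
#'   \code{flags} (data.frame bin_id, n_hydrogenases, has_A1, has_A3, has_B,
#'   has_bifurcating, has_rnf).
#' @export
summarize_hydrogenases <- function(calls, gene_bins, hits = NULL,
                                   bin_ids = NULL) {
  map <- unique(gene_bins[, c("gene_id", "bin_id")])
  if (anyDuplicated(map$gene_id))
    stop("gene(s) assigned to more than one bin", call. = FALSE)
  calls$bin_id <- map$bin_id[match(calls$gene_id, map$gene_id)]
  calls <- calls[!is.na(calls$bin_id), , drop = FALSE]
  type <- ifelse(calls$subgroup == "n/a",
                 paste(calls$cofactor, calls$group, sep = "-"),
                 paste(calls$cofactor, calls$group, calls$subgroup,
                       sep = "-"))
  bins <- sort(unique(c(calls$bin_id, bin_ids)))
  types <- sort(unique(type))
  counts <- matrix(0L, nrow = length(bins), ncol = length(types),
                   dimnames = list(bins, types))
  if (nrow(calls) > 0) {
    tab <- table(factor(calls$bin_id, levels = bins),
                 factor(type, levels = types))
    counts[] <- as.integer(tab)
  }
  rnf_bins <- character(0)
  if (!is.null(hits)) {
    rnf_genes <- hits$gene_id[grepl("^rnf", hits$profile,
                                    ignore.case = TRUE)]
    rnf_bins <- unique(map$bin_id[map$gene_id %in% rnf_genes])
  }
  has <- function(sub) vapply(bins, function(b)
    any(calls$bin_id == b & calls$subgroup == sub), logical(1))
  has_grp <- function(grp) vapply(bins, function(b)
    any(calls$bin_id == b & calls$cofactor == "FeFe" & calls$group == grp),
    logical(1))
  flags <- data.frame(
    bin_id = bins,
    n_hydrogenases = as.integer(rowSums(counts)),
    has_A1 = has("A1"),
    has_A3 = has("A3"),
    has_B = has_grp("B"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  flags$has_bifurcating <- flags$has_A3
  flags$has_rnf <- flags$bin_id %in% rnf_bins
  structure(list(counts = counts, flags = flags),
            class = "gp_hyd_summary")
}

#' @export
print.gp_hyd_summary <- function(x, ...) {
  cat("Hydrogenase summary:", nrow(x$flags), "bins,",
      sum(x$counts), "hydrogenases\n")
  cat("  bifurcating (A3) in", sum(x$flags$has_bifurcating), "bins;",
      "Rnf in", sum(x$flags$has_rnf), "bins\n")
  invisible(x)
}

#' Co-occurrence statistics between hydrogenase classes and Rnf complexes
#'
#' Each fraction is |bins with both features| / |bins with the first|, and
#' is \code{NA} when no bin carries the first feature: the fraction of
#' H2-evolving Group A1 genomes that also carry a bifurcating A3 enzyme,
#' the fraction of bifurcating-hydrogenase genomes that carry an Rnf
#' complex, and the fraction of Group B genomes that also carry A3.
#'
#' @param summary output of \code{\link{summarize_hydrogenases}}.
#' @return list(frac_A1_with_A3, frac_bifurcating_with_rnf, frac_B_with_A3).
#' @export
cooccurrence_stats <- function(summary) {
  f <- summary$flags
  frac <- function(a, b) {
    if (sum(a) == 0) NA_real_ else sum(a & b) / sum(a)
  }
  list(
    frac_A1_with_A3 = frac(f$has_A1, f$has_A3),
    frac_bifurcating_with_rnf = frac(f$has_bifurcating, f$has_rnf),
    frac_B_with_A3 = frac(f$has_B, f$has_A3)
  )
}
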