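#' Construct a pathway rule
#'
#' A rule is a conjunction of clauses, each clause a disjunction of
#' alternative marker genes (for example, denitrification to N2 requires a
#' nitrate reductase (narG or napA) AND a nitrite reductase (nirK or nirS)
#' AND nitric oxide reductase AND nitrous oxide reductase). A clause may be
#' negated: it is then satisfied only when none of its alternatives is
#' present. Negated clauses encode calls defined by an absence, such as
#' partial nitrification (hydroxylamine dehydrogenase present, ammonia
#' monooxygenase absent).
#'
#' @param pathway pathway name.
#' @param category one of nitrogen, sulfur, carbon_fixation, methane,
#'   fermentation, complex_carbon, iron, energy.
#' @param clauses list of character vectors (gene alternatives per clause).
#' @param negated logical vector, one flag per clause (default all FALSE).
#' @return object of class \code{gp_pathway_rule}.
#' @export
pathway_rule <- function(pathway, category, clauses,
                         negated = rep(FALSE, length(clauses))) {
  if (length(clauses) < 1)
    stop("a pathway rule needs at least one clause", call. = FALSE)
  if (any(lengths(clauses) < 1))
    stop("each clause needs at least one gene alternative", call. = FALSE)
  stopifnot(length(negated) == length(clauses))
  structure(list(pathway = pathway, category = category,
                 clauses = lapply(clauses, as.character),
                 negated = as.logical(negated)),
            class = "gp_pathway_rule")
}

#' @export
print.gp_pathway_rule <- function(x, ...) {
  cl <- mapply(function(alt, neg)
    paste0(if (neg) "NOT " else "", "{", paste(alt, collapse = "|"), "}"),
    x$clauses, x$negated)
  cat(x$pathway, " [", x$category, "]: ", paste(cl, collapse = " AND "),
      "\n", sep = "")
  invisible(x)
}

#' Read a pathway rulebook from TSV
#'
#' Columns: pathway, category, clause_index, alternatives (\code{|}-separated
#' gene labels), negated (TRUE/FALSE). One row per clause.
#'
#' @param path path to the TSV.
#' @return named list of \code{\link{pathway_rule}} objects.
#' @export
read_pathway_rules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pathway", "category", "clause_index", "alternatives", "negated")
  if (!all(need %in% names(df)))
    stop("rulebook needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rules <- lapply(split(df, df$pathway), function(d) {
    d <- d[order(d$clause_index), , drop = FALSE]
    pathway_rule(d$pathway[1], d$category[1],
                 strsplit(d$alternatives, "\\|"),
                 as.logical(d$negated))
  })
  rules[unique(df$pathway)]
}

#' The shipped default rulebook
#'
#' Marker-gene rules for the biogeochemical capacities profiled across
#' subsurface genomes: nitrogen fixation, denitrification to N2, DNRA,
#' partial nitrification, anammox, sulfate reduction, sulfur oxidation,
#' Wood-Ljungdahl carbon fixation, the Calvin cycle (RuBisCO forms
#' including II/III and III-like), hydrogenotrophic methanogenesis, the Rnf
#' complex and formate dehydrogenase. The rulebook is data
#' (\code{inst/extdata/pathway_rules.tsv}), not code, so marker lists can be
#' extended without changing the package.
#'
#' @return named list of \code{\link{pathway_rule}} objects.
#' @export
default_pathway_rules <- function() {
  read_pathway_rules(system.file("extdata", "pathway_rules.tsv",
                                 package = "genopotential",
                                 mustWork = TRUE))
}

#' Gene sets scored as counts rather than complete/partial/absent
#'
#' Fermentation and complex-carbon degradation involve large, partially
#' redundant gene families; genomes are compared by the relative number of
#' such genes rather than by pathway completeness.
#'
#' @return named list of character vectors (category -> gene labels), read
#'   from \code{inst/extdata/count_gene_sets.tsv}.
#' @export
default_count_gene_sets <- function() {
  df <- utils::read.delim(system.file("extdata", "count_gene_sets.tsv",
                                      package = "genopotential",
                                      mustWork = TRUE),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(strsplit(df$genes, "\\|"), df$category)
}

#' Evaluate one pathway rule against a bin's gene complement
#'
#' Status is \code{complete} when every clause (including negated ones) is
#' satisfied, \code{absent} when no positive clause is satisfied, and
#' \code{partial} otherwise. Gene labels outside the rule's vocabulary are
#' simply not consulted.
#'
#' @param bin_genes character vector of gene/profile labels present in the
#'   bin.
#' @param rule a \code{\link{pathway_rule}}.
#' @return list(pathway, status, satisfied_clauses, genes_found).
#' @examples
#' denit <- pathway_rule("denitrification", "nitrogen",
#'   list(c("narG", "napA"), c("nirK", "nirS"), "norB", "nosZ"))
#' evaluate_pathway(c("narG", "nirS", "norB"), denit)$status  # partial
#' @export
evaluate_pathway <- function(bin_genes, rule) {
  found <- lapply(rule$clauses, function(alt) intersect(alt, bin_genes))
  sat <- mapply(function(hit, neg) if (neg) length(hit) == 0
                else length(hit) > 0,
                found, rule$negated)
  pos_sat <- sat & !rule$negated
  status <- if (all(sat)) "complete"
            else if (!any(pos_sat)) "absent"
            else "partial"
  list(pathway = rule$pathway, status = status,
       satisfied_clauses = sum(sat),
       genes_found = unlist(found[!rule$negated], use.names = FALSE))
}

#' Evaluate a rulebook across many bins
#'
#' @param bin_gene_sets named list: bin_id -> character vector of gene
#'   labels present.
#' @param rules named list of \code{\link{pathway_rule}} objects (default
#'   the shipped rulebook).
#' @return data.frame with columns bin_id, pathway, category, status,
#'   satisfied_clauses.
#' @export
evaluate_pathways <- function(bin_gene_sets,
                              rules = default_pathway_rules()) {
  rows <- lapply(names(bin_gene_sets), function(b) {
    calls <- lapply(rules, function(r)
      evaluate_pathway(bin_gene_sets[[b]], r))
    data.frame(
      bin_id = b,
      pathway = vapply(calls, `[[`, character(1), "pathway"),
      category = vapply(rules, `[[`, character(1), "category"),
      status = vapply(calls, `[[`, character(1), "status"),
      satisfied_clauses = vapply(calls, function(x)
        as.integer(x$satisfied_clauses), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

# Bucket gene counts into none/low/high tiers. Tercile breaks are computed
# over all bins' counts; zero counts are always "none" and nonzero counts
# never are.
tier_counts <- function(counts) {
  tier <- rep("none", length(counts))
  pos <- counts > 0
  if (any(pos)) {
    cut2 <- stats::quantile(counts, 2 / 3, names = FALSE, type = 1)
    tier[pos] <- ifelse(counts[pos] > cut2, "high", "low")
  }
  tier
}

#' Build the bin-by-feature metabolic potential matrix
#'
#' The community-level summary: one row per genome above the rarity cutoff
#' (mean relative abundance across samples > \code{rare_abundance_frac},
#' default 0.1%), ordered by descending mean abundance. Columns give the
#' mean abundance, each pathway's status, per-class hydrogenase counts, and
#' none/low/high tiers for the count-scored categories (fermentation,
#' complex carbon).
#'
#' @param pathway_calls output of \code{\link{evaluate_pathways}}.
#' @param abundance bin x sample relative-abundance matrix (see
#'   \code{\link{relative_abundance}}).
#' @param hyd_summary optional \code{\link{summarize_hydrogenases}} output.
#' @param bin_gene_sets optional named list (bin -> gene labels) used for
#'   the count-scored categories.
#' @param count_sets named list of gene sets scored as counts (default
#'   \code{\link{default_count_gene_sets}}).
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return data.frame, one row per retained bin.
#' @export
build_profile_matrix <- function(pathway_calls, abundance,
                                 hyd_summary = NULL, bin_gene_sets = NULL,
                                 count_sets = default_count_gene_sets(),
                                 thresholds = gp_thresholds()) {
  mean_ab <- rowMeans(abundance)
  if (all(mean_ab == 0)) {
    warning("all-zero abundance table; empty profile matrix", call. = FALSE)
    return(data.frame(bin_id = character(0), mean_abundance = numeric(0)))
  }
  keep <- names(mean_ab)[mean_ab > thresholds$rare_abundance_frac]
  keep <- keep[order(mean_ab[keep], decreasing = TRUE)]
  out <- data.frame(bin_id = keep, mean_abundance = unname(mean_ab[keep]),
                    stringsAsFactors = FALSE)
  for (pw in unique(pathway_calls$pathway)) {
    sub <- pathway_calls[pathway_calls$pathway == pw, ]
    out[[pw]] <- sub$status[match(keep, sub$bin_id)]
    out[[pw]][is.na(out[[pw]])] <- "absent"
  }
  if (!is.null(hyd_summary)) {
    cm <- hyd_summary$counts
    idx <- match(keep, rownames(cm))
    for (ty in colnames(cm)) {
      v <- ifelse(is.na(idx), 0L, cm[idx, ty])
      out[[paste0("hyd_", ty)]] <- as.integer(v)
    }
  }
  if (!is.null(bin_gene_sets)) {
    for (cat in names(count_sets)) {
      n <- vapply(keep, function(b)
        length(intersect(count_sets[[cat]],
                         bin_gene_sets[[b]])), integer(1))
      out[[paste0(cat, "_genes")]] <- n
      out[[paste0(cat, "_tier")]] <- tier_counts(n)
    }
  }
  rownames(out) <- NULL
  out
}
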