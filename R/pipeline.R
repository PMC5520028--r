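#' The profile vocabulary the pipeline filters against
#'
#' Union of the hydrogenase family profiles, the hydB/hydC accessory
#' labels, the single-copy marker set, rpS3, and every gene label used by
#' the pathway rulebook and the count-scored gene sets.
#'
#' @param mset marker set (default \code{\link{default_marker_set}}).
#' @param rules rulebook (default \code{\link{default_pathway_rules}}).
#' @return character vector of profile names.
#' @export
profile_vocabulary <- function(mset = default_marker_set(),
                               rules = default_pathway_rules()) {
  rule_genes <- unlist(lapply(rules, function(r) unlist(r$clauses)))
  sort(unique(c(hydrogenase_profiles()$profile, "hydB", "hydC",
                mset$markers, "rpS3", rule_genes,
                unlist(default_count_gene_sets()))))
}

#' Write a synthetic community bundle to disk
#'
#' Emits the exact formats the pipeline reads: \code{proteins.faa},
#' \code{genes.gff3}, \code{hits.tsv}, \code{coverage.tsv},
#' \code{bins.tsv}, \code{scaffolds.fna}.
#'
#' @param bundle the \code{bundle} element of
#'   \code{\link{generate_community}} output.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteins = file.path(dir, "proteins.faa"),
    genes = file.path(dir, "genes.gff3"),
    hits = file.path(dir, "hits.tsv"),
    coverage = file.path(dir, "coverage.tsv"),
    bins = file.path(dir, "bins.tsv"),
    scaffolds = file.path(dir, "scaffolds.fna")
  )
  write_protein_fasta(bundle$proteome, paths["proteins"])
  write_gene_calls_gff3(bundle$genes, paths["genes"])
  write_profile_hits(bundle$hits, paths["hits"])
  write_coverage_table(bundle$coverage, paths["coverage"])
  write_bin_membership(bundle$membership, paths["bins"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$scaffold_seqs), paths["scaffolds"])
  invisible(paths)
}

# hydrogenase class label shared by the measured and planted summaries
hyd_truth_type <- function(label) {
  switch(label,
         A1 = "FeFe-A-A1", A3 = "FeFe-A-A3",
         A_unresolved = "FeFe-A-A_unresolved",
         B = "FeFe-B", C = "FeFe-C", Fe = "Fe-Fe",
         sub("^NiFe_", "NiFe-", label))
}

summary_field_order <- c(
  "schema_version", "seed", "n_samples", "thresholds", "n_bins",
  "n_high_quality", "n_derep_clusters", "n_mhc_proteins",
  "n_iron_reducer_bins", "n_hydrogenases", "n_bins_with_hydrogenases",
  "hyd_class_counts", "frac_groupA_A3", "cooccurrence",
  "pathway_status_counts", "n_rps3_organisms", "top_k", "top_k_binned",
  "frac_unbinned_below_rare", "n_bins_above_rare")

write_summary_json <- function(summary, path) {
  summary <- summary[intersect(summary_field_order, names(summary))]
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

pathway_count_block <- function(status_df, rules) {
  out <- list()
  for (pw in names(rules)) {
    st <- status_df$status[status_df$pathway == pw]
    out[[pw]] <- list(complete = sum(st == "complete"),
                      partial = sum(st == "partial"),
                      absent = sum(st == "absent"))
  }
  out
}

#' Planted-truth summary for a generated community
#'
#' Builds, from the generator's truth record alone (planted marker
#' complements, motif counts, hydrogenase labels, abundances, mutation
#' rates), the same summary the pipeline computes by measurement. Used to
#' verify end-to-end runs byte-for-byte.
#'
#' @param truth,bundle output of \code{\link{generate_community}}.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @param seed seed recorded in the header.
#' @param top_k ranking head size (default 10).
#' @param rules rulebook (for pathway ordering).
#' @return named list in summary schema order.
#' @export
truth_summary <- function(truth, bundle, thresholds = gp_thresholds(),
                          seed = 1L, top_k = 10L,
                          rules = default_pathway_rules()) {
  th <- thresholds
  n_markers <- truth$n_markers
  # QC from planted marker complements
  hq <- vapply(truth$bins, function(b) {
    mk <- truth$markers[[b]]
    comp <- 100 * length(mk$present) / n_markers
    cont <- 100 * length(mk$duplicated) / n_markers
    comp > th$hq_min_completeness && cont < th$hq_max_contamination
  }, logical(1))
  # dereplication from exactly realised mutation counts
  merged <- logical(nrow(truth$replicate_map))
  if (nrow(truth$replicate_map) > 0) {
    for (i in seq_len(nrow(truth$replicate_map))) {
      src <- truth$replicate_map$source[i]
      rate <- truth$replicate_map$rate[i]
      lens <- nchar(bundle$bin_scaffolds[[src]])
      ident <- 1 - sum(round(rate * lens)) / sum(lens)
      merged[i] <- ident >= th$derep_identity
    }
  }
  n_src <- sum(!truth$bins %in% truth$replicate_map$bin_id)
  n_derep <- n_src + sum(!merged)
  # MHC / iron from planted motif counts
  gene_bin <- stats::setNames(
    bundle$membership$bin_id[match(bundle$genes$scaffold_id,
                                   bundle$membership$scaffold_id)],
    bundle$genes$gene_id)
  is_mhc <- truth$motifs >= th$mhc_min_motifs
  mhc_bins <- gene_bin[names(truth$motifs)[is_mhc]]
  n_iron <- sum(table(factor(mhc_bins[!is.na(mhc_bins)],
                             levels = truth$bins)) >= th$iron_min_mhcs)
  # hydrogenases from planted labels
  types <- vapply(truth$hyd$label, hyd_truth_type, character(1))
  type_counts <- table(types)
  class_counts <- as.list(stats::setNames(as.integer(type_counts),
                                          names(type_counts)))
  class_counts <- class_counts[sort(names(class_counts))]
  a_labels <- truth$hyd$label[truth$hyd$label %in%
                                c("A1", "A3", "A_unresolved")]
  frac_a3 <- if (length(a_labels) == 0) NA_real_ else
    sum(a_labels == "A3") / length(a_labels)
  has <- function(b, lab) any(truth$hyd$bin_id == b & truth$hyd$label == lab)
  hA1 <- vapply(truth$bins, has, logical(1), lab = "A1")
  hA3 <- vapply(truth$bins, has, logical(1), lab = "A3")
  hB <- vapply(truth$bins, has, logical(1), lab = "B")
  hrnf <- vapply(truth$bins, function(b)
    any(grepl("^rnf", truth$label_sets[[b]])), logical(1))
  frac <- function(a, b) if (sum(a) == 0) NA_real_ else sum(a & b) / sum(a)
  # rpS3 organisms from exactly realised protein mutation counts
  rps_len <- 200L
  rmerged <- logical(nrow(truth$replicate_map))
  if (nrow(truth$replicate_map) > 0)
    for (i in seq_len(nrow(truth$replicate_map)))
      rmerged[i] <- (1 - round(truth$replicate_map$rate[i] * rps_len) /
                       rps_len) >= th$rps3_cluster_identity
  cluster_of <- stats::setNames(c(truth$bins, truth$unbinned),
                                c(truth$bins, truth$unbinned))
  if (nrow(truth$replicate_map) > 0)
    cluster_of[truth$replicate_map$bin_id[rmerged]] <-
      truth$replicate_map$source[rmerged]
  ab <- truth$abundance
  cl_ab <- tapply(rowSums(ab[names(cluster_of), , drop = FALSE]),
                  cluster_of[names(cluster_of)], sum) / sum(ab)
  cl_binned <- tapply(names(cluster_of) %in% truth$bins,
                      cluster_of[names(cluster_of)], any)
  ord <- order(-cl_ab, names(cl_ab))
  k <- min(top_k, length(cl_ab))
  unb <- !cl_binned
  # bins above the rarity cutoff (bin-normalised abundances)
  bab <- ab[truth$bins, , drop = FALSE]
  bab <- sweep(bab, 2, colSums(bab), "/")
  n_above <- sum(rowMeans(bab) > th$rare_abundance_frac)
  list(
    schema_version = "1.0",
    seed = as.integer(seed),
    n_samples = ncol(ab),
    thresholds = unclass(th),
    n_bins = length(truth$bins),
    n_high_quality = sum(hq),
    n_derep_clusters = as.integer(n_derep),
    n_mhc_proteins = sum(is_mhc),
    n_iron_reducer_bins = as.integer(n_iron),
    n_hydrogenases = nrow(truth$hyd),
    n_bins_with_hydrogenases = length(unique(truth$hyd$bin_id)),
    hyd_class_counts = class_counts,
    frac_groupA_A3 = frac_a3,
    cooccurrence = list(
      frac_A1_with_A3 = frac(hA1, hA3),
      frac_bifurcating_with_rnf = frac(hA3, hrnf),
      frac_B_with_A3 = frac(hB, hA3)),
    pathway_status_counts = pathway_count_block(truth$pathway_status,
                                                rules),
    n_rps3_organisms = length(unique(cluster_of)),
    top_k = as.integer(k),
    top_k_binned = sum(cl_binned[ord][seq_len(k)]),
    frac_unbinned_below_rare = if (sum(unb) == 0) NA_real_ else
      sum(unb & cl_ab < th$rare_abundance_frac) / sum(unb),
    n_bins_above_rare = as.integer(n_above)
  )
}

#' Write a demonstration community and its expected results
#'
#' Generates a seeded ~24-bin synthetic community (12 sources, 8 close
#' replicates, 4 divergent decoys, 6 unbinned organisms), writes the input
#' bundle, the planted truth, and the expected end-to-end summary computed
#' from the truth alone. Running \code{\link{run_pipeline}} on the bundle
#' with the same seed must reproduce \code{expected_summary.json}
#' byte-for-byte.
#'
#' @param seed RNG seed.
#' @param outdir output directory.
#' @param top_k ranking head size recorded in the summary (default 10).
#' @return invisible list with \code{dir}, \code{paths} and the generated
#'   \code{truth}.
#' @export
make_demo <- function(seed = 1L, outdir = "demo", top_k = 10L) {
  gen <- generate_community(seed = seed)
  paths <- write_bundle(gen$bundle, outdir)
  th <- gp_thresholds()
  truth_json <- list(
    markers = gen$truth$markers,
    motifs = as.list(gen$truth$motifs[gen$truth$motifs > 0]),
    hydrogenases = gen$truth$hyd,
    pathway_status = gen$truth$pathway_status,
    replicate_map = gen$truth$replicate_map,
    abundance = as.data.frame(gen$truth$abundance),
    bins = gen$truth$bins,
    unbinned = gen$truth$unbinned
  )
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  expected <- truth_summary(gen$truth, gen$bundle, th, seed = seed,
                            top_k = top_k)
  write_summary_json(expected, file.path(outdir, "expected_summary.json"))
  invisible(list(dir = outdir, paths = paths, truth = gen$truth))
}

#' Run the full genome-interpretation pipeline on an input directory
#'
#' Stages execute in dependency order: parse, bin QC, dereplication, MHC
#' scan and iron-reduction prediction, hydrogenase typing, pathway
#' profiling, abundance and rpS3 accounting, and the bin-by-feature matrix.
#' Per-stage tables are written as TSV, the combined accounting as
#' \code{summary.json}, and a log (with every threshold actually used) as
#' \code{run.log}. Any stage failure aborts with the stage named.
#'
#' @param config list with elements \code{input_dir}, \code{out_dir},
#'   optional \code{thresholds} (a \code{\link{gp_thresholds}} or a JSON
#'   path), \code{seed} (recorded in outputs), \code{top_k} (default 10),
#'   and \code{stages} - a named logical list to toggle \code{derep},
#'   \code{heme}, \code{hyd}, \code{pathway}, \code{abundance}.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$input_dir),
            !is.null(config$out_dir))
  th <- config$thresholds
  if (is.null(th)) th <- gp_thresholds()
  if (is.character(th)) th <- read_thresholds_json(th)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  top_k <- if (is.null(config$top_k)) 10L else as.integer(config$top_k)
  stages <- utils::modifyList(
    list(derep = TRUE, heme = TRUE, hyd = TRUE, pathway = TRUE,
         abundance = TRUE), as.list(config$stages))
  ind <- file.path(config$input_dir,
                   c("proteins.faa", "genes.gff3", "hits.tsv",
                     "coverage.tsv", "bins.tsv", "scaffolds.fna"))
  names(ind) <- c("proteins", "genes", "hits", "coverage", "bins",
                  "scaffolds")
  missing <- ind[!file.exists(ind)]
  if (length(missing) > 0)
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("genopotential run (seed %d)", seed),
                 sprintf("threshold %s = %s", names(th),
                         vapply(th, format, character(1))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$parse <- stage("parse", {
    proteome <- parse_protein_fasta(ind["proteins"])
    genes <- read_gene_calls(ind["genes"])
    hits <- parse_profile_hits(ind["hits"],
                               uniform_cutoffs(profile_vocabulary()))
    coverage <- parse_coverage_table(ind["coverage"])
    membership <- read_bin_membership(ind["bins"])
    scafs <- Biostrings::readDNAStringSet(ind["scaffolds"])
    scaffold_seqs <- stats::setNames(as.character(scafs),
                                     sub("\\s.*$", "", names(scafs)))
    list(proteome = proteome, genes = genes, hits = hits,
         coverage = coverage, membership = membership,
         scaffold_seqs = scaffold_seqs)
  })
  p <- res$parse
  gene_bins <- data.frame(
    gene_id = p$genes$gene_id,
    bin_id = p$membership$bin_id[match(p$genes$scaffold_id,
                                       p$membership$scaffold_id)],
    stringsAsFactors = FALSE)
  gene_bins <- gene_bins[!is.na(gene_bins$bin_id), ]
  bins <- sort(unique(p$membership$bin_id))

  res$qc <- stage("binqc", {
    qc <- bin_quality_table(p$hits, gene_bins, default_marker_set(), th)
    utils::write.table(qc, file.path(config$out_dir, "bin_quality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    qc
  })

  if (isTRUE(stages$derep)) {
    res$derep <- stage("derep", {
      bin_scafs <- lapply(stats::setNames(bins, bins), function(b)
        p$scaffold_seqs[p$membership$scaffold_id[
          p$membership$bin_id == b]])
      ids <- pairwise_identity_table(bin_scafs)
      dr <- dereplicate(bins, ids, res$qc, th)
      dd <- data.frame(
        representative = rep(dr$representatives,
                             lengths(dr$clusters)),
        bin_id = unlist(dr$clusters), stringsAsFactors = FALSE)
      utils::write.table(dd, file.path(config$out_dir,
                                       "derep_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dr
    })
  }

  if (isTRUE(stages$heme)) {
    res$heme <- stage("heme", {
      mhc <- call_mhcs(p$proteome, th)
      pred <- predict_iron_reducers(mhc, gene_bins, th, bin_ids = bins)
      utils::write.table(mhc[, c("gene_id", "motif_count", "is_mhc")],
                         file.path(config$out_dir, "mhc_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pred,
                         file.path(config$out_dir, "iron_predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(mhc = mhc, predictions = pred)
    })
  }

  if (isTRUE(stages$hyd)) {
    res$hyd <- stage("hyd", {
      calls <- call_hydrogenases(p$genes, p$hits, th)
      summ <- summarize_hydrogenases(calls, gene_bins, p$hits,
                                     bin_ids = bins)
      cooc <- cooccurrence_stats(summ)
      out <- calls[, c("gene_id", "scaffold_id", "cofactor", "group",
                       "subgroup", "ambiguous")]
      out$bin_id <- gene_bins$bin_id[match(out$gene_id,
                                           gene_bins$gene_id)]
      utils::write.table(out,
                         file.path(config$out_dir,
                                   "hydrogenase_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(calls = calls, summary = summ, cooccurrence = cooc)
    })
  }

  bin_gene_sets <- lapply(stats::setNames(bins, bins), function(b)
    sort(unique(p$hits$profile[p$hits$gene_id %in%
                                 gene_bins$gene_id[gene_bins$bin_id == b]])))
  rules <- default_pathway_rules()
  if (isTRUE(stages$pathway)) {
    res$pathway <- stage("pathway", {
      pc <- evaluate_pathways(bin_gene_sets, rules)
      utils::write.table(pc, file.path(config$out_dir, "pathway_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pc
    })
  }

  if (isTRUE(stages$abundance)) {
    res$abundance <- stage("abundance", {
      lens <- stats::setNames(nchar(p$scaffold_seqs),
                              names(p$scaffold_seqs))
      ab <- relative_abundance(p$membership, lens, p$coverage)
      utils::write.table(
        data.frame(bin_id = rownames(ab), ab, check.names = FALSE),
        file.path(config$out_dir, "abundance.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      # rpS3 accounting
      rps_genes <- p$hits$gene_id[p$hits$profile == "rpS3"]
      rps_genes <- intersect(rps_genes, p$genes$gene_id)
      rps_seqs <- p$proteome[rps_genes]
      rps_scaf <- stats::setNames(
        p$genes$scaffold_id[match(rps_genes, p$genes$gene_id)], rps_genes)
      cl <- cluster_rps3(rps_seqs, th)
      rk <- rank_abundance(cl, rps_scaf, p$coverage, p$membership, th,
                           top_k = top_k)
      utils::write.table(rk$ranking,
                         file.path(config$out_dir, "rps3_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(table = ab, rps3_clusters = cl, rank = rk)
    })
    res$matrix <- stage("matrix", {
      m <- build_profile_matrix(res$pathway, res$abundance$table,
                                if (!is.null(res$hyd)) res$hyd$summary,
                                bin_gene_sets, thresholds = th)
      utils::write.table(m, file.path(config$out_dir, "profile_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      m
    })
  }

  # --- combined summary ---
  summ <- list(schema_version = "1.0", seed = seed,
               n_samples = ncol(p$coverage), thresholds = unclass(th),
               n_bins = length(bins),
               n_high_quality = sum(res$qc$is_high_quality))
  if (!is.null(res$derep))
    summ$n_derep_clusters <- length(res$derep$clusters)
  if (!is.null(res$heme)) {
    summ$n_mhc_proteins <- sum(res$heme$mhc$is_mhc)
    summ$n_iron_reducer_bins <-
      sum(res$heme$predictions$predicted_iron_reducer)
  }
  if (!is.null(res$hyd)) {
    cm <- res$hyd$summary$counts
    cc <- as.list(stats::setNames(as.integer(colSums(cm)), colnames(cm)))
    cc <- cc[sort(names(cc))]
    acols <- grep("^FeFe-A-", colnames(cm), value = TRUE)
    n_a <- sum(cm[, acols, drop = FALSE])
    summ$n_hydrogenases <- sum(cm)
    summ$n_bins_with_hydrogenases <-
      sum(res$hyd$summary$flags$n_hydrogenases > 0)
    summ$hyd_class_counts <- cc
    summ$frac_groupA_A3 <- if (n_a == 0) NA_real_ else
      sum(cm[, intersect("FeFe-A-A3", colnames(cm)), drop = FALSE]) / n_a
    summ$cooccurrence <- res$hyd$cooccurrence
  }
  if (!is.null(res$pathway))
    summ$pathway_status_counts <- pathway_count_block(res$pathway, rules)
  if (!is.null(res$abundance)) {
    rk <- res$abundance$rank
    summ$n_rps3_organisms <- length(res$abundance$rps3_clusters$clusters)
    summ$top_k <- as.integer(rk$summary$top_k)
    summ$top_k_binned <- rk$summary$top_k_binned
    summ$frac_unbinned_below_rare <- rk$summary$frac_unbinned_below_rare
    summ$n_bins_above_rare <- nrow(res$matrix)
  }
  write_summary_json(summ, file.path(config$out_dir, "summary.json"))
  writeLines(c(log_lines, sprintf("completed %d stages",
                                  sum(unlist(stages)))), logf)
  res$summary <- summ
  invisible(res)
}
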