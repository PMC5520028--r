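#' Construct a single-copy marker set
#'
#' @param markers character vector of marker profile labels (unique).
#' @param domain "bacteria" or "archaea".
#' @return object of class \code{gp_marker_set}.
#' @export
marker_set <- function(markers, domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  markers <- as.character(markers)
  if (length(markers) == 0)
    stop("marker set is empty", call. = FALSE)
  if (anyDuplicated(markers))
    stop("marker set contains duplicates", call. = FALSE)
  structure(list(domain = domain, markers = markers),
            class = "gp_marker_set")
}

#' The default bacterial single-copy marker set
#'
#' Fifty-one conserved single-copy phylogenetic markers (ribosomal-protein
#' style labels \code{rp_01}..\code{rp_51}), the vocabulary the synthetic
#' community generator plants.
#'
#' @return a \code{\link{marker_set}}.
#' @export
default_marker_set <- function() {
  marker_set(sprintf("rp_%02d", 1:51), "bacteria")
}

#' Completeness, contamination and the high-quality call for one bin
#'
#' Completeness is the percentage of expected single-copy markers found at
#' least once among the bin's genes; contamination the percentage found in
#' two or more copies (distinct genes). A bin is a high-quality draft when
#' completeness exceeds \code{hq_min_completeness} (70) and contamination is
#' below \code{hq_max_contamination} (10) - both strict inequalities.
#'
#' @param bin_hits profile hits restricted to the bin's genes (columns
#'   gene_id, profile).
#' @param mset a \code{\link{marker_set}}.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return list(completeness, contamination, is_high_quality).
#' @export
bin_quality <- function(bin_hits, mset, thresholds = gp_thresholds()) {
  if (!inherits(mset, "gp_marker_set"))
    mset <- marker_set(mset)
  mh <- bin_hits[bin_hits$profile %in% mset$markers, , drop = FALSE]
  copies <- vapply(mset$markers, function(m)
    length(unique(mh$gene_id[mh$profile == m])), integer(1))
  completeness <- 100 * sum(copies >= 1) / length(mset$markers)
  contamination <- 100 * sum(copies >= 2) / length(mset$markers)
  list(completeness = completeness,
       contamination = contamination,
       is_high_quality = completeness > thresholds$hq_min_completeness &&
         contamination < thresholds$hq_max_contamination)
}

#' QC a whole set of bins
#'
#' @param hits profile hits for all genes.
#' @param gene_bins data.frame (gene_id, bin_id).
#' @param mset a \code{\link{marker_set}}.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return data.frame with columns bin_id, completeness, contamination,
#'   is_high_quality.
#' @export
bin_quality_table <- function(hits, gene_bins, mset = default_marker_set(),
                              thresholds = gp_thresholds()) {
  hits$bin_id <- gene_bins$bin_id[match(hits$gene_id, gene_bins$gene_id)]
  bins <- sort(unique(gene_bins$bin_id))
  rows <- lapply(bins, function(b) {
    q <- bin_quality(hits[!is.na(hits$bin_id) & hits$bin_id == b, ,
                          drop = FALSE], mset, thresholds)
    data.frame(bin_id = b, completeness = q$completeness,
               contamination = q$contamination,
               is_high_quality = q$is_high_quality,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

kmer_set <- function(seq, k = 16L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

align_identity <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 5, gapExtension = 2)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  }
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  list(matches = nm, aligned = nm + nmm)
}

#' Pairwise nucleotide identity between two bins
#'
#' A self-contained identity estimator for fixture-scale genomes: scaffolds
#' of the two bins are matched by shared 16-mers, matched pairs are globally
#' aligned, and identity is pooled over all aligned positions. The aligned
#' fraction is the pooled aligned length over the shorter genome's total
#' length, so unrelated bins (no shared 16-mers) score 0.
#'
#' @param scafs_a,scafs_b named character vectors of nucleotide scaffolds.
#' @param min_shared_kmers scaffold pairs sharing fewer 16-mers than this
#'   are not aligned (default 5).
#' @return list(identity, aligned_frac); identity is \code{NA} when nothing
#'   aligns.
#' @export
pairwise_identity <- function(scafs_a, scafs_b, min_shared_kmers = 5L) {
  if (length(scafs_a) == 0 || length(scafs_b) == 0)
    stop("both bins need nucleotide scaffolds", call. = FALSE)
  kb <- lapply(scafs_b, kmer_set)
  tot_match <- 0
  tot_aligned <- 0
  for (sa in scafs_a) {
    ka <- kmer_set(sa)
    shared <- vapply(kb, function(s) sum(ka %in% s), integer(1))
    if (max(shared) < min_shared_kmers) next
    sb <- scafs_b[[which.max(shared)]]
    al <- align_identity(sa, sb, "dna")
    tot_match <- tot_match + al$matches
    tot_aligned <- tot_aligned + al$aligned
  }
  shorter <- min(sum(nchar(scafs_a)), sum(nchar(scafs_b)))
  list(
    identity = if (tot_aligned == 0) NA_real_ else tot_match / tot_aligned,
    aligned_frac = tot_aligned / shorter
  )
}

#' All-pairs bin identities
#'
#' @param bin_scaffolds named list: bin_id -> named character vector of
#'   nucleotide scaffolds.
#' @return data.frame (bin_a, bin_b, identity, aligned_frac), one row per
#'   unordered pair.
#' @export
pairwise_identity_table <- function(bin_scaffolds) {
  bins <- sort(names(bin_scaffolds))
  rows <- list()
  for (i in seq_along(bins)) {
    for (j in seq_len(i - 1L)) {
      pid <- pairwise_identity(bin_scaffolds[[bins[j]]],
                               bin_scaffolds[[bins[i]]])
      rows[[length(rows) + 1L]] <- data.frame(
        bin_a = bins[j], bin_b = bins[i],
        identity = pid$identity, aligned_frac = pid$aligned_frac,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Dereplicate bins by pairwise identity
#'
#' Single-linkage clustering over edges with identity at or above
#' \code{derep_identity} (98%) and aligned fraction at or above
#' \code{derep_aligned_frac} (50%). Each cluster's representative is its
#' most complete bin; ties go to the lower contamination, then the
#' lexicographically first id.
#'
#' @param bin_ids character vector of all bins.
#' @param identities output of \code{\link{pairwise_identity_table}}.
#' @param qc optional data.frame (bin_id, completeness, contamination) used
#'   to pick representatives.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return list with \code{clusters} (list of bin-id character vectors) and
#'   \code{representatives} (character vector, one per cluster).
#' @export
dereplicate <- function(bin_ids, identities, qc = NULL,
                        thresholds = gp_thresholds()) {
  bin_ids <- sort(unique(bin_ids))
  parent <- stats::setNames(seq_along(bin_ids), bin_ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  good <- !is.na(identities$identity) &
    identities$identity >= thresholds$derep_identity &
    identities$aligned_frac >= thresholds$derep_aligned_frac
  for (r in which(good)) {
    a <- find(match(identities$bin_a[r], bin_ids))
    b <- find(match(identities$bin_b[r], bin_ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(bin_ids), find, numeric(1))
  clusters <- unname(split(bin_ids, roots))
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  pick_rep <- function(members) {
    if (is.null(qc)) return(sort(members)[1])
    q <- qc[match(members, qc$bin_id), ]
    ord <- order(-q$completeness, q$contamination, members)
    members[ord[1]]
  }
  list(clusters = clusters,
       representatives = vapply(clusters, pick_rep, character(1)))
}

#' Cluster rpS3 marker sequences into unique organisms
#'
#' Greedy centroid clustering: sequences are visited longest first (ties
#' broken by name), each either joining the first centroid it matches at or
#' above \code{rps3_cluster_identity} global amino-acid identity (99%), or
#' seeding a new cluster.
#'
#' @param seqs named character vector of rpS3 protein sequences.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return list with \code{clusters} (named list centroid -> member ids)
#'   and \code{membership} (named character vector id -> centroid).
#' @export
cluster_rps3 <- function(seqs, thresholds = gp_thresholds()) {
  if (length(seqs) == 0)
    return(list(clusters = list(),
                membership = stats::setNames(character(0), character(0))))
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  centroids <- character(0)
  membership <- stats::setNames(character(length(seqs)), names(seqs))
  for (id in ord) {
    assigned <- NA_character_
    for (ct in centroids) {
      al <- align_identity(seqs[[id]], seqs[[ct]], "protein")
      ident <- if (al$aligned == 0) 0 else al$matches / al$aligned
      if (ident >= thresholds$rps3_cluster_identity) {
        assigned <- ct
        break
      }
    }
    if (is.na(assigned)) {
      centroids <- c(centroids, id)
      assigned <- id
    }
    membership[id] <- assigned
  }
  clusters <- split(names(membership), membership)[centroids]
  list(clusters = clusters, membership = membership)
}

#' Rank organisms by rpS3 marker abundance
#'
#' Each rpS3 cluster is one organism; its abundance is the summed depth of
#' its members' scaffolds (over the chosen samples) as a fraction of all
#' rpS3-scaffold depth. Organisms are ranked by descending abundance. The
#' summary reports how many of the top \code{top_k} organisms fall inside a
#' bin, and - among organisms outside any bin - the fraction below the
#' rarity cutoff (0.1% by default), the accounting used to argue that a
#' genome catalogue captures the abundant community.
#'
#' @param rps3_clusters output of \code{\link{cluster_rps3}}.
#' @param rps3_scaffolds named character vector: rpS3 sequence id ->
#'   scaffold id.
#' @param coverage scaffold x sample depth matrix.
#' @param membership bin membership data.frame (bin_id, scaffold_id).
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @param top_k size of the head of the ranking summarised (default 50).
#' @param samples sample ids to pool (default all columns).
#' @return list with \code{ranking} (data.frame organism, abundance,
#'   binned, rank) and \code{summary} (list top_k, top_k_binned,
#'   frac_unbinned_below_rare).
#' @export
rank_abundance <- function(rps3_clusters, rps3_scaffolds, coverage,
                           membership, thresholds = gp_thresholds(),
                           top_k = 50L, samples = colnames(coverage)) {
  cl <- rps3_clusters$clusters
  if (length(cl) == 0) stop("no rpS3 clusters", call. = FALSE)
  depth_of <- function(members) {
    scafs <- rps3_scaffolds[members]
    if (anyNA(scafs) || !all(scafs %in% rownames(coverage)))
      stop("rpS3 scaffold without coverage entry", call. = FALSE)
    sum(coverage[scafs, samples, drop = FALSE])
  }
  depths <- vapply(cl, depth_of, numeric(1))
  if (sum(depths) == 0)
    stop("all rpS3 scaffold depths are zero", call. = FALSE)
  binned_scafs <- membership$scaffold_id
  binned <- vapply(cl, function(members)
    any(rps3_scaffolds[members] %in% binned_scafs), logical(1))
  ab <- depths / sum(depths)
  ord <- order(-ab, names(cl))
  ranking <- data.frame(
    organism = names(cl)[ord], abundance = unname(ab[ord]),
    binned = unname(binned[ord]), rank = seq_along(ord),
    stringsAsFactors = FALSE)
  k <- min(top_k, nrow(ranking))
  unb <- ranking[!ranking$binned, , drop = FALSE]
  frac_rare <- if (nrow(unb) == 0) NA_real_ else
    mean(unb$abundance < thresholds$rare_abundance_frac)
  list(ranking = ranking,
       summary = list(top_k = k,
                      top_k_binned = sum(ranking$binned[seq_len(k)]),
                      frac_unbinned_below_rare = frac_rare))
}

#' Per-sample relative abundance of genome bins
#'
#' A bin's coverage in a sample is the length-weighted mean depth of its
#' scaffolds (equivalently, mapped bases per genome base); abundances are
#' these coverages normalised to sum to one per sample across bins.
#'
#' @param membership bin membership data.frame (bin_id, scaffold_id).
#' @param scaffold_lengths named integer vector: scaffold -> length (bp).
#' @param coverage scaffold x sample depth matrix.
#' @return bin x sample matrix of relative abundances (columns sum to 1).
#' @export
relative_abundance <- function(membership, scaffold_lengths, coverage) {
  bins <- sort(unique(membership$bin_id))
  samples <- colnames(coverage)
  cov <- matrix(0, length(bins), length(samples),
                dimnames = list(bins, samples))
  for (b in bins) {
    scafs <- membership$scaffold_id[membership$bin_id == b]
    miss <- setdiff(scafs, rownames(coverage))
    if (length(miss) > 0)
      stop("scaffold(s) of bin ", b, " missing from coverage: ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    len <- scaffold_lengths[scafs]
    if (anyNA(len) || sum(len) == 0)
      stop("bin ", b, " has zero total scaffold length", call. = FALSE)
    cov[b, ] <- colSums(coverage[scafs, , drop = FALSE] * len) / sum(len)
  }
  tot <- colSums(cov)
  if (any(tot == 0))
    stop("sample(s) with zero total bin coverage: ",
         paste(samples[tot == 0], collapse = ", "), call. = FALSE)
  sweep(cov, 2, tot, "/")
}

#' Trim and concatenate per-gene alignment blocks
#'
#' The standard preparation of a concatenated ribosomal-protein alignment
#' for phylogenetics, as a single non-iterated pass: (1) within each gene
#' block, delete columns whose gap fraction exceeds \code{gap_col_max_frac}
#' (90%); (2) concatenate blocks over the union of taxa, filling taxa
#' absent from a block with gaps; (3) drop taxa whose non-gap fraction of
#' the concatenated alignment is below \code{seq_min_aligned_frac} (50%).
#' Taxa with at least \code{tree_min_positions} (450) non-gap columns are
#' flagged tree-eligible; those below remain in the alignment but should be
#' excluded from tree building.
#'
#' @param blocks list of named character vectors; each block holds aligned,
#'   equal-length sequences (gap character \code{-}) for one gene.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return list(alignment = named character vector, dropped_taxa,
#'   tree_eligible, n_columns).
#' @export
trim_concatenated_alignment <- function(blocks,
                                        thresholds = gp_thresholds()) {
  if (length(blocks) == 0) stop("no alignment blocks", call. = FALSE)
  taxa <- sort(unique(unlist(lapply(blocks, names))))
  if (is.null(taxa) || any(taxa == ""))
    stop("alignment blocks must carry taxon names", call. = FALSE)
  trimmed <- lapply(blocks, function(bl) {
    w <- unique(nchar(bl))
    if (length(w) != 1)
      stop("sequences within a block must have equal length", call. = FALSE)
    m <- matrix("-", length(taxa), w, dimnames = list(taxa, NULL))
    chars <- strsplit(bl, "")
    for (tx in names(bl)) m[tx, ] <- chars[[tx]]
    gapfrac <- colMeans(m == "-" | m == ".")
    m[, gapfrac <= thresholds$gap_col_max_frac, drop = FALSE]
  })
  cat_m <- do.call(cbind, trimmed)
  nongap <- rowSums(cat_m != "-" & cat_m != ".")
  frac <- nongap / ncol(cat_m)
  dropped <- taxa[frac < thresholds$seq_min_aligned_frac]
  kept <- setdiff(taxa, dropped)
  eligible <- kept[nongap[kept] >= thresholds$tree_min_positions]
  aln <- apply(cat_m[kept, , drop = FALSE], 1, paste, collapse = "")
  list(alignment = aln, dropped_taxa = dropped, tree_eligible = eligible,
       n_columns = ncol(cat_m))
}

#' Abundance correlation screen between genomes
#'
#' An exploratory utility: Spearman correlation of per-sample abundances,
#' restricted to genome pairs whose mean abundances differ by at most
#' \code{cooccur_ratio}-fold (default 10:1), so that correlations are not
#' driven by pairs at wildly different scales. This is an interpretation of
#' a loosely specified screen and is documented as such.
#'
#' @param abundance bin x sample relative-abundance matrix.
#' @param thresholds a \code{\link{gp_thresholds}} object.
#' @return data.frame (bin_a, bin_b, rho) or an empty data.frame when no
#'   pair qualifies.
#' @export
abundance_correlation <- function(abundance,
                                  thresholds = gp_thresholds()) {
  bins <- rownames(abundance)
  mean_ab <- rowMeans(abundance)
  rows <- list()
  for (i in seq_along(bins)) {
    for (j in seq_len(i - 1L)) {
      hi <- max(mean_ab[i], mean_ab[j])
      lo <- min(mean_ab[i], mean_ab[j])
      if (lo == 0 || hi / lo > thresholds$cooccur_ratio) next
      rho <- suppressWarnings(
        stats::cor(abundance[i, ], abundance[j, ], method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        bin_a = bins[j], bin_b = bins[i], rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(bin_a = character(0), bin_b = character(0),
                      rho = numeric(0)))
  do.call(rbind, rows)
}
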