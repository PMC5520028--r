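# Seeded evaluation that restores the caller's RNG state afterwards, so the
# generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 18-letter background alphabet for guarded fixtures: no C and no H, so the
# only CXXCH motifs in a guarded protein are the planted ones (an accidental
# motif would need a background C at its first and fourth position).
aa_guard_alphabet <- function()
  strsplit("ADEFGIKLMNPQRSTVWY", "")[[1]]

aa_full_alphabet <- function()
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

dna_alphabet <- function() c("A", "C", "G", "T")

random_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A protein of exactly `len` residues carrying exactly `k` planted CXXCH
# motifs at random non-overlapping positions, background from `alphabet`.
plant_motif_protein <- function(len, k, alphabet = aa_guard_alphabet()) {
  if (len < 5L * k)
    stop("motif payload (", 5L * k, " aa) longer than protein length (",
         len, " aa)", call. = FALSE)
  motifs <- replicate(k, paste0("C", random_string(2, alphabet), "CH"))
  spare <- len - 5L * k
  cuts <- sort(sample(0:spare, k, replace = TRUE))
  gaps <- diff(c(0L, cuts, spare))  # k + 1 background gap lengths
  bg <- vapply(gaps, function(g)
    if (g > 0) random_string(g, alphabet) else "", character(1))
  paste0(paste0(bg[seq_len(k)], motifs, collapse = ""), bg[k + 1L])
}

#' Generate a synthetic proteome with planted CXXCH motifs
#'
#' Each protein carries exactly its assigned number of planted heme-binding
#' motifs. In the default guarded mode the background alphabet contains
#' neither C nor H, so the planted count is provably the total count; the
#' full-alphabet mode (\code{guard = FALSE}) produces realistic sequences
#' whose motif counts are only known to be at least the planted number, and
#' exists for oracle-versus-implementation testing.
#'
#' @param n_proteins number of proteins.
#' @param motif_counts integer vector of planted motif counts, recycled to
#'   \code{n_proteins}.
#' @param length_range min/max protein length (aa); each protein's length is
#'   drawn uniformly, then raised to fit its motif payload if needed.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param guard use the C/H-free background alphabet (default TRUE).
#' @param prefix gene-id prefix.
#' @return list with \code{proteome} (named character vector) and
#'   \code{truth} (data.frame gene_id, planted_motifs).
#' @export
generate_proteome <- function(n_proteins, motif_counts = 0L,
                              length_range = c(60L, 300L), seed = 1L,
                              guard = TRUE, prefix = "prot") {
  stopifnot(n_proteins >= 1)
  counts <- rep_len(as.integer(motif_counts), n_proteins)
  alphabet <- if (guard) aa_guard_alphabet() else aa_full_alphabet()
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    lens <- pmax(lens, 5L * counts)
    seqs <- mapply(plant_motif_protein, lens, counts,
                   MoreArgs = list(alphabet = alphabet))
    ids <- sprintf("%s_%04d", prefix, seq_len(n_proteins))
    names(seqs) <- ids
    list(proteome = seqs,
         truth = data.frame(gene_id = ids, planted_motifs = counts,
                            stringsAsFactors = FALSE))
  })
}

# Point-mutate a sequence with an exactly realised substitution count:
# round(rate * length) positions are replaced by a different letter. The
# realised divergence is therefore deterministic given the seed, which keeps
# identity-threshold behaviour of downstream clustering exact.
mutate_seq <- function(seq, rate, alphabet) {
  n <- nchar(seq)
  m <- as.integer(round(rate * n))
  if (m == 0L) return(seq)
  pos <- sample.int(n, m)
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(ch)
    sample(setdiff(alphabet, ch), 1L), character(1))
  paste(chars, collapse = "")
}

## ---- operon layouts ----------------------------------------------------

#' Describe one hydrogenase operon layout
#'
#' A layout is one catalytic hydrogenase gene plus an ordered list of
#' downstream genes (in the catalytic gene's reading direction). Downstream
#' tokens are \code{"hydB"}, \code{"hydC"} or \code{"other"}; a
#' \code{":flip"} suffix puts that neighbor on the opposite strand. The
#' scaffold ends right after the last listed downstream gene, so a layout
#' listing fewer than \code{window} downstream genes is truncated at the
#' scaffold edge.
#'
#' @param catalytic profile label of the catalytic gene (e.g.
#'   \code{FeFe_GA}, \code{FeFe_GB}, \code{NiFe_G1}, \code{Fe_hmd}).
#' @param strand strand of the catalytic gene.
#' @param downstream character vector of downstream tokens.
#' @param n_upstream number of padding genes upstream (default 1).
#' @return list of class \code{gp_operon_layout}.
#' @export
operon_layout <- function(catalytic = "FeFe_GA", strand = c("+", "-"),
                          downstream = character(0), n_upstream = 1L) {
  strand <- match.arg(strand)
  ok <- grepl("^(hydB|hydC|other)(:flip)?$", downstream)
  if (!all(ok))
    stop("unknown layout token(s): ",
         paste(downstream[!ok], collapse = ", "), call. = FALSE)
  structure(list(catalytic = catalytic, strand = strand,
                 downstream = downstream,
                 n_upstream = as.integer(n_upstream)),
            class = "gp_operon_layout")
}

# Ground-truth label for a layout, derived from the layout description
# itself (never from the classifier): A3 when co-oriented hydB and hydC both
# sit within the downstream window; A_unresolved when the window is cut by
# the scaffold edge without complete A3 evidence; A1 otherwise. Non-Group-A
# catalytic genes are labelled by their profile.
profile_truth_label <- function(profile) {
  switch(profile,
         FeFe_GB = "B", FeFe_GC = "C", Fe_hmd = "Fe",
         sub("^NiFe_G", "NiFe_", profile))
}

layout_truth <- function(layout, window = 3L) {
  if (layout$catalytic != "FeFe_GA")
    return(profile_truth_label(layout$catalytic))
  toks <- utils::head(layout$downstream, window)
  co <- !grepl(":flip$", toks)
  base <- sub(":flip$", "", toks)
  has_b <- any(base == "hydB" & co)
  has_c <- any(base == "hydC" & co)
  truncated <- length(layout$downstream) < window
  if (has_b && has_c) "A3" else if (truncated) "A_unresolved" else "A1"
}

#' Generate a gene-call and hit-table fixture from operon layouts
#'
#' One scaffold per layout, with gene calls in the proper coordinate order
#' for the catalytic strand, matching profile hits (catalytic profile,
#' hydB/hydC neighbor labels), and the planted subgroup truth derived from
#' the layout description independently of the classifier.
#'
#' @param layouts list of \code{\link{operon_layout}} objects.
#' @param seed RNG seed (gene spacing only; calls are deterministic).
#' @param prefix scaffold-id prefix.
#' @param window window size recorded into the truth (default 3).
#' @return list(genes, hits, truth) where truth has one row per layout
#'   (scaffold_id, catalytic_gene, label).
#' @export
generate_operon_fixture <- function(layouts, seed = 1L, prefix = "op",
                                    window = 3L) {
  with_seed(seed, {
    genes <- list()
    hits <- list()
    truth <- list()
    for (li in seq_along(layouts)) {
      lay <- layouts[[li]]
      scaf <- sprintf("%s_%03d", prefix, li)
      up <- rep("other", lay$n_upstream)
      toks_down <- lay$downstream
      # token list in coordinate order (left to right on the scaffold)
      if (lay$strand == "+") {
        coord_toks <- c(up, "CATALYTIC", toks_down)
      } else {
        coord_toks <- c(rev(toks_down), "CATALYTIC", rev(up))
      }
      cat_gene <- NA_character_
      for (gi in seq_along(coord_toks)) {
        tok <- coord_toks[gi]
        gid <- sprintf("%s_g%02d", scaf, gi)
        start <- 10L + (gi - 1L) * 110L
        if (tok == "CATALYTIC") {
          strand <- lay$strand
          cat_gene <- gid
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = gid, profile = lay$catalytic, bit_score = 200,
            e_value = 1e-50, stringsAsFactors = FALSE)
        } else {
          base <- sub(":flip$", "", tok)
          flip <- grepl(":flip$", tok)
          strand <- if (flip) setdiff(c("+", "-"), lay$strand) else
            lay$strand
          if (base %in% c("hydB", "hydC"))
            hits[[length(hits) + 1L]] <- data.frame(
              gene_id = gid, profile = base,
              bit_score = if (base == "hydB") 130 else 120,
              e_value = 1e-30, stringsAsFactors = FALSE)
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, scaffold_id = scaf, start = start,
          end = start + 99L, strand = strand, ordinal = gi,
          stringsAsFactors = FALSE)
      }
      truth[[li]] <- data.frame(
        scaffold_id = scaf, catalytic_gene = cat_gene,
        label = layout_truth(lay, window), stringsAsFactors = FALSE)
    }
    list(genes = do.call(rbind, genes), hits = do.call(rbind, hits),
         truth = do.call(rbind, truth))
  })
}

#' Exhaustive grid of operon layouts
#'
#' Enumerates catalytic strand x hydB state (absent / co-oriented /
#' opposite strand) x hydC state x neighbor order x window truncation:
#' 72 layouts covering every subgroup decision branch, including all
#' scaffold-edge cases.
#'
#' @return list of \code{\link{operon_layout}} objects.
#' @export
operon_layout_grid <- function() {
  states <- c("absent", "same", "flip")
  grid <- expand.grid(strand = c("+", "-"), b = states, c = states,
                      c_first = c(FALSE, TRUE), pad = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  layouts <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tok <- function(base, state)
      switch(state, absent = NULL, same = base,
             flip = paste0(base, ":flip"))
    parts <- if (g$c_first) c(tok("hydC", g$c), tok("hydB", g$b)) else
      c(tok("hydB", g$b), tok("hydC", g$c))
    down <- unlist(parts)
    if (is.null(down)) down <- character(0)
    if (g$pad) down <- c(down, rep("other", 3L))
    layouts[[length(layouts) + 1L]] <-
      operon_layout("FeFe_GA", g$strand, down)
  }
  layouts
}

## ---- community generator -----------------------------------------------

# Minimal clause evaluator used only to record planted pathway truth from a
# bin's final gene-label complement. Kept separate from evaluate_pathway so
# the planted truth and the rule engine are two code paths.
plant_status <- function(labels, rule) {
  sat <- logical(length(rule$clauses))
  pos_hit <- FALSE
  for (ci in seq_along(rule$clauses)) {
    present <- any(rule$clauses[[ci]] %in% labels)
    sat[ci] <- if (rule$negated[ci]) !present else present
    if (!rule$negated[ci] && present) pos_hit <- TRUE
  }
  if (all(sat)) "complete" else if (!pos_hit) "absent" else "partial"
}

# Pick gene labels aiming a rule at a drawn status; the recorded truth is
# re-derived from the final complement so cross-rule label collisions can
# never desynchronise truth and fixture.
genes_for_status <- function(rule, status) {
  pos <- which(!rule$negated)
  pick_one <- function(ci) sample(rule$clauses[[ci]], 1L)
  if (status == "complete") {
    vapply(pos, pick_one, character(1))
  } else if (status == "partial" && length(pos) >= 2) {
    k <- sample(seq_len(length(pos) - 1L), 1L)
    vapply(sample(pos, k), pick_one, character(1))
  } else {
    character(0)
  }
}

default_hyd_plan <- function() {
  list(
    bin01 = list(operon_layout("FeFe_GA", "+", c("hydB", "hydC", "other")),
                 operon_layout("FeFe_GA", "-", c("hydB", "hydC")),
                 operon_layout("FeFe_GA", "+", rep("other", 3))),
    bin02 = list(operon_layout("FeFe_GA", "+", c("hydC", "hydB", "other")),
                 operon_layout("FeFe_GA", "-", c("hydB", "hydC", "other")),
                 operon_layout("FeFe_GA", "-", rep("other", 4))),
    bin03 = list(operon_layout("FeFe_GA", "+", c("hydB", "hydC")),
                 operon_layout("FeFe_GA", "+", rep("other", 3))),
    bin04 = list(operon_layout("FeFe_GA", "-", c("hydB", "hydC", "other")),
                 operon_layout("FeFe_GB", "+")),
    bin05 = list(operon_layout("FeFe_GA", "+", c("hydB", "hydC", "other")),
                 operon_layout("FeFe_GB", "-")),
    bin06 = list(operon_layout("FeFe_GA", "-", c("hydB", "hydC")),
                 operon_layout("FeFe_GC", "+")),
    bin07 = list(operon_layout("NiFe_G1", "+"),
                 operon_layout("FeFe_GA", "+", character(0))),
    bin08 = list(operon_layout("NiFe_G1", "-")),
    bin09 = list(operon_layout("NiFe_G3", "+"),
                 operon_layout("Fe_hmd", "+"))
  )
}

default_mhc_plan <- function() {
  list(bin01 = c(12L, 15L, 20L, 55L, 10L),
       bin02 = c(10L, 11L, 12L, 13L),
       bin03 = c(10L, 10L, 12L, 9L),
       bin04 = c(11L, 9L),
       bin05 = c(10L))
}

default_replicate_spec <- function() {
  data.frame(
    source = c(sprintf("bin%02d", 1:8), sprintf("bin%02d", 1:4)),
    rate = c(rep(0.005, 8), rep(0.10, 4)),
    suffix = c(rep("rep", 8), rep("far", 4)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic community with planted ground truth
#'
#' Emits everything the pipeline consumes - per-bin nucleotide scaffolds,
#' gene calls, proteins, profile hits, per-scaffold per-sample depths and a
#' bin membership table - together with a truth record for every planted
#' quantity: marker complements (hence completeness/contamination),
#' hydrogenase labels, MHC motif counts, pathway gene complements,
#' organism abundances, and the replicate lineage map.
#'
#' Key constructions: depth is identical for all scaffolds of a bin and
#' proportional to the organism's drawn abundance (log-normal across
#' organisms, with log-normal per-sample variation); every organism carries
#' exactly one rpS3 gene (a 200-aa guarded random string, point-mutated per
#' replicate); replicate bins are copies of a source whose scaffolds and
#' rpS3 are mutated with an exactly realised substitution count, so
#' identity-threshold behaviour is deterministic.
#'
#' @param n_bins number of source bins (default 12).
#' @param mset marker set planted (default \code{\link{default_marker_set}}).
#' @param rules pathway rulebook used to plant gene complements.
#' @param n_samples number of samples (default 4).
#' @param abundance_sdlog log-normal sd of organism base abundances
#'   (default 2.2, giving a realistic long-tailed rank-abundance curve);
#'   per-sample variation uses sdlog 0.5.
#' @param total_depth depth assigned to an organism at relative abundance 1.
#' @param replicate_spec data.frame (source, rate, suffix) of mutated bin
#'   copies; rates must lie in [0, 0.3]. Default: 8 replicates at 0.5%
#'   divergence plus 4 decoys at 10%.
#' @param n_unbinned number of organisms with an rpS3 scaffold but no bin.
#' @param n_scaffolds,scaffold_bp scaffold count and length per source bin.
#' @param hyd_plan named list (bin -> list of \code{\link{operon_layout}});
#'   default plants bifurcating-dominated hydrogenase content.
#' @param mhc_plan named list (bin -> planted motif counts, one protein
#'   each); default plants two iron-reducer bins.
#' @param seed RNG seed; the whole bundle is a pure function of arguments.
#' @return list with \code{bundle} (proteome, genes, hits, coverage,
#'   membership, scaffolds, rps3) and \code{truth}.
#' @export
generate_community <- function(n_bins = 12L,
                               mset = default_marker_set(),
                               rules = default_pathway_rules(),
                               n_samples = 4L,
                               abundance_sdlog = 2.2,
                               total_depth = 1000,
                               replicate_spec = default_replicate_spec(),
                               n_unbinned = 6L,
                               n_scaffolds = 5L,
                               scaffold_bp = 2500L,
                               hyd_plan = default_hyd_plan(),
                               mhc_plan = default_mhc_plan(),
                               seed = 1L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (length(mset$markers) == 0) stop("marker set empty", call. = FALSE)
  if (!is.null(replicate_spec) && nrow(replicate_spec) > 0) {
    if (any(replicate_spec$rate < 0 | replicate_spec$rate > 0.3))
      stop("replicate mutation rates must lie in [0, 0.3]", call. = FALSE)
    bad <- setdiff(replicate_spec$source, sprintf("bin%02d", seq_len(n_bins)))
    if (length(bad) > 0)
      stop("replicate source(s) not among bins: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    src_bins <- sprintf("bin%02d", seq_len(n_bins))
    hyd_plan <- hyd_plan[intersect(names(hyd_plan), src_bins)]
    mhc_plan <- mhc_plan[intersect(names(mhc_plan), src_bins)]

    genes <- list(); hits <- list(); proteome <- list()
    scaffolds <- list()      # bin -> named chr of nucleotide scaffolds
    membership <- list()
    rps3_seq <- list(); rps3_scaf <- list(); rps3_bin <- list()
    truth_hyd <- list(); truth_mark <- list(); truth_motifs <- list()
    bin_labels <- list()     # bin -> planted gene-label complement
    gene_ctr <- 0L
    new_gid <- function(bin) {
      gene_ctr <<- gene_ctr + 1L
      sprintf("%s_g%04d", bin, gene_ctr)
    }
    slot <- new.env(parent = emptyenv())
    add_gene <- function(bin, scaf, profile = NULL, protein = NULL,
                         score = 150) {
      gid <- new_gid(bin)
      k <- if (is.null(slot[[scaf]])) 1L else slot[[scaf]] + 1L
      slot[[scaf]] <- k
      start <- 10L + (k - 1L) * 110L
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = gid, scaffold_id = scaf, start = start,
        end = start + 99L, strand = "+", stringsAsFactors = FALSE)
      if (!is.null(profile))
        for (p in profile)
          hits[[length(hits) + 1L]] <<- data.frame(
            gene_id = gid, profile = p, bit_score = score,
            e_value = 1e-40, stringsAsFactors = FALSE)
      proteome[[gid]] <<- if (is.null(protein))
        random_string(80L, aa_guard_alphabet()) else protein
      gid
    }

    build_bin <- function(bin, markers_present, markers_dup, labels,
                          mhc_counts, layouts, src = NULL, rate = 0) {
      # scaffolds: mutated copies of the source's, or fresh sequence
      if (is.null(src)) {
        scafs <- stats::setNames(
          vapply(seq_len(n_scaffolds), function(i)
            random_string(scaffold_bp, dna_alphabet()), character(1)),
          sprintf("%s_s%d", bin, seq_len(n_scaffolds)))
      } else {
        srcseq <- scaffolds[[src]]
        srcseq <- srcseq[grepl("_s[0-9]+$", names(srcseq))]
        scafs <- stats::setNames(
          vapply(srcseq, mutate_seq, character(1), rate = rate,
                 alphabet = dna_alphabet()),
          sprintf("%s_s%d", bin, seq_along(srcseq)))
      }
      # extra small scaffolds, one per hydrogenase operon
      for (li in seq_along(layouts)) {
        nm <- sprintf("%s_h%d_001", bin, li)
        scafs[[nm]] <- if (is.null(src))
          random_string(1200L, dna_alphabet()) else
          mutate_seq(scaffolds[[src]][[sprintf("%s_h%d_001", src, li)]],
                     rate, dna_alphabet())
      }
      scaffolds[[bin]] <<- scafs
      membership[[length(membership) + 1L]] <<- data.frame(
        bin_id = bin, scaffold_id = names(scafs), stringsAsFactors = FALSE)
      home <- names(scafs)[1:min(4L, length(scafs))]
      # single-copy markers (duplicated ones get a second gene)
      for (m in markers_present) {
        add_gene(bin, sample(home, 1L), profile = m)
        if (m %in% markers_dup) add_gene(bin, sample(home, 1L), profile = m)
      }
      # pathway / count genes; hydrogenase-family labels planted as pathway
      # markers (e.g. an uptake [NiFe]) are hydrogenases too and enter the
      # hydrogenase truth with their profile's label
      hyd_fam <- hydrogenase_profiles()$profile
      for (lab in labels) {
        gid <- add_gene(bin, sample(home, 1L), profile = lab)
        if (lab %in% setdiff(hyd_fam, "FeFe_GA"))
          truth_hyd[[length(truth_hyd) + 1L]] <<- data.frame(
            bin_id = bin, gene_id = gid, catalytic = lab,
            label = profile_truth_label(lab), stringsAsFactors = FALSE)
      }
      # MHC proteins (planted motif counts) + one motif-free protein
      motifs <- c(mhc_counts, 0L)
      for (k in motifs) {
        prot <- plant_motif_protein(max(60L, 5L * k + 10L), k)
        gid <- add_gene(bin, home[length(home)], protein = prot)
        truth_motifs[[gid]] <<- k
      }
      # rpS3: one per organism
      rid <- sprintf("%s_rps3", bin)
      rseq <- if (is.null(src)) random_string(200L, aa_guard_alphabet())
        else mutate_seq(rps3_seq[[sprintf("%s_rps3", src)]], rate,
                        aa_guard_alphabet())
      gid <- add_gene(bin, home[1], profile = "rpS3", protein = rseq)
      rps3_seq[[rid]] <<- rseq
      rps3_scaf[[rid]] <<- home[1]
      rps3_bin[[rid]] <<- bin
      # hydrogenase operons, one dedicated scaffold each
      for (li in seq_along(layouts)) {
        lay <- layouts[[li]]
        fx <- generate_operon_fixture(list(lay),
                                      seed = sample.int(1e6, 1),
                                      prefix = sprintf("%s_h%d", bin, li))
        for (ri in seq_len(nrow(fx$genes))) {
          genes[[length(genes) + 1L]] <<- fx$genes[ri, c(
            "gene_id", "scaffold_id", "start", "end", "strand")]
          proteome[[fx$genes$gene_id[ri]]] <<-
            random_string(80L, aa_guard_alphabet())
        }
        for (ri in seq_len(nrow(fx$hits)))
          hits[[length(hits) + 1L]] <<- fx$hits[ri, ]
        truth_hyd[[length(truth_hyd) + 1L]] <<- data.frame(
          bin_id = bin, gene_id = fx$truth$catalytic_gene,
          catalytic = lay$catalytic, label = fx$truth$label,
          stringsAsFactors = FALSE)
      }
      truth_mark[[bin]] <<- list(present = markers_present,
                                 duplicated = markers_dup)
      bin_labels[[bin]] <<- labels
    }

    # --- source bins ---
    src_mark <- list(); src_labels <- list()
    pathway_names <- names(rules)
    for (bi in seq_len(n_bins)) {
      bin <- src_bins[bi]
      n_present <- sample(28:length(mset$markers), 1L)
      present <- sort(sample(mset$markers, n_present))
      dup <- sort(sample(present, sample(0:6, 1L)))
      statuses <- sample(c("complete", "partial", "absent"),
                         length(pathway_names), replace = TRUE,
                         prob = c(0.25, 0.25, 0.5))
      names(statuses) <- pathway_names
      # controlled Rnf planting: complete in the first five bifurcating
      # bins, absent in the sixth, so Rnf co-occurrence is known by design
      if ("rnf_complex" %in% pathway_names) {
        if (bin %in% sprintf("bin%02d", 1:5)) statuses["rnf_complex"] <- "complete"
        if (bin == "bin06") statuses["rnf_complex"] <- "absent"
      }
      labels <- unlist(lapply(pathway_names, function(pw)
        genes_for_status(rules[[pw]], statuses[pw])))
      # count-scored gene families (fermentation / complex carbon)
      csets <- default_count_gene_sets()
      for (cs in csets)
        labels <- c(labels, sample(cs, sample(0:6, 1L)))
      labels <- sort(unique(labels))
      src_mark[[bin]] <- list(present = present, dup = dup)
      src_labels[[bin]] <- labels
      build_bin(bin, present, dup, labels,
                mhc_counts = if (bin %in% names(mhc_plan))
                  mhc_plan[[bin]] else integer(0),
                layouts = if (bin %in% names(hyd_plan))
                  hyd_plan[[bin]] else list())
    }

    # --- replicate / decoy bins: inherit the source's annotation ---
    rep_map <- list()
    if (!is.null(replicate_spec) && nrow(replicate_spec) > 0) {
      for (ri in seq_len(nrow(replicate_spec))) {
        src <- replicate_spec$source[ri]
        rate <- replicate_spec$rate[ri]
        bin <- sprintf("%s_%s", src, replicate_spec$suffix[ri])
        mk <- src_mark[[src]]
        drop_m <- sample(mk$present, sample(0:2, 1L))
        present <- setdiff(mk$present, drop_m)
        build_bin(bin, present, intersect(mk$dup, present),
                  src_labels[[src]],
                  mhc_counts = if (src %in% names(mhc_plan))
                    mhc_plan[[src]] else integer(0),
                  layouts = if (src %in% names(hyd_plan))
                    hyd_plan[[src]] else list(),
                  src = src, rate = rate)
        rep_map[[length(rep_map) + 1L]] <- data.frame(
          bin_id = bin, source = src, rate = rate,
          stringsAsFactors = FALSE)
      }
    }
    rep_map <- if (length(rep_map) > 0) do.call(rbind, rep_map) else
      data.frame(bin_id = character(0), source = character(0),
                 rate = numeric(0))

    # --- unbinned organisms: an rpS3 scaffold outside any bin ---
    unbinned_scafs <- list()
    for (ui in seq_len(n_unbinned)) {
      org <- sprintf("unb%02d", ui)
      scaf <- sprintf("%s_s1", org)
      unbinned_scafs[[scaf]] <- random_string(1500L, dna_alphabet())
      rid <- sprintf("%s_rps3", org)
      rseq <- random_string(200L, aa_guard_alphabet())
      gid <- sprintf("%s_g1", org)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, scaffold_id = scaf, start = 10L, end = 109L,
        strand = "+", stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = gid, profile = "rpS3", bit_score = 150, e_value = 1e-40,
        stringsAsFactors = FALSE)
      proteome[[gid]] <- rseq
      rps3_seq[[rid]] <- rseq
      rps3_scaf[[rid]] <- scaf
      rps3_bin[[rid]] <- NA_character_
    }

    # --- a few sub-cutoff junk hits that the parser must drop ---
    all_gids <- vapply(genes, `[[`, character(1), "gene_id")
    for (g in sample(all_gids, min(3L, length(all_gids))))
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = g, profile = "narG", bit_score = 12, e_value = 0.5,
        stringsAsFactors = FALSE)

    # --- abundances and depths ---
    all_bins <- c(src_bins, rep_map$bin_id)
    organisms <- c(all_bins, sprintf("unb%02d", seq_len(n_unbinned)))
    base <- stats::rlnorm(length(organisms), 0, abundance_sdlog)
    raw <- base * matrix(stats::rlnorm(length(organisms) * n_samples,
                                       0, 0.5),
                         length(organisms), n_samples)
    ab <- sweep(raw, 2, colSums(raw), "/")
    dimnames(ab) <- list(organisms, sprintf("sample%d", seq_len(n_samples)))

    memb <- do.call(rbind, membership)
    scaffold_seqs <- c(unlist(unname(lapply(scaffolds, as.list)),
                              recursive = FALSE), unbinned_scafs)
    scaffold_seqs <- stats::setNames(as.character(scaffold_seqs),
                                     names(scaffold_seqs))
    org_of_scaffold <- stats::setNames(
      c(memb$bin_id, names(unbinned_scafs)),
      c(memb$scaffold_id, names(unbinned_scafs)))
    org_of_scaffold[names(unbinned_scafs)] <-
      sub("_s1$", "", names(unbinned_scafs))
    coverage <- ab[org_of_scaffold[names(scaffold_seqs)], , drop = FALSE] *
      total_depth
    rownames(coverage) <- names(scaffold_seqs)

    genes_df <- do.call(rbind, genes)
    genes_df <- genes_df[order(genes_df$scaffold_id, genes_df$start), ]
    genes_df$ordinal <- as.integer(
      stats::ave(genes_df$start, genes_df$scaffold_id, FUN = seq_along))
    rownames(genes_df) <- NULL
    hits_df <- do.call(rbind, hits)
    rownames(hits_df) <- NULL

    motifs_all <- stats::setNames(integer(length(proteome)),
                                  names(proteome))
    motifs_all[names(truth_motifs)] <-
      unlist(truth_motifs)[names(truth_motifs)]
    # planted pathway truth, re-derived from each bin's final label set
    label_sets <- lapply(stats::setNames(all_bins, all_bins), function(b) {
      g <- memb$scaffold_id[memb$bin_id == b]
      gg <- genes_df$gene_id[genes_df$scaffold_id %in% g]
      sort(unique(hits_df$profile[hits_df$gene_id %in% gg &
                                    hits_df$bit_score >= 50]))
    })
    truth_path <- do.call(rbind, lapply(all_bins, function(b)
      data.frame(bin_id = b, pathway = pathway_names,
                 status = vapply(rules, plant_status, character(1),
                                 labels = label_sets[[b]]),
                 stringsAsFactors = FALSE)))

    bundle <- list(
      proteome = stats::setNames(as.character(proteome), names(proteome)),
      genes = genes_df,
      hits = hits_df,
      coverage = coverage,
      membership = memb,
      scaffold_seqs = scaffold_seqs,
      bin_scaffolds = scaffolds,
      rps3 = list(
        seqs = stats::setNames(as.character(rps3_seq), names(rps3_seq)),
        scaffold = stats::setNames(as.character(rps3_scaf),
                                   names(rps3_scaf)),
        bin = stats::setNames(as.character(rps3_bin), names(rps3_bin)))
    )
    truth <- list(
      motifs = motifs_all,
      mhc_plan = mhc_plan,
      markers = truth_mark,
      n_markers = length(mset$markers),
      hyd = if (length(truth_hyd) > 0) do.call(rbind, truth_hyd) else
        data.frame(bin_id = character(0), gene_id = character(0),
                   catalytic = character(0), label = character(0)),
      pathway_status = truth_path,
      label_sets = label_sets,
      abundance = ab,
      total_depth = total_depth,
      replicate_map = rep_map,
      bins = all_bins,
      unbinned = sprintf("unb%02d", seq_len(n_unbinned))
    )
    list(bundle = bundle, truth = truth)
  })
}
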