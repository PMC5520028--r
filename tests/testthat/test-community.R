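mk_marker_hits <- function(counts) {
  # counts: named integer, marker -> copy number
  rows <- lapply(names(counts), function(m) {
    k <- counts[[m]]
    if (k == 0) return(NULL)
    data.frame(gene_id = paste0(m, "_g", seq_len(k)), profile = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("completeness and contamination count marker copies", {
  ms <- default_marker_set()
  counts <- stats::setNames(rep(0L, 51), ms$markers)
  counts[1:43] <- 1L
  counts[1:3] <- 2L
  q <- bin_quality(mk_marker_hits(counts), ms)
  expect_equal(round(q$completeness, 2), 84.31)
  expect_equal(round(q$contamination, 2), 5.88)
  expect_true(q$is_high_quality)

  counts[] <- 1L
  q <- bin_quality(mk_marker_hits(counts), ms)
  expect_equal(c(q$completeness, q$contamination), c(100, 0))
  expect_true(q$is_high_quality)

  counts[] <- 0L; counts[1:35] <- 1L
  q <- bin_quality(mk_marker_hits(counts), ms)
  expect_equal(round(q$completeness, 2), 68.63)
  expect_false(q$is_high_quality)

  expect_error(bin_quality(mk_marker_hits(counts),
                           marker_set(character(0))), "empty")
})

test_that("high-quality calls flip exactly at the 70/10 boundaries", {
  ms <- marker_set(paste0("m", 1:10))
  at <- function(n_present, n_dup) {
    counts <- stats::setNames(rep(0L, 10), ms$markers)
    counts[seq_len(n_present)] <- 1L
    if (n_dup > 0) counts[seq_len(n_dup)] <- 2L
    bin_quality(mk_marker_hits(counts), ms)
  }
  expect_false(at(7, 0)$is_high_quality)   # 70% is not > 70%
  expect_true(at(8, 0)$is_high_quality)    # 80% > 70%
  expect_false(at(8, 1)$is_high_quality)   # 10% is not < 10%
  expect_true(at(10, 0)$is_high_quality)
})

test_that("pairwise identity recovers planted divergence", {
  set.seed(21)
  dna <- c("A", "C", "G", "T")
  src <- stats::setNames(
    replicate(4, paste(sample(dna, 3000, replace = TRUE), collapse = "")),
    paste0("s", 1:4))
  same <- pairwise_identity(src, src)
  expect_equal(same$identity, 1.0)
  expect_equal(same$aligned_frac, 1.0)

  mut <- stats::setNames(vapply(src, genopotential:::mutate_seq,
                                character(1), rate = 0.05,
                                alphabet = dna), paste0("m", 1:4))
  got <- pairwise_identity(src, mut)
  expect_equal(got$identity, 0.95, tolerance = 0.01)
  expect_gt(got$aligned_frac, 0.95)

  other <- stats::setNames(
    replicate(2, paste(sample(dna, 3000, replace = TRUE), collapse = "")),
    paste0("o", 1:2))
  far <- pairwise_identity(src, other)
  expect_equal(far$aligned_frac, 0)
  expect_true(is.na(far$identity))
})

test_that("dereplication uses single linkage and completeness-based reps", {
  ids <- data.frame(bin_a = c("A", "B", "A"), bin_b = c("B", "C", "C"),
                    identity = c(0.985, 0.985, 0.96),
                    aligned_frac = 0.9)
  dr <- dereplicate(c("A", "B", "C"), ids)
  expect_equal(dr$clusters, list(c("A", "B", "C")))  # chained linkage

  ids2 <- data.frame(bin_a = "A", bin_b = "B",
                     identity = 0.995, aligned_frac = 0.9)
  qc <- data.frame(bin_id = c("A", "B", "C"),
                   completeness = c(80, 95, 70),
                   contamination = c(2, 2, 1))
  dr <- dereplicate(c("A", "B", "C"), ids2, qc)
  expect_equal(length(dr$clusters), 2)
  expect_equal(dr$representatives[vapply(dr$clusters, function(cl)
    "A" %in% cl, logical(1))], "B")  # higher completeness wins
  # low aligned fraction blocks an edge even at high identity
  ids3 <- data.frame(bin_a = "A", bin_b = "B",
                     identity = 0.999, aligned_frac = 0.2)
  expect_equal(length(dereplicate(c("A", "B"), ids3)$clusters), 2)
})

test_that("rpS3 clustering respects the identity threshold", {
  base <- generate_proteome(1, 0, length_range = c(200, 200),
                            seed = 31)$proteome[[1]]
  near <- genopotential:::mutate_seq(base, 0.005,
                                     genopotential:::aa_guard_alphabet())
  far <- genopotential:::mutate_seq(base, 0.05,
                                    genopotential:::aa_guard_alphabet())
  cl <- cluster_rps3(c(a = base, b = base))
  expect_equal(length(cl$clusters), 1)
  cl <- cluster_rps3(c(a = base, b = near, c = far))
  expect_equal(length(cl$clusters), 2)  # 99.5% joins, 95% does not
  expect_equal(unname(cl$membership["b"]), unname(cl$membership["a"]))
  expect_equal(length(cluster_rps3(stats::setNames(character(0),
                                                   character(0)))$clusters),
               0)
  # at threshold 1.0 only exact duplicates cluster
  cl <- cluster_rps3(c(a = base, b = near, c = base),
                     gp_thresholds(rps3_cluster_identity = 1.0))
  expect_equal(length(cl$clusters), 2)
})

test_that("rank abundance normalises depth and flags binned organisms", {
  cl <- list(clusters = list(o1 = "r1", o2 = "r2", o3 = "r3"),
             membership = c(r1 = "o1", r2 = "o2", r3 = "o3"))
  cov <- matrix(c(50, 30, 20), 3, 1,
                dimnames = list(c("s1", "s2", "s3"), "samp"))
  rscaf <- c(r1 = "s1", r2 = "s2", r3 = "s3")
  memb <- data.frame(bin_id = c("b1", "b2"), scaffold_id = c("s1", "s2"))
  rk <- rank_abundance(cl, rscaf, cov, memb, top_k = 3)
  expect_equal(rk$ranking$abundance, c(0.5, 0.3, 0.2))
  expect_equal(rk$ranking$organism, c("o1", "o2", "o3"))
  expect_equal(rk$ranking$binned, c(TRUE, TRUE, FALSE))
  expect_equal(rk$summary$top_k_binned, 2)
  expect_equal(rk$summary$frac_unbinned_below_rare, 0)
  cov0 <- cov * 0
  expect_error(rank_abundance(cl, rscaf, cov0, memb), "zero")
})

test_that("bin relative abundance is length-weighted and scale-invariant", {
  memb <- data.frame(bin_id = c("b1", "b1", "b2"),
                     scaffold_id = c("s1", "s2", "s3"))
  lens <- c(s1 = 1000L, s2 = 3000L, s3 = 2000L)
  cov <- matrix(c(10, 10, 30,
                  2, 2, 6), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("x", "y")))
  ab <- relative_abundance(memb, lens, cov)
  expect_equal(unname(ab[, "x"]), c(0.25, 0.75))
  expect_equal(unname(ab[, "y"]), c(0.25, 0.75))  # scale invariance
  expect_equal(unname(colSums(ab)), c(1, 1), tolerance = 1e-12)
  # single bin -> abundance 1 everywhere
  ab1 <- relative_abundance(memb[memb$bin_id == "b1", ], lens, cov)
  expect_equal(unname(ab1), matrix(1, 1, 2), ignore_attr = TRUE)
  # permuting membership rows changes nothing
  ab2 <- relative_abundance(memb[c(3, 1, 2), ], lens, cov)
  expect_identical(ab, ab2)
  expect_error(relative_abundance(
    data.frame(bin_id = "b9", scaffold_id = "nope"), lens, cov),
    "missing from coverage")
})

test_that("correlation screen restricts pairs by abundance ratio", {
  ab <- rbind(b1 = c(0.50, 0.40, 0.45, 0.55),
              b2 = c(0.25, 0.20, 0.225, 0.275),
              b3 = c(0.001, 0.002, 0.001, 0.002))
  ab <- sweep(ab, 2, colSums(ab), "/")
  got <- abundance_correlation(ab)
  # b3 is ~300-fold below b1/b2: only the b1-b2 pair qualifies at 10:1
  expect_equal(nrow(got), 1)
  expect_setequal(c(got$bin_a, got$bin_b), c("b1", "b2"))
  expect_equal(got$rho, 1)  # perfectly co-varying profiles
})

test_that("alignment trimming enforces column, taxon and tree thresholds", {
  # block with 20 taxa; column 2 is gap in 19/20 (95% > 90% -> removed),
  # column 3 is gap in 18/20 (90%, not above -> kept)
  taxa <- paste0("t", sprintf("%02d", 1:20))
  col1 <- rep("A", 20)
  col2 <- c("A", rep("-", 19))
  col3 <- c("A", "A", rep("-", 18))
  block <- stats::setNames(paste0(col1, col2, col3), taxa)
  tr <- trim_concatenated_alignment(list(block),
                                    gp_thresholds(tree_min_positions = 1L))
  expect_equal(tr$n_columns, 2)
  # retained columns never exceed the gap threshold
  m <- do.call(rbind, strsplit(tr$alignment, ""))
  expect_true(all(colMeans(m == "-") <= 0.9))

  # taxon with 40% coverage of the concatenation is dropped
  long <- stats::setNames(c(strrep("A", 100), strrep("A", 100),
                            paste0(strrep("A", 40), strrep("-", 60))),
                          c("x", "y", "z"))
  tr <- trim_concatenated_alignment(list(long),
                                    gp_thresholds(tree_min_positions = 50L))
  expect_equal(tr$dropped_taxa, "z")
  expect_setequal(names(tr$alignment), c("x", "y"))

  # trimming its own output is a no-op
  tr2 <- trim_concatenated_alignment(list(tr$alignment),
                                     gp_thresholds(tree_min_positions = 50L))
  expect_identical(tr2$alignment, tr$alignment)
})

test_that("tree eligibility flips exactly at 450 aligned positions", {
  n <- 898L  # 449 non-gap positions = exactly 50% coverage, so both
             # boundary taxa survive the 50% sequence filter
  mk <- function(non_gap) paste0(strrep("A", non_gap),
                                 strrep("-", n - non_gap))
  block <- c(at449 = mk(449L), at450 = mk(450L), full = strrep("A", n))
  tr <- trim_concatenated_alignment(list(block))
  expect_equal(tr$n_columns, n)               # no column is >90% gaps
  expect_equal(tr$dropped_taxa, character(0))
  expect_true("at450" %in% tr$tree_eligible)
  expect_false("at449" %in% tr$tree_eligible) # retained but not eligible
  expect_true("at449" %in% names(tr$alignment))
})
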