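mk_hits <- function(...) {
  v <- c(...)
  data.frame(gene_id = "g", profile = names(v), bit_score = unname(v),
             e_value = NA_real_, stringsAsFactors = FALSE)
}

test_that("cofactor/group assignment takes the best hit, ties flagged", {
  a <- assign_group(mk_hits(FeFe_GA = 200, FeFe_GB = 50))
  expect_equal(c(a$cofactor, a$group), c("FeFe", "A"))
  expect_false(a$ambiguous)
  a <- assign_group(mk_hits(NiFe_G1 = 80))
  expect_equal(c(a$cofactor, a$group), c("NiFe", "1"))
  a <- assign_group(mk_hits(FeFe_GA = 100, FeFe_GB = 100))
  expect_equal(c(a$cofactor, a$group), c("FeFe", "A"))
  expect_true(a$ambiguous)
  expect_null(assign_group(mk_hits(narG = 500)))
})

test_that("Group A resolution follows the downstream hydB/hydC rule", {
  fx <- generate_operon_fixture(list(
    operon_layout("FeFe_GA", "+", c("hydB", "hydC", "other")),
    operon_layout("FeFe_GA", "+", rep("other", 3)),
    operon_layout("FeFe_GA", "+", character(0)),
    operon_layout("FeFe_GA", "+", c("hydB", "hydC:flip", "other"))),
    seed = 2)
  calls <- call_hydrogenases(fx$genes, fx$hits)
  got <- calls$subgroup[match(fx$truth$catalytic_gene, calls$gene_id)]
  expect_equal(got, c("A3", "A1", "A_unresolved", "A1"))
  # A3 evidence carries both roles
  a3 <- calls$evidence[[match(fx$truth$catalytic_gene[1], calls$gene_id)]]
  expect_setequal(a3$role, c("hydB", "hydC"))
  expect_error(resolve_groupA("nope", fx$genes, fx$hits), "not present")
})

test_that("the exhaustive layout grid is classified to planted truth", {
  layouts <- operon_layout_grid()
  expect_gte(length(layouts), 64)
  fx <- generate_operon_fixture(layouts, seed = 4)
  calls <- call_hydrogenases(fx$genes, fx$hits)
  got <- calls$subgroup[match(fx$truth$catalytic_gene, calls$gene_id)]
  expect_identical(got, fx$truth$label)
})

test_that("subgroup calls are strand-symmetric and order-independent", {
  fx <- generate_operon_fixture(operon_layout_grid(), seed = 4)
  ref <- call_hydrogenases(fx$genes, fx$hits)
  # mirror every scaffold: reverse coordinates, flip strands
  mir <- fx$genes
  for (sc in unique(mir$scaffold_id)) {
    i <- mir$scaffold_id == sc
    L <- max(mir$end[i]) + 10L
    s <- L - mir$end[i]
    e <- L - mir$start[i]
    mir$start[i] <- s
    mir$end[i] <- e
    mir$strand[i] <- ifelse(mir$strand[i] == "+", "-", "+")
  }
  mir <- mir[order(mir$scaffold_id, mir$start), ]
  mir$ordinal <- as.integer(stats::ave(mir$start, mir$scaffold_id,
                                       FUN = seq_along))
  mcalls <- call_hydrogenases(mir, fx$hits)
  expect_identical(
    mcalls$subgroup[match(ref$gene_id, mcalls$gene_id)], ref$subgroup)
  # shuffling gene-row order changes nothing
  set.seed(1)
  shuf <- fx$genes[sample(nrow(fx$genes)), ]
  scalls <- call_hydrogenases(shuf, fx$hits[sample(nrow(fx$hits)), ])
  expect_identical(scalls$subgroup, ref$subgroup)
  expect_identical(scalls$gene_id, ref$gene_id)
})

test_that("per-bin summaries and co-occurrence fractions are correct", {
  fx <- generate_operon_fixture(list(
    operon_layout("FeFe_GA", "+", c("hydB", "hydC")),
    operon_layout("FeFe_GA", "-", c("hydB", "hydC")),
    operon_layout("FeFe_GB", "+"),
    operon_layout("FeFe_GA", "+", rep("other", 3)),
    operon_layout("NiFe_G1", "+")), seed = 6)
  calls <- call_hydrogenases(fx$genes, fx$hits)
  gene_bins <- data.frame(
    gene_id = fx$genes$gene_id,
    bin_id = c("b1", "b1", "b1", "b2", "b2")[
      match(fx$genes$scaffold_id, unique(fx$genes$scaffold_id))])
  rnf <- data.frame(gene_id = fx$genes$gene_id[1], profile = "rnfC",
                    bit_score = 100, e_value = NA_real_)
  s <- summarize_hydrogenases(calls, gene_bins,
                              rbind(fx$hits, rnf), bin_ids = c("b1", "b2", "b3"))
  expect_equal(sum(s$counts), 5)
  expect_equal(unname(rowSums(s$counts)), c(3L, 2L, 0L))
  f <- s$flags
  expect_equal(f$has_bifurcating, c(TRUE, FALSE, FALSE))
  expect_equal(f$has_A1, c(FALSE, TRUE, FALSE))
  expect_equal(f$has_rnf, c(TRUE, FALSE, FALSE))
  cs <- cooccurrence_stats(s)
  expect_equal(cs$frac_A1_with_A3, 0)      # the A1 bin lacks A3
  expect_equal(cs$frac_bifurcating_with_rnf, 1)
  expect_equal(cs$frac_B_with_A3, 1)
})

test_that("co-occurrence fractions handle degenerate denominators", {
  flags <- data.frame(bin_id = paste0("b", 1:10),
                      n_hydrogenases = 1L,
                      has_A1 = FALSE,
                      has_A3 = rep(TRUE, 10),
                      has_B = FALSE)
  flags$has_bifurcating <- flags$has_A3
  flags$has_rnf <- c(rep(TRUE, 7), rep(FALSE, 3))
  s <- structure(list(counts = matrix(0, 0, 0), flags = flags),
                 class = "gp_hyd_summary")
  cs <- cooccurrence_stats(s)
  expect_equal(cs$frac_bifurcating_with_rnf, 0.7)
  expect_true(is.na(cs$frac_A1_with_A3))
  expect_true(is.na(cs$frac_B_with_A3))
})
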