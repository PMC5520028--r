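test_that("count_cxxch matches the motif definition on crafted cases", {
  expect_equal(count_cxxch("CAACH"), list(count = 1L, starts = 1L))
  expect_equal(count_cxxch("CAACHACH"), list(count = 2L, starts = c(1L, 4L)))
  expect_equal(count_cxxch("CAACA")$count, 0L)
  expect_equal(count_cxxch("")$count, 0L)
  # middle positions are unrestricted, including C and H
  expect_equal(count_cxxch("CCHCH")$count, 1L)
  # X never matches a constrained position
  expect_equal(count_cxxch("XAACH")$count, 0L)
  expect_equal(count_cxxch("CAXCH")$count, 1L)
  expect_equal(count_cxxch("CAACX")$count, 0L)
})

test_that("count_cxxch equals the brute-force scan on random proteins", {
  set.seed(42)
  for (i in 1:500) {
    p <- random_protein(sample(5:120, 1))
    got <- count_cxxch(p)
    exp_pos <- oracle_cxxch(p)
    expect_identical(got$starts, as.integer(exp_pos))
    expect_identical(got$count, length(exp_pos))
  }
})

test_that("motif count is monotone under appending residues", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_protein(sample(10:60, 1))
    longer <- paste0(p, random_protein(sample(1:10, 1)))
    expect_gte(count_cxxch(longer)$count, count_cxxch(p)$count)
  }
})

test_that("MHC calls fall on the printed 10-motif threshold", {
  p10 <- strrep("CAACH", 10)
  p9 <- strrep("CAACH", 9)
  # junctions of the repeat unit create no extra motifs (oracle-confirmed)
  expect_identical(length(oracle_cxxch(p10)), 10L)
  rec <- call_mhcs(c(a = p10, b = p9, c = "MKLVV"))
  expect_equal(rec$motif_count, c(10L, 9L, 0L))
  expect_equal(rec$is_mhc, c(TRUE, FALSE, FALSE))
  # raising the threshold never increases the number of MHCs
  for (k in c(5L, 10L, 12L, 20L)) {
    n_k <- sum(call_mhcs(c(a = p10, b = p9),
                         gp_thresholds(mhc_min_motifs = k))$is_mhc)
    n_k1 <- sum(call_mhcs(c(a = p10, b = p9),
                          gp_thresholds(mhc_min_motifs = k + 1L))$is_mhc)
    expect_lte(n_k1, n_k)
  }
})

test_that("iron-reduction prediction follows the 4-MHC threshold per bin", {
  mhc10 <- strrep("CAACH", 10)
  prot <- c(stats::setNames(rep(mhc10, 7), paste0("g", 1:7)),
            g8 = "MKLV")
  rec <- call_mhcs(prot)
  gene_bins <- data.frame(
    gene_id = paste0("g", 1:8),
    bin_id = c(rep("b4", 4), rep("b3", 3), "b3"))
  pred <- predict_iron_reducers(rec, gene_bins, bin_ids = "b0")
  pred <- pred[order(pred$bin_id), ]
  expect_equal(pred$bin_id, c("b0", "b3", "b4"))
  expect_equal(pred$n_mhcs, c(0L, 3L, 4L))
  expect_equal(pred$predicted_iron_reducer, c(FALSE, FALSE, TRUE))
  expect_equal(pred$max_motifs_single_protein, c(0L, 10L, 10L))
  # a flag is always recomputable from its own fields
  expect_equal(pred$predicted_iron_reducer, pred$n_mhcs >= 4)

  bad <- rbind(gene_bins, data.frame(gene_id = "g1", bin_id = "bX"))
  expect_error(predict_iron_reducers(rec, bad), "more than one bin")
})

test_that("predictor evaluation computes prevalence and precision", {
  mk <- function(n, flagged) data.frame(
    bin_id = paste0("b", seq_len(n)), n_mhcs = 0L,
    max_motifs_single_protein = 0L,
    predicted_iron_reducer = seq_len(n) <= flagged)
  ev <- evaluate_predictor(mk(100, 5), stats::setNames(
    c(rep(TRUE, 4), FALSE), paste0("b", 1:5)))
  expect_equal(ev$prevalence, 0.05)
  expect_equal(ev$precision, 0.80)

  ev <- evaluate_predictor(mk(3, 3), stats::setNames(rep(TRUE, 3),
                                                     paste0("b", 1:3)))
  expect_equal(ev$prevalence, 1.0)
  expect_equal(ev$precision, 1.0)

  ev <- evaluate_predictor(mk(1000, 12), stats::setNames(
    c(rep(TRUE, 11), FALSE), paste0("b", 1:12)))
  expect_equal(ev$prevalence, 0.012)
  expect_equal(round(ev$precision, 4), 0.9167)

  ev <- evaluate_predictor(mk(10, 0), c(b1 = TRUE))
  expect_true(is.na(ev$precision))
  expect_warning(
    ev <- evaluate_predictor(mk(10, 2), c(b1 = TRUE)),
    "without a label")
  expect_equal(ev$precision, 1.0)
})
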