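denit <- pathway_rule("denitrification", "nitrogen",
                      list(c("narG", "napA"), c("nirK", "nirS"),
                           "norB", "nosZ"))

test_that("pathway status follows the clause semantics", {
  expect_equal(evaluate_pathway(c("narG", "nirS", "norB", "nosZ"),
                                denit)$status, "complete")
  got <- evaluate_pathway(c("narG", "nirS", "norB"), denit)
  expect_equal(got$status, "partial")
  expect_equal(got$satisfied_clauses, 3L)
  expect_equal(evaluate_pathway(character(0), denit)$status, "absent")
  # labels outside the vocabulary are simply not consulted
  expect_equal(evaluate_pathway(c("xyzA", "qqq"), denit)$status, "absent")
})

test_that("negated clauses encode absence-defined calls", {
  pn <- pathway_rule("nitrification_partial", "nitrogen",
                     list("hao", c("amoA", "amoB")),
                     negated = c(FALSE, TRUE))
  expect_equal(evaluate_pathway("hao", pn)$status, "complete")
  expect_equal(evaluate_pathway(c("hao", "amoA"), pn)$status, "partial")
  expect_equal(evaluate_pathway(character(0), pn)$status, "absent")
  expect_equal(evaluate_pathway("amoA", pn)$status, "absent")
})

test_that("rule engine agrees with exhaustive truth-table enumeration", {
  rules <- default_pathway_rules()
  expect_true(all(vapply(rules, function(r)
    length(r$clauses) <= 4, logical(1))))
  for (r in rules) {
    vocab <- unique(unlist(r$clauses))
    # every subset of the rule's vocabulary (vocab is small by design)
    if (length(vocab) > 12) vocab <- vocab[1:12]
    for (mask in 0:(2^length(vocab) - 1)) {
      labels <- vocab[bitwAnd(mask, 2^(seq_along(vocab) - 1)) > 0]
      expect_identical(evaluate_pathway(labels, r)$status,
                       oracle_pathway_status(labels, r),
                       info = paste(r$pathway, mask))
    }
  }
})

test_that("adding genes never moves a positive rule away from complete", {
  set.seed(13)
  rules <- Filter(function(r) !any(r$negated), default_pathway_rules())
  ord <- c(absent = 0, partial = 1, complete = 2)
  vocab <- unique(unlist(lapply(rules, function(r) unlist(r$clauses))))
  for (i in 1:100) {
    base <- sample(vocab, sample(0:6, 1))
    extra <- union(base, sample(vocab, sample(1:6, 1)))
    for (r in rules)
      expect_gte(ord[evaluate_pathway(extra, r)$status],
                 ord[evaluate_pathway(base, r)$status])
  }
})

test_that("the rulebook TSV round-trips through its reader", {
  rules <- default_pathway_rules()
  expect_true(all(c("denitrification", "dnra", "wood_ljungdahl",
                    "calvin", "methanogenesis_h2", "rnf_complex",
                    "nitrification_partial", "anammox",
                    "sulfate_reduction", "sulfur_oxidation",
                    "nitrogen_fixation", "formate_dehydrogenase")
                  %in% names(rules)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tcategory\tclause_index\talternatives\tnegated",
               "demo\tnitrogen\t1\ta|b\tFALSE",
               "demo\tnitrogen\t2\tc\tTRUE"), f)
  r <- read_pathway_rules(f)$demo
  expect_equal(r$clauses, list(c("a", "b"), "c"))
  expect_equal(r$negated, c(FALSE, TRUE))
})

test_that("profile matrix keeps only bins above the rarity cutoff", {
  ab <- matrix(c(0.6, 0.3, 0.0005, 0.0995,
                 0.5, 0.4, 0.0015, 0.0985), 4, 2,
               dimnames = list(c("b1", "b2", "b3", "b4"), c("s1", "s2")))
  pc <- evaluate_pathways(list(b1 = c("narG", "nirS", "norB", "nosZ"),
                               b2 = "narG", b3 = character(0),
                               b4 = character(0)),
                          list(denitrification = denit))
  m <- build_profile_matrix(pc, ab)
  expect_equal(m$bin_id, c("b1", "b2", "b4"))  # descending mean abundance
  expect_equal(m$denitrification, c("complete", "partial", "absent"))
  expect_false("b3" %in% m$bin_id)             # mean 0.001 is not > 0.001
  zero <- ab * 0
  expect_warning(m0 <- build_profile_matrix(pc, zero), "all-zero")
  expect_equal(nrow(m0), 0)
})
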