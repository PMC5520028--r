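test_that("protein FASTA ingest uppercases, strips stops and validates ids", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "mkcaach"), f)
  expect_identical(parse_protein_fasta(f), c(g1 = "MKCAACH"))

  writeLines(c(">g1", "AAA*"), f)
  expect_identical(parse_protein_fasta(f), c(g1 = "AAA"))

  writeLines(c(">a desc", "MKLVP", ">b", "MKLVPQR"), f)
  got <- parse_protein_fasta(f)
  ora <- oracle_read_fasta(f)
  expect_length(got, 2)
  expect_identical(unname(nchar(got)), c(5L, 7L))
  expect_identical(got, toupper(ora))

  writeLines(c(">g1", "AAA", ">g1", "CCC"), f)
  expect_error(parse_protein_fasta(f), "g1")
  writeLines(c(">g1", "*", ">g2", "AAA"), f)
  expect_error(parse_protein_fasta(f), "empty")
})

test_that("FASTA write/parse round-trips a proteome", {
  prot <- generate_proteome(10, motif_counts = 0:4, seed = 3)$proteome
  f <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(prot, f)
  expect_identical(parse_protein_fasta(f), prot)
})

test_that("profile hit parsing filters by per-profile cutoff", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "g1 FeFe_GA 150 1e-30"), f)
  expect_equal(nrow(parse_profile_hits(f, c(FeFe_GA = 50))), 1)
  writeLines("g1 FeFe_GA 10 1e-3", f)
  expect_equal(nrow(parse_profile_hits(f, c(FeFe_GA = 50))), 0)

  writeLines(c("g1 FeFe_GA 150 1e-30", "g2 FeFe_GA 10 1",
               "g3 hydB 80 1e-10", "g4 hydB 12 1", "g5 narG 99 1e-20"), f)
  hits <- parse_profile_hits(f, c(FeFe_GA = 50, hydB = 50, narG = 50))
  expect_equal(nrow(hits), 3)
  # survivors all satisfy their cutoff
  cut <- c(FeFe_GA = 50, hydB = 50, narG = 50)
  expect_true(all(hits$bit_score >= cut[hits$profile]))

  writeLines("g1 mystery 99 1e-20", f)
  expect_warning(h <- parse_profile_hits(f, c(FeFe_GA = 50)), "mystery")
  expect_equal(nrow(h), 1)

  writeLines(c("g1 FeFe_GA 150 1e-30", "badrow only"), f)
  expect_error(parse_profile_hits(f), "line 2")
})

test_that("hmmsearch domain-table rows are parsed from the full dialect", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(
    "#                      --- full sequence ---",
    paste("g1 - 210 FeFe_GA - 400 1.2e-50 170.3 0.1 1 1",
          "2e-50 1.5e-48 160.0 0.1 5 390 10 200 8 205 0.95 -"),
    paste("g2 - 110 hydB - 300 3e-20 72.0 0.0 1 1",
          "4e-20 2e-18 70.0 0.0 1 100 1 100 1 100 0.90 -")), f)
  hits <- parse_profile_hits(f)
  expect_equal(hits$gene_id, c("g1", "g2"))
  expect_equal(hits$profile, c("FeFe_GA", "hydB"))
  expect_equal(hits$bit_score, c(170.3, 72.0))
  expect_equal(hits$e_value, c(1.2e-50, 3e-20))
})

test_that("coverage tables reject negatives and duplicates, default blanks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scaffold_id\ts1\ts2\ts3", "sc1\t1\t2\t3", "sc2\t4\t5\t6"), f)
  m <- parse_coverage_table(f)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(sum(m), 21)

  writeLines(c("scaffold_id\ts1\ts2", "sc1\t1\t", "sc2\t4\t5"), f)
  expect_warning(m <- parse_coverage_table(f), "missing")
  expect_equal(m["sc1", "s2"], 0)

  writeLines(c("scaffold_id\ts1", "sc1\t1", "sc1\t2"), f)
  expect_error(parse_coverage_table(f), "duplicated")

  writeLines(c("scaffold_id\ts1", "sc1\t-2"), f)
  expect_error(parse_coverage_table(f), "negative")
})

test_that("coverage write/parse round-trips doubles exactly", {
  m <- matrix(c(pi, exp(1), 1 / 3, 1e-7), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_table(m, f)
  expect_identical(parse_coverage_table(f), m)
})

test_that("GFF3 gene calls get strand-agnostic ordinals by start", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genes <- data.frame(
    gene_id = c("gB", "gA", "gC"), scaffold_id = "sc1",
    start = c(500L, 10L, 900L), end = c(700L, 300L, 980L),
    strand = c("-", "+", "+"), stringsAsFactors = FALSE)
  write_gene_calls_gff3(genes, f)
  got <- read_gene_calls(f)
  expect_equal(got$gene_id, c("gA", "gB", "gC"))
  expect_equal(got$ordinal, 1:3)
  expect_equal(got$strand, c("+", "-", "+"))
})

test_that("bin membership rejects a scaffold in two bins", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("bin_id\tscaffold_id", "b1\tsc1", "b2\tsc1"), f)
  expect_error(read_bin_membership(f), "more than one bin")
})

test_that("thresholds validate ranges and load JSON overrides", {
  th <- gp_thresholds()
  expect_equal(th$mhc_min_motifs, 10L)
  expect_equal(th$iron_min_mhcs, 4L)
  expect_equal(th$tree_min_positions, 450L)
  expect_error(gp_thresholds(gap_col_max_frac = 1.2), "fraction")
  expect_error(gp_thresholds(operon_window = 0), "count")
  expect_error(gp_thresholds(hq_min_completeness = 150), "percent")

  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"operon_window": 4, "derep_identity": 0.95}', f)
  ov <- read_thresholds_json(f)
  expect_equal(ov$operon_window, 4L)
  expect_equal(ov$derep_identity, 0.95)
  expect_equal(ov$mhc_min_motifs, 10L)
  writeLines('{"nonsense": 1}', f)
  expect_error(read_thresholds_json(f), "unknown threshold")
})
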