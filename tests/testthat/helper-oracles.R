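# Independent oracles, deliberately implemented with different algorithms
# than the package functions they check.

# position-by-position motif scan (vectorised character comparison, no regex)
oracle_cxxch <- function(protein) {
  n <- nchar(protein)
  if (n < 5) return(integer(0))
  ch <- strsplit(protein, "")[[1]]
  idx <- seq_len(n - 4L)
  idx[ch[idx] == "C" & ch[idx + 3L] == "C" & ch[idx + 4L] == "H"]
}

# truth-table clause logic for a pathway rule, written independently
oracle_pathway_status <- function(labels, rule) {
  n_sat <- 0L
  any_pos <- FALSE
  for (i in seq_along(rule$clauses)) {
    hit <- length(intersect(rule$clauses[[i]], labels)) > 0
    ok <- if (rule$negated[i]) !hit else hit
    if (ok) n_sat <- n_sat + 1L
    if (ok && !rule$negated[i]) any_pos <- TRUE
  }
  if (n_sat == length(rule$clauses)) "complete"
  else if (!any_pos) "absent"
  else "partial"
}

# naive line-by-line FASTA reader
oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ids <- c(ids, strsplit(sub("^>", "", ln), "\\s+")[[1]][1])
      seqs <- c(seqs, ""); cur <- length(seqs)
    } else seqs[cur] <- paste0(seqs[cur], ln)
  }
  names(seqs) <- ids
  seqs
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYXU", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# one shared demo community per test run (generation + full pipeline are
# the expensive steps; several acceptance checks reuse them)
.fixture_cache <- new.env(parent = emptyenv())
demo_fixture <- function(seed = 7L) {
  key <- paste0("demo_", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("gp_demo_", seed))
    t0 <- Sys.time()
    demo <- make_demo(seed = seed, outdir = dir)
    gen <- generate_community(seed = seed)
    res <- run_pipeline(list(input_dir = dir,
                             out_dir = file.path(dir, "out"),
                             seed = seed))
    .fixture_cache[[key]] <- list(
      dir = dir, truth = gen$truth, bundle = gen$bundle, result = res,
      elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  }
  .fixture_cache[[key]]
}
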