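test_that("PSSM probabilities and scores invert each other", {
  seqs <- c("ACDE", "ACDF", "ACWE")
  ps <- build_pssm(seqs, pseudocount_weight = 1)
  ## round trip: probs reconstructed from half-bit scores
  back <- ps$background
  p_back <- sweep(2^(ps$scores / 2), 2, back, "*")
  expect_lt(max(abs(p_back - ps$probs)), 1e-9)
  expect_error(build_pssm(seqs, pseudocount_weight = 0), "beta")
  ## conserved column: positive for the observed type, negative for a rare one
  uni <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  ps2 <- build_pssm(rep("A", 5), background = uni)
  expect_gt(ps2$scores[1, "A"], 0)
  expect_lt(ps2$scores[1, "W"], 0)
  expect_error(build_pssm(character(0)), "at least one")
})

test_that("PSSM exports round-trip and carry the consensus", {
  seqs <- c("ACDEFG", "ACDEFA", "ACWEFG")
  ps <- build_pssm(seqs)
  f_tsv <- tempfile(fileext = ".tsv")
  export_pssm(ps, f_tsv, "tsv")
  ps2 <- read_pssm_tsv(f_tsv)
  expect_lt(max(abs(ps2$scores - ps$scores)), 1e-6)
  expect_identical(ps2$consensus, ps$consensus)
  tab <- utils::read.table(f_tsv, header = TRUE, sep = "\t",
                           check.names = FALSE)
  expect_equal(dim(tab), c(6, 22))  # position + consensus + 20 scores
  f_ascii <- tempfile(fileext = ".pssm")
  export_pssm(ps, f_ascii, "ascii-pssm")
  expect_true(any(grepl(ps$consensus, readLines(f_ascii), fixed = TRUE)))
  f_fa <- tempfile(fileext = ".fasta")
  export_pssm(ps, f_fa, "aligned-fasta", sequences = seqs)
  expect_identical(unname(read_fasta(f_fa)), seqs)
  expect_error(export_pssm(ps, tempfile(), "xml"), "arg")
})

test_that("the consensus sequence is the top hit in its own database", {
  set.seed(2)
  fam <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "D", "E", "F"), 12, replace = TRUE),
          collapse = ""), character(1))
  ps <- build_pssm(fam)
  decoys <- vapply(1:30, function(i)
    paste(sample(AA_ALPHABET, 12, replace = TRUE), collapse = ""),
    character(1))
  db <- stats::setNames(c(ps$consensus, decoys),
                        c("consensus", sprintf("d%02d", 1:30)))
  hits <- profile_search(ps, db, e_threshold = Inf, seed = 5)
  expect_identical(hits$id[1], "consensus")
})

test_that("raising the E-value threshold never removes hits", {
  set.seed(3)
  fam <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "D"), 10, replace = TRUE), collapse = ""),
    character(1))
  ps <- build_pssm(fam)
  db <- stats::setNames(
    vapply(1:50, function(i)
      paste(sample(AA_ALPHABET, 10, replace = TRUE), collapse = ""),
      character(1)), sprintf("t%02d", 1:50))
  nf <- NULL
  prev <- character(0)
  for (t in c(0.01, 0.1, 1, 10, 1e6)) {
    h <- profile_search(ps, db, e_threshold = t, seed = 7,
                        null_fit = nf)
    nf <- attr(h, "null_fit")
    expect_true(all(prev %in% h$id))
    prev <- h$id
  }
})

test_that("profiles longer than every target return empty with a warning", {
  ps <- build_pssm(c("ACDEFGHIKL"))
  db <- c(short1 = "ACD", short2 = "WY")
  expect_warning(h <- profile_search(ps, db, seed = 1), "longer")
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "n_skipped"), 2)
})

test_that("duplicating a true homologue cannot lose it from the hit list", {
  set.seed(11)
  types <- c("A", "D", "F", "K", "S")
  cols <- peaked_columns(14, types, seed = 4)
  fam <- make_planted_msa(60, 14, background = cols, seed = 6)
  fseqs <- msa_sequences(fam$msa)
  ps <- build_pssm(fseqs[1:30])
  db <- make_search_database(fseqs[31:60], n_true = 10, n_decoys = 90,
                             seed = 8)
  h1 <- profile_search(ps, db$sequences, e_threshold = 0.1, seed = 9)
  tp1 <- intersect(h1$id, names(db$labels)[db$labels])
  db2 <- c(db$sequences, dup_true = unname(db$sequences[tp1[1]]))
  h2 <- profile_search(ps, db2, e_threshold = 0.1, seed = 9)
  expect_true(tp1[1] %in% h2$id)
  expect_gte(nrow(h2), nrow(h1))
})

test_that("pattern-subset retrieval separates planted subfamilies", {
  pats <- list(list(positions = c(3, 6, 9), types = c("F", "K", "L")),
               list(positions = c(3, 6, 9), types = c("Y", "D", "V")))
  types <- c("A", "S", "T", "E", "Q")
  cols <- peaked_columns(12, types, seed = 14)
  pl <- make_planted_msa(400, 12, background = cols,
                         subfamilies = list(weights = c(0.6, 0.4),
                                            patterns = pats),
                         seed = 15)
  seqs <- unname(msa_sequences(pl$msa))
  tp <- top_patterns(seqs, c(3, 6, 9), k = 2)
  db <- make_search_database(seqs[1:100], n_true = 40, n_decoys = 160,
                             seed = 16)
  rep_out <- pattern_retrieval_experiment(
    seqs[101:400], tp, db$sequences, db$labels,
    sample_size = 30, repeats = 2, e_threshold = 1, seed = 17)
  expect_s3_class(rep_out$per_subset, "data.frame")
  ## cumulative union dominates every single subset
  expect_gte(rep_out$cumulative["tp"], max(rep_out$per_subset$tp))
  expect_error(pattern_retrieval_experiment(seqs, tp[0, ],
                                            db$sequences, db$labels),
               "empty pattern")
})
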