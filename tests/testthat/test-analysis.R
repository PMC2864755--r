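test_that("identity scores match hand counts and reject length mismatch", {
  expect_equal(identity_score("ACDE", "ACDE"), 100)
  expect_equal(identity_score("ACDE", "WYFH"), 0)
  expect_equal(identity_score("ACDE", "ACDF"), 75)
  expect_error(identity_score("ACD", "ACDE"), "mismatch")
})

test_that("similarity against a single-sequence MSA is the pairwise BLOSUM sum", {
  b <- blosum62_matrix()
  m1 <- msa("AC")
  expect_equal(similarity_score("AC", m1)$score,
               b["A", "A"] + b["C", "C"])
  expect_equal(similarity_score("AC", m1)$score, 4 + 9)
  ## general linearity: matches an independent pairwise scorer
  set.seed(3)
  seqs <- vapply(1:6, function(i)
    paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = ""),
    character(1))
  q <- paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = "")
  prof_score <- similarity_score(q, msa(seqs))$score
  pair_mean <- mean(vapply(seqs, function(s) {
    sum(b[cbind(strsplit(q, "")[[1]], strsplit(s, "")[[1]])])
  }, numeric(1)))
  expect_equal(prof_score, pair_mean, tolerance = 1e-9)
})

test_that("gap columns contribute the gap score and mixed columns average", {
  m_gap <- msa(c("-A", "-A"))
  ps <- similarity_score("AA", m_gap)$per_column
  expect_equal(ps[1], -5)
  m_av <- msa(c("AA", "VA"))
  expect_equal(similarity_score("AA", m_av)$per_column[1],
               0.5 * 4 + 0.5 * 0)  # B(A,A)=4, B(A,V)=0
  expect_error(similarity_score("AAA", m_av), "columns")
})

test_that("the NCBI matrix text format parses back to BLOSUM62", {
  b <- blosum62_matrix()
  f <- tempfile()
  hdr <- paste(c("", AA_ALPHABET), collapse = " ")
  rows <- vapply(AA_ALPHABET, function(a)
    paste(c(a, b[a, AA_ALPHABET]), collapse = " "), character(1))
  writeLines(c("# test matrix", hdr, rows), f)
  b2 <- read_substitution_matrix(f)
  expect_equal(b2, b)
})

test_that("score overlap covers its boundary cases", {
  expect_equal(score_overlap(c(5, 6, 7), c(1, 2)), 100)
  expect_equal(score_overlap(c(-5, -6), c(1, 2)), 0)
  expect_equal(score_overlap(c(1, 2, 3), c(2, 9)), 100 * 2 / 3,
               tolerance = 1e-9)
  expect_equal(score_overlap(c(1, 2), c(1, 2), method = "coefficient"),
               100)
})

test_that("reduced alphabets partition the 20 types as published", {
  nine <- reduced_alphabet("nine")
  six <- reduced_alphabet("six")
  expect_setequal(attr(nine, "classes"),
                  c("LVIMC", "FY", "W", "G", "A", "STP", "EDNQ",
                    "KR", "H"))
  expect_setequal(attr(six, "classes"),
                  c("LVIMC", "FYW", "G", "ASTP", "EDNQ", "KRH"))
  for (ab in list(nine, six)) {
    expect_setequal(unique(unlist(strsplit(attr(ab, "classes"), ""))),
                    AA_ALPHABET)
    expect_equal(sum(nchar(attr(ab, "classes"))), 20)
  }
  expect_identical(nine[["F"]], nine[["Y"]])
  expect_false(nine[["F"]] == nine[["W"]])
})

test_that("positional entropies hit their closed forms and bounds", {
  nine <- reduced_alphabet("nine")
  ## conserved column
  e1 <- positional_entropy(rep("A", 50), nine)
  expect_equal(e1$expS[1], 1)
  ## uniform over the nine classes: one representative per class
  reps <- c("L", "F", "W", "G", "A", "S", "E", "K", "H")
  e9 <- positional_entropy(reps, nine)
  expect_equal(e9$expS[1], 9, tolerance = 1e-12)
  ## F/Y merge within one class
  efy <- positional_entropy(c("F", "Y", "F", "Y"), nine)
  expect_equal(efy$expS[1], 1)
  ## but two classes under the identity alphabet
  e20 <- positional_entropy(c("F", "Y", "F", "Y"),
                            reduced_alphabet("identity20"))
  expect_equal(e20$expS[1], 2, tolerance = 1e-12)
  ## bounds on random alignments; all-gap columns are flagged
  set.seed(9)
  seqs <- vapply(1:30, function(i)
    paste(c(sample(AA_ALPHABET, 5, replace = TRUE), "-"),
          collapse = ""), character(1))
  e <- positional_entropy(seqs, nine)
  expect_true(all(e$expS[1:5] >= 1 - 1e-12 & e$expS[1:5] <= 9 + 1e-12))
  expect_identical(e$excluded, 6L)
})

test_that("mutual information matches closed forms and coarsening monotonicity", {
  ## perfectly coupled equiprobable binary columns
  coupled <- c(rep("AK", 250), rep("VE", 250))
  mi <- mutual_information_matrix(coupled)
  expect_equal(mi[1, 2], log(2), tolerance = 1e-12)
  expect_identical(mi[1, 2], mi[2, 1])
  expect_equal(mi[1, 1], log(2), tolerance = 1e-12)  # diagonal = entropy
  ## independent columns: MI near zero at large n
  set.seed(21)
  ind <- vapply(1:2000, function(i)
    paste(sample(c("A", "V"), 2, replace = TRUE), collapse = ""),
    character(1))
  expect_lt(mutual_information_matrix(ind)[1, 2], 0.01)
  ## data processing: 6-class <= 9-class <= 20-class, pairwise
  set.seed(22)
  seqs <- vapply(1:80, function(i)
    paste(sample(AA_ALPHABET, 6, replace = TRUE), collapse = ""),
    character(1))
  m6 <- mutual_information_matrix(seqs, reduced_alphabet("six"))
  m9 <- mutual_information_matrix(seqs, reduced_alphabet("nine"))
  m20 <- mutual_information_matrix(seqs, reduced_alphabet("identity20"))
  off <- upper.tri(m6)
  expect_true(all(m6[off] <= m9[off] + 1e-9))
  expect_true(all(m9[off] <= m20[off] + 1e-9))
  expect_true(all(m9[off] >= -1e-12))
})

test_that("pattern extraction recovers planted subfamilies and partitions", {
  pats <- list(list(positions = c(2, 4, 6), types = c("F", "K", "L")),
               list(positions = c(2, 4, 6), types = c("Y", "D", "V")))
  pl <- make_planted_msa(1000, 8,
                         subfamilies = list(weights = c(0.6, 0.4),
                                            patterns = pats),
                         seed = 31)
  tp <- top_patterns(pl$msa, c(2, 4, 6), k = 2)
  expect_equal(tp$pattern[1], "FY/KR/LVIMC")
  expect_equal(tp$pattern[2], "FY/EDNQ/LVIMC")
  expect_lt(abs(tp$frequency[1] - 0.6), 0.05)
  expect_lt(abs(tp$frequency[2] - 0.4), 0.05)
  ## single sequence: one pattern at frequency 1
  t1 <- top_patterns("AVSD", c(1, 3), k = 5)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$frequency, 1)
  ## frequencies over all patterns sum to 1
  t_all <- top_patterns(pl$msa, c(2, 4, 6), k = 1000)
  expect_equal(sum(t_all$frequency), 1, tolerance = 1e-12)
  expect_error(top_patterns(pl$msa, c(2, 4), k = 0), "positive")
  ## subsets: size consistency, disjointness, partition
  seqs <- msa_sequences(pl$msa)
  s1 <- subset_by_pattern(seqs, tp$pattern[1], c(2, 4, 6))
  expect_equal(sum(s1), tp$count[1])
  s2 <- subset_by_pattern(seqs, tp$pattern[2], c(2, 4, 6))
  expect_equal(sum(s1 & s2), 0)
  none <- subset_by_pattern(seqs, NULL, c(2, 4, 6),
                            complement_of = t_all$pattern)
  expect_equal(sum(s1) + sum(s2) + sum(none) +
               sum(!(s1 | s2 | none)), length(seqs))
})

test_that("core positions are the buried ones in a packed fixture", {
  fx <- fix_helix()
  core <- core_positions(fx$template, threshold = 0.9)
  expect_true(all(core %in% fx$template$positions$index))
  core_strict <- core_positions(fx$template, threshold = 0.05)
  expect_lte(length(core_strict), length(core))
})

test_that("aligned FASTA round-trips through the MSA container", {
  seqs <- c(a = "AC-DE", b = "ACWDE", c = "AC-DF")
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  m <- read_msa(f)
  expect_identical(unname(msa_sequences(m)), unname(seqs))
  expect_identical(m$ids, names(seqs))
  expect_equal(msa_length(m), 5)
  expect_error(msa(c("AC", "ACD")), "equal lengths")
  prof <- msa_profile(m)
  expect_equal(rowSums(prof), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(prof[3, "-"]), 2 / 3, tolerance = 1e-12)
})
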