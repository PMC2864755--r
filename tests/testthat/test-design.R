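test_that("a one-position system is solved exactly in one cycle", {
  em <- random_energy_matrix(1, c("A", "S", "V"), 2, seed = 3)
  r <- heuristic_cycle(em, design_config(seed = 1))
  expect_equal(r$dg_fold, enumerate_gmec(em)$energy, tolerance = 1e-12)
})

test_that("cycle energies never increase along the sweep trajectory", {
  for (s in 1:10) {
    em <- random_energy_matrix(4, c("A", "S", "V"), 2, seed = 100 + s)
    keys <- as.character(em$positions)
    ns <- vapply(em$states[keys], nrow, integer(1))
    set.seed(s)
    a <- vapply(ns, function(n) sample.int(n, 1), integer(1))
    e <- designkit:::matrix_total(em, a)
    for (pass in 1:5) {
      a <- designkit:::sweep_once(em, a,
             designkit:::allowed_states(em))
      e2 <- designkit:::matrix_total(em, a)
      expect_lte(e2, e + 1e-12)
      e <- e2
    }
  }
})

test_that("ensembles are deterministic, sorted, and capped at select_k", {
  em <- random_energy_matrix(4, c("A", "S", "V"), 2, seed = 7)
  cfg <- design_config(n_cycles = 40, seed = 13, select_k = 10)
  e1 <- run_design(em, cfg)
  e2 <- run_design(em, cfg)
  expect_identical(e1$records, e2$records)
  expect_equal(nrow(e1$records), 10)
  expect_false(is.unsorted(e1$records$dg_fold))
  ## select_k >= n_cycles keeps everything
  e3 <- run_design(em, design_config(n_cycles = 15, seed = 13,
                                     select_k = 50))
  expect_equal(nrow(e3$records), 15)
  ## best-so-far is monotone in the number of cycles (nested seeds)
  e_small <- run_design(em, design_config(n_cycles = 10, seed = 13,
                                          select_k = 10))
  expect_gte(e_small$records$dg_fold[1], e1$records$dg_fold[1] - 1e-12)
})

test_that("every record's energy is reproducible from the matrix", {
  em <- random_energy_matrix(4, c("A", "S", "V"), 2, seed = 9)
  ens <- run_design(em, design_config(n_cycles = 20, seed = 3))
  for (r in sample(nrow(ens$records), 5)) {
    rot <- as.integer(strsplit(ens$records$rotamers[r], ",")[[1]])
    sq <- strsplit(ens$records$sequence[r], "")[[1]]
    keys <- as.character(em$positions)
    a <- vapply(seq_along(keys), function(ii) {
      st <- em$states[[keys[ii]]]
      which(st$aa == sq[ii] & st$rot == rot[ii])[1]
    }, integer(1))
    expect_lt(abs(fold_free_energy(em, a)$total -
                  ens$records$dg_fold[r]), 1e-6)
  }
})

test_that("restrained optimization is dominated by unrestrained optimization", {
  ab <- reduced_alphabet("nine")
  for (s in 1:5) {
    em <- random_energy_matrix(4, c("F", "Y", "W", "S", "T"), 2,
                               seed = 300 + s)
    free <- heuristic_cycle(em, design_config(seed = s))
    res <- restrained_cycle(em, free$assignment,
                            design_config(seed = s), ab)
    expect_gte(res$dg_fold, enumerate_gmec(em)$energy - 1e-12)
    ## a Phe start may visit Tyr but never Trp
    keys <- as.character(em$positions)
    st1 <- em$states[[keys[1]]]
    start <- free$assignment
    start[1] <- which(st1$aa == "F")[1]
    r2 <- restrained_cycle(em, start, design_config(seed = s), ab)
    aa1 <- st1$aa[r2$assignment[1]]
    expect_true(aa1 %in% c("F", "Y"))
  }
})

test_that("frozen positions and overrides never mutate in any output", {
  fx <- fix_strand_g()  # Gly at position 4
  em <- fix_matrix_small()
  ens <- run_design(em, design_config(n_cycles = 25, seed = 4))
  expect_true(all(substr(ens$records$sequence, 4, 4) == "G"))
  cfg <- design_config(n_cycles = 10, seed = 4,
                       frozen_overrides = list("2" = "V"))
  ens2 <- run_design(em, cfg)
  expect_true(all(substr(ens2$records$sequence, 2, 2) == "V"))
})

test_that("rotamer-only optimization keeps types fixed and beats random rotamers", {
  em <- fix_matrix_small()
  sq <- "SVAGSV"
  r <- rotamer_only_optimize(em, sq, design_config(seed = 2))
  expect_identical(r$sequence, sq)
  keys <- as.character(em$positions)
  set.seed(8)
  for (t in 1:20) {
    a <- vapply(seq_along(keys), function(ii) {
      st <- em$states[[keys[ii]]]
      cand <- which(st$aa == substr(sq, ii, ii))
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    expect_lte(r$dg_fold, fold_free_energy(em, a)$total + 1e-9)
  }
  expect_error(rotamer_only_optimize(em, "WWWGWW"), "not available")
})

test_that("profile sampling preserves marginals and destroys correlations", {
  ## delta columns: always the consensus
  prof <- matrix(0, 3, 21, dimnames = list(NULL, c(AA_ALPHABET, "-")))
  prof[1, "A"] <- 1; prof[2, "V"] <- 1; prof[3, "S"] <- 1
  expect_true(all(sample_from_profile(prof, 5, seed = 1) == "AVS"))
  ## frequencies within multinomial 3-sigma bands
  p2 <- matrix(0, 2, 21, dimnames = list(NULL, c(AA_ALPHABET, "-")))
  p2[1, c("A", "V")] <- c(0.7, 0.3)
  p2[2, c("S", "T", "D")] <- c(0.5, 0.3, 0.2)
  s <- sample_from_profile(p2, 10000, seed = 5)
  fA <- mean(substr(s, 1, 1) == "A")
  expect_lt(abs(fA - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  ## an anti-correlated source loses its coupling when resampled
  set.seed(7)
  coupled <- ifelse(stats::runif(500) < 0.5, "AK", "VE")
  mi_src <- mutual_information_matrix(coupled)[1, 2]
  prof_c <- msa_profile(coupled)
  resamp <- sample_from_profile(prof_c, 500, seed = 6)
  mi_new <- mutual_information_matrix(resamp)[1, 2]
  expect_gt(mi_src, 0.6)
  expect_lt(mi_new, 0.05)
  ## gap mass is redistributed; an all-gap column errors
  pg <- matrix(0, 1, 21, dimnames = list(NULL, c(AA_ALPHABET, "-")))
  pg[1, "-"] <- 1
  expect_error(sample_from_profile(pg, 3, seed = 1), "no residue mass")
})

test_that("random-identity batches hit their target and keep preserved positions", {
  fx <- fix_helix()
  tpl <- fx$template
  expect_true(all(random_identity_sequences(tpl, 100, 5, seed = 1) ==
                  template_sequence(tpl)))
  tpl40 <- make_structure("helix", 40, seed = 12)$template
  s55 <- random_identity_sequences(tpl40, 55, 500, seed = 2)
  ids <- vapply(s55, identity_score, numeric(1),
                seq_b = template_sequence(tpl40), USE.NAMES = FALSE)
  expect_lt(abs(mean(ids) - 55), 2)
  s_pres <- random_identity_sequences(tpl, 50, 200, seed = 3,
                                      preserve = c(2, 5))
  expect_true(all(substr(s_pres, 2, 2) == "S"))
  expect_true(all(substr(s_pres, 5, 5) == "K"))
  expect_error(random_identity_sequences(tpl, 5, 10, seed = 1,
                                         preserve = 1:6), "below")
})

test_that("identity-vs-energy binning conserves counts and finds planted trends", {
  em <- random_energy_matrix(4, c("A", "S", "V"), 2, seed = 44)
  ens <- run_design(em, design_config(n_cycles = 30, seed = 2))
  tab <- identity_vs_energy(ens, ens$records$sequence[1])
  expect_equal(sum(tab$n), nrow(ens$records))
  one <- ens; one$records <- ens$records[1, ]
  expect_equal(nrow(identity_vs_energy(one, "AAAA")), 1)
  ## planted: identity rises as energy falls
  ref <- "AAAAAAAAAA"
  n <- 200
  recs <- data.frame(
    sequence = vapply(seq_len(n), function(i) {
      k <- round(9 * (i - 1) / (n - 1))  # mutations grow with index
      v <- rep("A", 10); if (k > 0) v[seq_len(k)] <- "V"
      paste(v, collapse = "")
    }, character(1)),
    dg_fold = seq(-100, 100, length.out = n))
  tab2 <- identity_vs_energy(recs, ref)
  fit <- stats::lm(mean_identity ~ bin_lo, tab2)
  expect_lt(unname(stats::coef(fit)[2]), 0)
})
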