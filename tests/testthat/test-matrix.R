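test_that("matrix-reconstructed energies equal direct whole-system evaluation", {
  fx <- fix_strand_g()
  em <- fix_matrix_small()
  model <- fix_model_rigid()
  keys <- as.character(em$positions)
  ns <- vapply(em$states[keys], nrow, integer(1))
  set.seed(11)
  for (t in 1:10) {
    a <- vapply(ns, function(n) sample.int(n, 1), integer(1))
    fm <- fold_free_energy(em, a)
    fd <- direct_fold_energy(fx$template, em, a, model)
    expect_lt(abs(fm$total - fd$total), 1e-3)
    expect_lt(abs(fm$vdw - fd$vdw), 1e-3)
    expect_lt(abs(fm$coulomb - fd$coulomb), 1e-3)
    expect_lt(abs(fm$surface - fd$surface), 1e-3)
  }
})

test_that("fold energy breakdown is internally consistent on every evaluation", {
  em <- fix_matrix_small()
  keys <- as.character(em$positions)
  ns <- vapply(em$states[keys], nrow, integer(1))
  set.seed(5)
  for (t in 1:25) {
    a <- vapply(ns, function(n) sample.int(n, 1), integer(1))
    bd <- fold_free_energy(em, a)
    expect_lt(abs(bd$total -
                  (bd$vdw + bd$coulomb + bd$surface - bd$unfolded)),
              1e-6)
    expect_equal(bd$per_residue, bd$total / length(ns))
  }
})

test_that("pair blocks are symmetric and respect the cutoff", {
  em <- fix_matrix_small()
  ## symmetry: the (i,j) block transposed equals the (j,i) view
  b_ij <- designkit:::pair_block(em, 1, 2)
  b_ji <- designkit:::pair_block(em, 2, 1)
  expect_identical(t(b_ij), b_ji)
  ## tight cutoff removes far pairs but leaves near entries unchanged
  fx <- fix_strand_g()
  em_cut <- build_energy_matrix(fx$template,
                                builtin_rotamer_library(),
                                energy_model(pair_min_steps = 0,
                                             cutoff = 8),
                                allowed_types = c("A", "S", "V"))
  expect_lt(length(em_cut$pair), length(em$pair))
  for (k in names(em_cut$pair))
    expect_equal(em_cut$pair[[k]], em$pair[[k]], tolerance = 1e-12)
  ## beyond-cutoff pair interaction is identically zero
  e_far <- pair_interaction_energy(fx$template, 1, "S", 1, 6, "S", 1,
                                   energy_model(pair_min_steps = 0,
                                                cutoff = 1))
  expect_identical(unname(e_far), c(0, 0, 0))
})

test_that("rigid pair interaction matches the stored matrix entries", {
  fx <- fix_strand_g()
  em <- fix_matrix_small()
  model <- fix_model_rigid()
  st1 <- em$states[["1"]]
  s_v <- which(st1$aa == "V")[2]
  st2 <- em$states[["2"]]
  s_s <- which(st2$aa == "S")[1]
  direct <- pair_interaction_energy(fx$template,
                                    1, st1$aa[s_v], st1$rot[s_v],
                                    2, st2$aa[s_s], st2$rot[s_s],
                                    model)
  stored <- em$pair[["1|2"]][s_v, s_s, ]
  expect_equal(unname(direct), unname(stored), tolerance = 1e-9)
})

test_that("relaxation lowers or keeps pair energies finite and flags none spuriously", {
  fx <- fix_strand_g()
  model_rlx <- energy_model(pair_min_steps = 5, cutoff = 1e6)
  e_rigid <- pair_interaction_energy(fx$template, 2, "V", 1, 3, "V", 1,
                                     fix_model_rigid())
  e_rlx <- pair_interaction_energy(fx$template, 2, "V", 1, 3, "V", 1,
                                   model_rlx)
  expect_true(all(is.finite(e_rlx)))
  ## far-apart Ala pair: every component negligible either way
  e_far <- pair_interaction_energy(fx$template, 1, "A", 1, 6, "A", 1,
                                   fix_model_rigid())
  expect_lt(max(abs(e_far)), 1e-3)
  expect_true(is.numeric(e_rigid))
})

test_that("matrix serialization round-trips states, energies and totals", {
  em <- fix_matrix_small()
  f <- tempfile(fileext = ".json")
  write_energy_matrix(em, f)
  em2 <- read_energy_matrix(f)
  expect_equal(em2$positions, em$positions)
  expect_equal(em2$const, em$const, tolerance = 1e-12)
  for (k in names(em$sing))
    expect_equal(em2$sing[[k]], em$sing[[k]], tolerance = 1e-12)
  for (k in names(em$pair))
    expect_equal(em2$pair[[k]], em$pair[[k]], tolerance = 1e-12)
  a <- rep(1L, length(em$positions))
  expect_equal(fold_free_energy(em2, a)$total,
               fold_free_energy(em, a)$total, tolerance = 1e-9)
})

test_that("unknown states and mismatched assignments are rejected", {
  em <- fix_matrix_small()
  expect_error(fold_free_energy(em, rep(1L, 2)), "length")
  expect_error(fold_free_energy(em, c(999L, rep(1L, 5))), "not in matrix")
  expect_error(build_energy_matrix(fix_strand_g()$template,
                                   allowed_types = c("A", "G")),
               "frozen types")
})
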