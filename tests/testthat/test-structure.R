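test_that("chi angles round-trip through placement for every library rotamer", {
  fx <- fix_helix()
  lib <- builtin_rotamer_library()
  tpl <- fx$template
  n <- bb_coord(tpl, 3, "N"); ca <- bb_coord(tpl, 3, "CA")
  cc <- bb_coord(tpl, 3, "C")
  for (aa in setdiff(AA_DESIGNABLE, "A")) {
    for (r in seq_len(nrow(lib[[aa]]))) {
      sc <- place_rotamer(tpl, 3, aa, r, lib)
      ch <- sidechain_chis(aa, sc, n, ca, cc)
      expect_lt(max(abs(wrap_angle(ch - rotamer_chis(lib, aa, r)))),
                1e-6)
    }
  }
})

test_that("Ala placement yields CB only (no chi) and an L-configured CA", {
  tpl <- fix_helix()$template
  sc <- place_rotamer(tpl, 2, "A", numeric(0))
  expect_identical(sc$name, "CB")
  cb <- c(sc$x[1], sc$y[1], sc$z[1])
  dih <- measure_dihedral(bb_coord(tpl, 2, "C"), bb_coord(tpl, 2, "N"),
                          bb_coord(tpl, 2, "CA"), cb)
  expect_equal(dih, 122.5, tolerance = 1e-6)
})

test_that("PDB write/read round-trips sequence and coordinates", {
  fx <- fix_helix()
  tpl2 <- read_pdb(fx$path)
  expect_identical(template_sequence(tpl2), "ASLVKDEF")
  ## backbone coordinates are carried verbatim: PDB fixed-width
  ## precision only
  b1 <- fx$template$bb_atoms
  b2 <- tpl2$bb_atoms
  m <- match(paste(b1$resno, b1$name), paste(b2$resno, b2$name))
  expect_lt(max(abs(b1$x - b2$x[m]), abs(b1$y - b2$y[m]),
                abs(b1$z - b2$z[m])), 1e-3)
  ## designable side chains live as measured chi angles
  for (p in names(fx$template$native_chis))
    expect_lt(max(abs(wrap_angle(tpl2$native_chis[[p]] -
                                 fx$template$native_chis[[p]]))), 0.2)
  ## rebuilt side chains agree to well under the rotamer scale
  a1 <- assemble_atoms(fx$template, parameters = NULL)
  a2 <- assemble_atoms(tpl2, parameters = NULL)
  expect_lt(max(abs(a1$x - a2$x), abs(a1$y - a2$y), abs(a1$z - a2$z)),
            2e-2)
  ## a second write/read cycle is stable at PDB precision
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(tpl2, f2)
  tpl3 <- read_pdb(f2)
  b3 <- tpl3$bb_atoms
  m3 <- match(paste(b2$resno, b2$name), paste(b3$resno, b3$name))
  expect_lt(max(abs(b2$x - b3$x[m3])), 2e-3)
})

test_that("native side chains rebuilt from measured chis stay close", {
  fx <- fix_helix()
  tpl <- read_pdb(fx$path)
  for (p in c(3, 5, 6)) {  # L, K, D
    aa <- tpl$positions$native[p]
    ch <- tpl$native_chis[[as.character(p)]]
    sc <- place_rotamer(tpl, p, aa, ch)
    orig <- assemble_atoms(fx$template, parameters = NULL)
    orig <- orig[orig$resno == p & orig$group == "sc", ]
    heavy <- sc$element != "H"
    m <- match(sc$name[heavy], orig$name)
    rmsd <- sqrt(mean((sc$x[heavy] - orig$x[m])^2 +
                      (sc$y[heavy] - orig$y[m])^2 +
                      (sc$z[heavy] - orig$z[m])^2))
    expect_lt(rmsd, 0.5)
  }
})

test_that("Cys/Gly/Pro positions are frozen and never designable", {
  tpl <- fix_strand_g()$template
  expect_false(tpl$positions$designable[4])  # the Gly
  expect_true(all(tpl$positions$designable[-4]))
  expect_length(intersect(which(tpl$positions$designable),
                          which(tpl$positions$native %in% c("C", "G", "P"))),
                0)
  fx2 <- make_structure("helix", 5, sequence = "ACPGA", seed = 4)
  tplf <- read_pdb(fx2$path)
  expect_identical(which(tplf$positions$designable), c(1L, 5L))
  ## frozen side chains carried at input coordinates
  expect_true(all(c("2", "3") %in% names(tplf$frozen)))
  expect_error(place_rotamer(tplf, 2, "S", c(60)), "frozen")
  expect_error(place_rotamer(tplf, 1, "G", numeric(0)), "not allowed")
})

test_that("degenerate PDB inputs fail loudly with the residue named", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   2       3.300   2.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_pdb(f), "ALA 2")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   XXX A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), f2)
  expect_error(read_pdb(f2), "unknown residue")
})

test_that("rotamer libraries load, validate, and fail with line numbers", {
  lib <- builtin_rotamer_library()
  expect_equal(nrow(lib$L), 9)    # 3 x 3 grid over chi1, chi2
  expect_equal(nrow(lib$K), 81)   # 3^4
  expect_equal(nrow(lib$A), 1)    # chi-less
  f <- tempfile(fileext = ".tsv")
  writeLines(c("aa_type\tchi1\tchi2\tchi3\tchi4",
               "S\t-60\t\t\t", "S\t60\t\t\t", "S\t180\t\t\t"), f)
  lib2 <- load_rotamer_library(f)
  expect_equal(nrow(lib2$S), 3)
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("aa_type\tchi1\tchi2\tchi3\tchi4",
               "S\t-60\t\t\t", "S\t720\t\t\t"), f3)
  expect_error(load_rotamer_library(f3), "line 3")
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("aa_type\tchi1\tchi2\tchi3\tchi4", "L\t-60\t\t\t"), f4)
  expect_error(load_rotamer_library(f4), "needs 2 chi")
})

test_that("the parameter set resolves every placeable atom exactly once", {
  params <- default_parameters()
  expect_false(anyDuplicated(paste(params$aa, params$atom)) > 0)
  expect_true(all(params$lj_epsilon >= 0))
  expect_true(all(params$radius > 0))
  expect_true(all(params$class %in% names(SOLVATION_SIGMA)))
  expect_equal(unname(params$sigma_solv[params$class == "carbon_sulfur"][1]),
               0.012)
  expect_equal(unname(params$sigma_solv[params$class == "ionized"][1]),
               -0.15)
  ## every topology atom resolves
  for (aa in AA_ALPHABET) {
    nms <- c("N", if (aa != "P") "H", "CA", "C", "O",
             sidechain_atom_names(aa))
    atoms <- data.frame(aa = aa, name = nms, stringsAsFactors = FALSE)
    expect_silent(assign_parameters(atoms, params))
  }
  ## net side-chain charges are integral
  for (aa in AA_ALPHABET) {
    q <- sum(params$charge[params$aa == aa])
    expq <- if (aa %in% c("D", "E")) -1 else if (aa %in% c("K", "R")) 1
            else 0
    expect_equal(q, expq, tolerance = 1e-9)
  }
  ## TSV round trip
  f <- tempfile(fileext = ".tsv")
  write_parameters(params, f)
  p2 <- load_parameters(f)
  expect_equal(as.data.frame(p2), as.data.frame(params),
               ignore_attr = TRUE)
})
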