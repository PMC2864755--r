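## Residue topologies: united-atom (polar-hydrogen) side-chain
## definitions with ideal internal coordinates, chi dihedral
## definitions, partial charges and solvation atom classes.
##
## Convention: each side-chain atom is placed by NeRF from three
## reference atoms -- bond to `parent`, bond angle `aref`-`parent`-atom
## and dihedral `dref`-`aref`-`parent`-atom.  Dihedrals are either
## fixed (chi = 0) or chi-driven: dihedral = chi_k + offset.
## Aliphatic carbons are extended (united) atoms; only polar hydrogens
## (O-H, N-H, S-H) are explicit.  Ideal bond lengths and angles are
## canonical values; the backbone is always held fixed so they are
## never varied.

sc_row <- function(name, el, parent, aref, dref, bond, angle, chi, dih,
                   charge = 0, cls = NA_character_) {
  data.frame(name = name, element = el, parent = parent, aref = aref,
             dref = dref, bond = bond, angle = angle, chi = as.integer(chi),
             dih = dih, charge = charge, cls = cls,
             stringsAsFactors = FALSE)
}

## dihedral C-N-CA-CB that yields an L-amino acid
CB_DIH <- 122.5

cb_row <- function(charge = 0)
  sc_row("CB", "C", "CA", "N", "C", 1.53, 110.5, 0, CB_DIH, charge)

sidechain_defs <- function() {
  d <- list()
  d$A <- cb_row()
  d$S <- rbind(cb_row(0.25),
    sc_row("OG", "O", "CB", "CA", "N", 1.417, 110.8, 1, 0, -0.65),
    sc_row("HG", "H", "OG", "CB", "CA", 0.96, 109.5, 0, 180, 0.40))
  d$T <- rbind(cb_row(0.25),
    sc_row("OG1", "O", "CB", "CA", "N", 1.43, 109.6, 1, 0, -0.65),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1, -120, 0),
    sc_row("HG1", "H", "OG1", "CB", "CA", 0.96, 109.5, 0, 180, 0.40))
  d$C <- rbind(cb_row(0.10),
    sc_row("SG", "S", "CB", "CA", "N", 1.808, 113.8, 1, 0, -0.45),
    sc_row("HG", "H", "SG", "CB", "CA", 1.33, 96.0, 0, 180, 0.35))
  d$V <- rbind(cb_row(),
    sc_row("CG1", "C", "CB", "CA", "N", 1.52, 110.5, 1, 0),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1, 122))
  d$L <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.53, 116.3, 1, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.52, 110.7, 2, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.52, 110.7, 2, 122))
  d$I <- rbind(cb_row(),
    sc_row("CG1", "C", "CB", "CA", "N", 1.53, 110.4, 1, 0),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1, -122),
    sc_row("CD1", "C", "CG1", "CB", "CA", 1.52, 113.8, 2, 0))
  d$M <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1, 0, 0.06),
    sc_row("SD", "S", "CG", "CB", "CA", 1.803, 112.7, 2, 0, -0.12),
    sc_row("CE", "C", "SD", "CG", "CB", 1.791, 100.9, 3, 0, 0.06))
  d$F <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.50, 113.8, 1, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, 2, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, 2, 180),
    sc_row("CE1", "C", "CD1", "CG", "CB", 1.39, 120.8, 0, 180),
    sc_row("CE2", "C", "CD2", "CG", "CB", 1.39, 120.8, 0, 180),
    sc_row("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, 0, 0))
  d$Y <- rbind(d$F,
    sc_row("OH", "O", "CZ", "CE1", "CD1", 1.38, 119.9, 0, 180, -0.65),
    sc_row("HH", "H", "OH", "CZ", "CE1", 0.96, 109.5, 0, 0, 0.40))
  d$Y[d$Y$name == "CZ", "charge"] <- 0.25
  d$W <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.50, 113.6, 1, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.37, 126.9, 2, 0, 0.06),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.43, 126.8, 2, 180),
    sc_row("NE1", "N", "CD1", "CG", "CB", 1.38, 110.2, 0, 180, -0.36),
    sc_row("CE2", "C", "CD2", "CG", "CB", 1.41, 107.2, 0, 180),
    sc_row("CE3", "C", "CD2", "CG", "CB", 1.40, 133.9, 0, 0),
    sc_row("CZ2", "C", "CE2", "CD2", "CG", 1.40, 122.4, 0, 180),
    sc_row("CZ3", "C", "CE3", "CD2", "CG", 1.39, 118.7, 0, 180),
    sc_row("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117.5, 0, 0),
    sc_row("HE1", "H", "NE1", "CD1", "CG", 1.00, 125.0, 0, 180, 0.30))
  d$H <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.50, 113.8, 1, 0, 0.30),
    sc_row("ND1", "N", "CG", "CB", "CA", 1.38, 122.7, 2, 0, -0.40),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.36, 131.0, 2, 180, 0.10),
    sc_row("CE1", "C", "ND1", "CG", "CB", 1.32, 109.3, 0, 180, 0.10),
    sc_row("NE2", "N", "CD2", "CG", "CB", 1.37, 107.2, 0, 180, -0.40),
    sc_row("HD1", "H", "ND1", "CG", "CD2", 1.00, 126.0, 0, 180, 0.30))
  d$D <- rbind(cb_row(-0.16),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 112.6, 1, 0, 0.36),
    sc_row("OD1", "O", "CG", "CB", "CA", 1.25, 118.4, 2, 0, -0.60, "ionized"),
    sc_row("OD2", "O", "CG", "CB", "CA", 1.25, 118.4, 2, 180, -0.60, "ionized"))
  d$N <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 112.7, 1, 0, 0.55),
    sc_row("OD1", "O", "CG", "CB", "CA", 1.23, 120.8, 2, 0, -0.55),
    sc_row("ND2", "N", "CG", "CB", "CA", 1.33, 116.4, 2, 180, -0.60),
    sc_row("HD21", "H", "ND2", "CG", "CB", 1.00, 120.0, 0, 0, 0.30),
    sc_row("HD22", "H", "ND2", "CG", "CB", 1.00, 120.0, 0, 180, 0.30))
  d$E <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1, 0, -0.16),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 112.6, 2, 0, 0.36),
    sc_row("OE1", "O", "CD", "CG", "CB", 1.25, 118.4, 3, 0, -0.60, "ionized"),
    sc_row("OE2", "O", "CD", "CG", "CB", 1.25, 118.4, 3, 180, -0.60, "ionized"))
  d$Q <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 112.7, 2, 0, 0.55),
    sc_row("OE1", "O", "CD", "CG", "CB", 1.23, 120.8, 3, 0, -0.55),
    sc_row("NE2", "N", "CD", "CG", "CB", 1.33, 116.4, 3, 180, -0.60),
    sc_row("HE21", "H", "NE2", "CD", "CG", 1.00, 120.0, 0, 0, 0.30),
    sc_row("HE22", "H", "NE2", "CD", "CG", 1.00, 120.0, 0, 180, 0.30))
  d$K <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 111.3, 2, 0),
    sc_row("CE", "C", "CD", "CG", "CB", 1.52, 111.3, 3, 0, 0.25),
    sc_row("NZ", "N", "CE", "CD", "CG", 1.49, 111.9, 4, 0, -0.30, "ionized"),
    sc_row("HZ1", "H", "NZ", "CE", "CD", 1.00, 109.5, 0, 60, 0.35),
    sc_row("HZ2", "H", "NZ", "CE", "CD", 1.00, 109.5, 0, 180, 0.35),
    sc_row("HZ3", "H", "NZ", "CE", "CD", 1.00, 109.5, 0, -60, 0.35))
  d$R <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 111.3, 2, 0, 0.10),
    sc_row("NE", "N", "CD", "CG", "CB", 1.46, 112.0, 3, 0, -0.40, "ionized"),
    sc_row("CZ", "C", "NE", "CD", "CG", 1.33, 124.2, 4, 0, 0.50),
    sc_row("HE", "H", "NE", "CD", "CG", 1.00, 118.0, 4, 180, 0.30),
    sc_row("NH1", "N", "CZ", "NE", "CD", 1.33, 120.0, 0, 0, -0.45, "ionized"),
    sc_row("NH2", "N", "CZ", "NE", "CD", 1.33, 120.0, 0, 180, -0.45, "ionized"),
    sc_row("HH11", "H", "NH1", "CZ", "NE", 1.00, 120.0, 0, 0, 0.35),
    sc_row("HH12", "H", "NH1", "CZ", "NE", 1.00, 120.0, 0, 180, 0.35),
    sc_row("HH21", "H", "NH2", "CZ", "NE", 1.00, 120.0, 0, 0, 0.35),
    sc_row("HH22", "H", "NH2", "CZ", "NE", 1.00, 120.0, 0, 180, 0.35))
  d$P <- rbind(cb_row(),
    sc_row("CG", "C", "CB", "CA", "N", 1.49, 104.5, 0, -30),
    sc_row("CD", "C", "CG", "CB", "CA", 1.50, 106.1, 0, 35))
  d$G <- sc_row(character(0), character(0), character(0), character(0),
                character(0), numeric(0), numeric(0), integer(0),
                numeric(0), numeric(0), character(0))
  d
}

.topo_cache <- new.env(parent = emptyenv())

#' Residue topology
#'
#' Internal-coordinate template for one amino-acid type: ordered
#' side-chain atom records (parent/angle/dihedral references, ideal
#' bond lengths and angles, chi assignment, partial charge) plus the
#' derived chi dihedral definitions (4-atom name tuples).
#'
#' @param aa one-letter amino-acid code.
#' @return list with elements `aa`, `atoms` (data.frame), `chi_defs`
#'   (list of character(4)), `n_chi`.
#' @export
residue_topology <- function(aa) {
  if (!aa %in% AA_ALPHABET) stop("unknown amino-acid type: ", aa)
  key <- paste0("t_", aa)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  defs <- sidechain_defs()
  atoms <- defs[[aa]]
  n_chi <- AA_N_CHI[[aa]]
  chi_defs <- vector("list", n_chi)
  if (n_chi > 0) {
    for (k in seq_len(n_chi)) {
      cand <- atoms[atoms$chi == k & atoms$dih == 0, ]
      if (nrow(cand) == 0)
        stop("no chi-", k, " defining atom for ", aa)
      a <- cand[1, ]
      chi_defs[[k]] <- c(a$dref, a$aref, a$parent, a$name)
    }
  }
  out <- list(aa = aa, atoms = atoms, chi_defs = chi_defs, n_chi = n_chi)
  .topo_cache[[key]] <- out
  out
}

#' Side-chain atom names of a residue type
#' @param aa one-letter code.
#' @return character vector (empty for Gly).
#' @export
sidechain_atom_names <- function(aa) residue_topology(aa)$atoms$name

## Backbone atom parameter block (charge, class comes from element).
backbone_atoms <- function(aa) {
  has_h <- aa != "P"
  df <- data.frame(
    name = c("N", if (has_h) "H", "CA", "C", "O"),
    element = c("N", if (has_h) "H", "C", "C", "O"),
    charge = c(if (has_h) -0.35 else -0.10, if (has_h) 0.25,
               0.10, 0.55, -0.55),
    stringsAsFactors = FALSE)
  df
}

## Build side-chain coordinates for a residue given backbone N/CA/C
## coordinates (rows of a 3x3 matrix) and chi angles.  Returns a
## data.frame: name, element, charge, x, y, z.
build_sidechain <- function(aa, n_xyz, ca_xyz, c_xyz, chis = numeric(0)) {
  topo <- residue_topology(aa)
  atoms <- topo$atoms
  if (length(chis) != topo$n_chi)
    stop(aa, " needs ", topo$n_chi, " chi angle(s), got ", length(chis))
  coords <- list(N = n_xyz, CA = ca_xyz, C = c_xyz)
  out <- atoms[, c("name", "element", "charge")]
  xyz <- matrix(NA_real_, nrow(atoms), 3)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    dih <- if (a$chi > 0) chis[[a$chi]] + a$dih else a$dih
    p <- place_atom(coords[[a$dref]], coords[[a$aref]], coords[[a$parent]],
                    a$bond, a$angle, dih)
    coords[[a$name]] <- p
    xyz[i, ] <- p
  }
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

## Measure chi angles from a named coordinate lookup function
## get(name) -> 3-vector (or NULL if absent).
measure_chis <- function(aa, getter) {
  topo <- residue_topology(aa)
  if (topo$n_chi == 0) return(numeric(0))
  vapply(topo$chi_defs, function(def) {
    ps <- lapply(def, getter)
    if (any(vapply(ps, is.null, TRUE))) return(NA_real_)
    measure_dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

## Ring-closure bonds not captured by the parent-child placement tree.
RING_CLOSURES <- list(
  F = rbind(c("CE2", "CZ")),
  Y = rbind(c("CE2", "CZ")),
  H = rbind(c("CE1", "NE2")),
  W = rbind(c("NE1", "CE2"), c("CZ3", "CH2")),
  P = rbind(c("CD", "N")))

## Bond list (pairs of atom names) for one residue, including backbone
## bonds and ring closures; used to build the 1-2/1-3 exclusion graph.
residue_bonds <- function(aa) {
  topo <- residue_topology(aa)
  bb <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (aa != "P") bb <- rbind(bb, c("N", "H"))
  sc <- if (nrow(topo$atoms) > 0)
    cbind(topo$atoms$parent, topo$atoms$name) else NULL
  rbind(bb, sc, RING_CLOSURES[[aa]])
}
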