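## The CASA effective energy: CHARMM-style van der Waals term plus a
## screened Coulomb term (dielectric eps, default 10) plus atomic
## solvation sigma * SASA terms.  Bonded 1-2 and 1-3 pairs are
## excluded from the nonbonded sums; 1-4 pairs enter at full weight.

COULOMB_K <- 332.0636  # kcal A / (mol e^2)

#' Energy model settings
#'
#' @param eps_design Coulomb dielectric used for design energies
#'   (default 10).
#' @param eps_prep dielectric used during structure preparation
#'   (default 20).
#' @param surface_scale overall scale of the surface term (default 1).
#' @param probe_radius solvent probe radius, A (default 1.4).
#' @param cutoff residue-pair distance cutoff on pseudo-CB distances,
#'   A (default 14); pairs beyond it get identically zero energies.
#' @param pair_min_steps relaxation iterations per stage in pairwise
#'   energy evaluation (default 15; 0 = rigid rotamers).
#' @return list of class `energy_model`.
#' @export
energy_model <- function(eps_design = 10, eps_prep = 20,
                         surface_scale = 1, probe_radius = 1.4,
                         cutoff = 14, pair_min_steps = 15) {
  stopifnot(eps_design > 0, eps_prep > 0, probe_radius >= 0,
            pair_min_steps >= 0)
  structure(list(eps_design = eps_design, eps_prep = eps_prep,
                 surface_scale = surface_scale,
                 probe_radius = probe_radius, cutoff = cutoff,
                 pair_min_steps = pair_min_steps),
            class = "energy_model")
}

## ---- exclusion graph ---------------------------------------------------

## Atom keys "resno:name" for a whole-molecule atom table.
atom_keys <- function(atoms) paste0(atoms$resno, ":", atoms$name)

## Set of excluded (1-2 and 1-3) atom-pair keys "a|b" (a < b
## lexicographically) for a molecule given per-residue types.
exclusion_set <- function(res_aa) {
  ## res_aa: named character vector index -> aa
  edges <- list()
  idx <- as.integer(names(res_aa))
  for (i in seq_along(idx)) {
    b <- residue_bonds(res_aa[[i]])
    edges[[length(edges) + 1]] <-
      cbind(paste0(idx[i], ":", b[, 1]), paste0(idx[i], ":", b[, 2]))
  }
  if (length(idx) > 1)
    for (i in seq_len(length(idx) - 1))
      edges[[length(edges) + 1]] <-
        cbind(paste0(idx[i], ":C"), paste0(idx[i + 1], ":N"))
  em <- do.call(rbind, edges)
  adj <- split(c(em[, 2], em[, 1]), c(em[, 1], em[, 2]))
  excl <- new.env(hash = TRUE, parent = emptyenv())
  put <- function(a, b) {
    if (a == b) return()
    k <- if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
    assign(k, TRUE, envir = excl)
  }
  for (a in names(adj)) {
    nb1 <- unique(adj[[a]])
    for (b in nb1) {
      put(a, b)
      for (cc in adj[[b]]) put(a, cc)
    }
  }
  excl
}

is_excluded <- function(excl, ka, kb) {
  if (is.null(excl)) return(FALSE)
  k <- if (ka < kb) paste0(ka, "|", kb) else paste0(kb, "|", ka)
  exists(k, envir = excl, inherits = FALSE)
}

## Build the nonbonded pair list between atoms of table A and table B
## (or within A if B is NULL): returns data.frame i, j (row indices
## into A / B), qq, eps_ij, rmin_ij.  Exclusions looked up by key.
pair_list <- function(A, B = NULL, excl = NULL) {
  intra <- is.null(B)
  if (intra) B <- A
  ka <- atom_keys(A); kb <- atom_keys(B)
  na <- nrow(A); nb <- nrow(B)
  if (na == 0 || nb == 0)
    return(data.frame(i = integer(0), j = integer(0), qq = numeric(0),
                      eps_ij = numeric(0), rmin_ij = numeric(0)))
  ii <- rep(seq_len(na), each = nb)
  jj <- rep(seq_len(nb), times = na)
  if (intra) {
    keep <- ii < jj
    ii <- ii[keep]; jj <- jj[keep]
  }
  if (!is.null(excl)) {
    ex <- vapply(seq_along(ii),
                 function(t) is_excluded(excl, ka[ii[t]], kb[jj[t]]),
                 logical(1))
    ii <- ii[!ex]; jj <- jj[!ex]
  }
  data.frame(i = ii, j = jj,
             qq = A$charge[ii] * B$charge[jj],
             eps_ij = sqrt(A$lj_epsilon[ii] * B$lj_epsilon[jj]),
             rmin_ij = A$lj_rmin[ii] + B$lj_rmin[jj])
}

## Evaluate vdW + Coulomb over a pair list.  xa, xb: coordinate
## matrices.  Returns c(vdw, coulomb).
eval_pairs <- function(pl, xa, xb, eps) {
  if (nrow(pl) == 0) return(c(vdw = 0, coulomb = 0))
  dv <- xa[pl$i, , drop = FALSE] - xb[pl$j, , drop = FALSE]
  r2 <- rowSums(dv * dv)
  if (any(r2 < 1e-12 & abs(pl$qq) > 0))
    stop("coincident charged atoms")
  r2[r2 < 1e-12] <- 1e-12
  r <- sqrt(r2)
  s6 <- (pl$rmin_ij^2 / r2)^3
  c(vdw = sum(pl$eps_ij * (s6 * s6 - 2 * s6)),
    coulomb = sum(COULOMB_K * pl$qq / (eps * r)))
}

## Gradient of vdW + Coulomb wrt coordinates of the A-side atoms
## (and B-side if requested).  Returns list(e = c(vdw, coulomb),
## ga = matrix, gb = matrix).
eval_pairs_grad <- function(pl, xa, xb, eps) {
  ga <- matrix(0, nrow(xa), 3)
  gb <- matrix(0, nrow(xb), 3)
  if (nrow(pl) == 0)
    return(list(e = c(vdw = 0, coulomb = 0), ga = ga, gb = gb))
  dv <- xa[pl$i, , drop = FALSE] - xb[pl$j, , drop = FALSE]
  r2 <- rowSums(dv * dv)
  r2[r2 < 1e-12] <- 1e-12
  r <- sqrt(r2)
  s6 <- (pl$rmin_ij^2 / r2)^3
  evdw <- sum(pl$eps_ij * (s6 * s6 - 2 * s6))
  ecou <- sum(COULOMB_K * pl$qq / (eps * r))
  ## dE/dr terms
  dvdw <- pl$eps_ij * (-12 * s6 * s6 + 12 * s6) / r
  dcou <- -COULOMB_K * pl$qq / (eps * r2)
  coef <- (dvdw + dcou) / r
  gvec <- dv * coef
  gas <- rowsum(gvec, pl$i)
  ga[as.integer(rownames(gas)), ] <- gas
  gbs <- rowsum(-gvec, pl$j)
  gb[as.integer(rownames(gbs)), ] <- gbs
  list(e = c(vdw = evdw, coulomb = ecou), ga = ga, gb = gb)
}

## ---- exported pair-energy operations -----------------------------------

#' Screened Coulomb energy between two atom sets
#'
#' Sum of k q_i q_j / (eps r_ij) over cross pairs, k = 332.0636
#' kcal A / (mol e^2).  Bonded 1-2/1-3 pairs can be excluded via
#' `excl` (an exclusion set built from the molecular graph).
#'
#' @param atoms_a,atoms_b atom tables with `charge`, `x`, `y`, `z`
#'   (and `resno`, `name` when exclusions are used).
#' @param eps dielectric constant (> 0).
#' @param excl optional exclusion set.
#' @return kcal/mol.
#' @export
coulomb_energy <- function(atoms_a, atoms_b, eps = 10, excl = NULL) {
  stopifnot(eps > 0)
  pl <- pair_list(fill_lj(atoms_a), fill_lj(atoms_b), excl = excl)
  unname(eval_pairs(pl, coord_mat(atoms_a), coord_mat(atoms_b),
                    eps)["coulomb"])
}

#' Lennard-Jones (van der Waals) energy between two atom sets
#'
#' eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6] with the combination
#' rules eps_ij = sqrt(eps_i eps_j), rmin_ij = rmin_i + rmin_j.
#'
#' @inheritParams coulomb_energy
#' @return kcal/mol.
#' @export
lj_energy <- function(atoms_a, atoms_b, excl = NULL) {
  pl <- pair_list(fill_lj(atoms_a), fill_lj(atoms_b), excl = excl)
  xa <- coord_mat(atoms_a); xb <- coord_mat(atoms_b)
  dv <- xa[pl$i, , drop = FALSE] - xb[pl$j, , drop = FALSE]
  r2 <- rowSums(dv * dv)
  if (any(r2 < 1e-12)) stop("coincident atoms")
  s6 <- (pl$rmin_ij^2 / r2)^3
  sum(pl$eps_ij * (s6 * s6 - 2 * s6))
}

coord_mat <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

## Tolerate atom tables missing charge/LJ columns (default 0 / keys).
fill_lj <- function(atoms) {
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$lj_epsilon)) atoms$lj_epsilon <- 0
  if (is.null(atoms$lj_rmin)) atoms$lj_rmin <- 1
  if (is.null(atoms$resno)) atoms$resno <- 0
  if (is.null(atoms$name))
    atoms$name <- sprintf("X%d", seq_len(nrow(atoms)))
  atoms
}

## ---- whole-system CASA evaluation --------------------------------------

## Direct CASA evaluation of a fully assembled atom table (the
## whole-system oracle): vdW + screened Coulomb over all non-excluded
## pairs, plus the linear pairwise surface energy.
system_casa_energy <- function(atoms, model, excl = NULL) {
  if (is.null(excl)) {
    res_aa <- tapply(atoms$aa, atoms$resno, function(a) a[1])
    excl <- exclusion_set(res_aa)
  }
  pl <- pair_list(atoms, excl = excl)
  x <- coord_mat(atoms)
  e <- eval_pairs(pl, x, x, model$eps_design)
  surf <- model$surface_scale *
    surface_self_energy(atoms, probe = model$probe_radius)
  c(vdw = unname(e["vdw"]), coulomb = unname(e["coulomb"]),
    surface = surf)
}

## ---- structure preparation ---------------------------------------------

#' Minimize a structure's nonbonded energy
#'
#' Conjugate-gradient minimization of the van der Waals plus Coulomb
#' (dielectric `eps_prep`) energy over all atom coordinates,
#' emulating the preparation step applied to crystal structures
#' before design.  Bonded terms are not modelled; the intended use is
#' light relaxation of near-ideal geometry, not refinement.
#'
#' @param atoms assembled atom table (see [assemble_atoms()]).
#' @param model an [energy_model()].
#' @param maxit maximum iterations (default 500; 0 returns the input).
#' @return list: `atoms` (relaxed), `energy` (final vdw+coulomb),
#'   `initial_energy`, `rmsd` (all-atom RMSD to input, A).
#' @export
minimize_structure <- function(atoms, model = energy_model(),
                               maxit = 500) {
  res_aa <- tapply(atoms$aa, atoms$resno, function(a) a[1])
  excl <- exclusion_set(res_aa)
  pl <- pair_list(atoms, excl = excl)
  x0 <- coord_mat(atoms)
  n <- nrow(x0)
  efun <- function(v) {
    x <- matrix(v, n, 3)
    e <- eval_pairs(pl, x, x, model$eps_prep)
    unname(e["vdw"] + e["coulomb"])
  }
  gfun <- function(v) {
    x <- matrix(v, n, 3)
    g <- eval_pairs_grad(pl, x, x, model$eps_prep)
    as.numeric(g$ga + g$gb)
  }
  e0 <- efun(as.numeric(x0))
  if (!is.finite(e0)) stop("non-finite initial energy")
  if (maxit == 0)
    return(list(atoms = atoms, energy = e0, initial_energy = e0,
                rmsd = 0))
  opt <- stats::optim(as.numeric(x0), efun, gfun, method = "CG",
                      control = list(maxit = maxit))
  x1 <- matrix(opt$par, n, 3)
  out <- atoms
  out$x <- x1[, 1]; out$y <- x1[, 2]; out$z <- x1[, 3]
  list(atoms = out, energy = min(opt$value, e0), initial_energy = e0,
       rmsd = sqrt(mean(rowSums((x1 - x0)^2))))
}
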