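## The precomputed energy matrix over (position, type, rotamer)
## states.  Singleton entries hold each state's interaction with the
## fixed backbone plus intra-side-chain and self-surface terms;
## pairwise entries hold side-chain/side-chain interactions, zero (and
## unstored) beyond the residue cutoff.  Folding free energies of any
## sequence/rotamer assignment are then sums over the matrix, which is
## what makes heuristic design cycles cheap.

#' Construct a pair energy matrix
#'
#' Low-level constructor (used directly in tests with synthetic
#' energies; [build_energy_matrix()] builds one from a structure).
#'
#' @param states list per position: data.frame with columns `aa`,
#'   `rot`.
#' @param sing list per position: numeric matrix n_states x 3
#'   (columns vdw, coulomb, surface), kcal/mol.
#' @param unfold list per position: numeric vector n_states of
#'   unfolded-reference energies (e_ref + correction), kcal/mol.
#' @param pair named list `"i|j"` (i < j, position order) of arrays
#'   n_i x n_j x 3; absent entries are zero by the cutoff.
#' @param const length-3 constant channel vector (backbone-backbone).
#' @param positions integer position indices.
#' @param meta provenance list.
#' @return object of class `pair_energy_matrix`.
#' @export
pair_energy_matrix <- function(states, sing, unfold, pair = list(),
                               const = c(0, 0, 0), positions = NULL,
                               meta = list()) {
  if (is.null(positions)) positions <- as.integer(names(states))
  for (k in names(pair)) {
    ij <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    stopifnot(ij[1] < ij[2])
    if (any(!is.finite(pair[[k]]))) stop("non-finite pair entry at ", k)
  }
  for (p in names(sing)) if (any(!is.finite(sing[[p]])))
    stop("non-finite singleton entry at position ", p)
  ## per-position totals used by the optimizer: sing - unfold
  tot <- lapply(names(states), function(p)
    rowSums(sing[[p]]) - unfold[[p]])
  names(tot) <- names(states)
  ptot <- lapply(pair, function(a) {
    m <- a[, , 1] + a[, , 2] + a[, , 3]
    if (!is.matrix(m)) m <- matrix(m, dim(a)[1], dim(a)[2])
    m
  })
  structure(list(states = states, sing = sing, unfold = unfold,
                 pair = pair, const = const, positions = positions,
                 tot = tot, ptot = ptot, meta = meta),
            class = "pair_energy_matrix")
}

#' @export
print.pair_energy_matrix <- function(x, ...) {
  ns <- vapply(x$states, nrow, integer(1))
  cat("Pair energy matrix:", length(x$positions), "positions,",
      sum(ns), "states,", length(x$pair), "stored pair blocks\n")
  invisible(x)
}

pair_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

## Retrieve the pair block oriented as (states of i) x (states of j),
## or NULL if absent (beyond cutoff).
pair_block <- function(em, i, j, channel = NULL) {
  k <- pair_key(i, j)
  a <- if (is.null(channel)) em$ptot[[k]] else em$pair[[k]][, , channel]
  if (is.null(a)) return(NULL)
  if (i <= j) a else t(a)
}

#' Build the energy matrix for a template
#'
#' Precomputes singleton and pairwise CASA energies over all
#' (type, rotamer) states at every position.  Designable positions get
#' `allowed_types` x rotamers states; frozen positions a single native
#' state at the frozen coordinates.  With `model$pair_min_steps > 0`,
#' side chains are relaxed by conjugate-gradient minimization in two
#' stages (alone against the backbone, then as an interacting pair)
#' before the interaction energy is taken; with 0 the rigid rotamer
#' geometry is used, which is the mode the whole-system oracle checks.
#'
#' @param template a `backbone_template`.
#' @param library rotamer library.
#' @param model an [energy_model()].
#' @param unfolded an `unfolded_reference` (or NULL for all-zero
#'   references).
#' @param allowed_types candidate types at designable positions
#'   (default all 17 non-C/G/P types).
#' @param parameters a `parameter_set`.
#' @return a `pair_energy_matrix`.
#' @export
build_energy_matrix <- function(template,
                                library = builtin_rotamer_library(),
                                model = energy_model(),
                                unfolded = NULL,
                                allowed_types = AA_DESIGNABLE,
                                parameters = default_parameters()) {
  pos <- template$positions
  L <- nrow(pos)
  bad <- setdiff(allowed_types, AA_DESIGNABLE)
  if (length(bad) > 0)
    stop("allowed_types contains frozen types: ",
         paste(bad, collapse = ", "))
  ## backbone atom table with parameters (native types fix the
  ## backbone parameter rows; G/P backbones never change type)
  bb <- template$bb_atoms
  bb$aa <- pos$native[match(bb$resno, pos$index)]
  bb <- assign_parameters(bb, parameters)
  scale <- model$surface_scale
  probe <- model$probe_radius

  ## enumerate states and their (possibly relaxed) side-chain atoms
  states <- list(); sc_atoms <- list(); sing <- list(); unfold <- list()
  for (ii in seq_len(L)) {
    p <- pos$index[ii]
    key <- as.character(p)
    if (pos$designable[ii]) {
      st <- do.call(rbind, lapply(allowed_types, function(aa)
        data.frame(aa = aa, rot = seq_len(n_rotamers(library, aa)),
                   stringsAsFactors = FALSE)))
    } else {
      st <- data.frame(aa = pos$native[ii], rot = NA_integer_,
                       stringsAsFactors = FALSE)
    }
    states[[key]] <- st
    sc_atoms[[key]] <- vector("list", nrow(st))
    sing[[key]] <- matrix(0, nrow(st), 3,
                          dimnames = list(NULL,
                            c("vdw", "coulomb", "surface")))
    unfold[[key]] <- numeric(nrow(st))
    for (s in seq_len(nrow(st))) {
      aa <- st$aa[s]
      sc <- if (is.na(st$rot[s])) {
        fr <- template$frozen[[key]]
        if (!is.null(fr)) { fr$resno <- p; fr$aa <- aa }
        fr
      } else {
        a <- place_rotamer(template, p, aa, st$rot[s], library)
        a$resno <- p; a$aa <- aa
        a
      }
      if (!is.null(sc) && nrow(sc) > 0) {
        sc <- assign_parameters(sc[, c("resno", "aa", "name", "element",
                                       "x", "y", "z")], parameters)
      } else sc <- NULL
      ## exclusion graph for this residue's type at this position
      res_aa <- stats::setNames(pos$native, pos$index)
      res_aa[key] <- aa
      excl <- exclusion_set(res_aa)
      if (!is.null(sc) && model$pair_min_steps > 0 && !is.na(st$rot[s]))
        sc <- relax_sidechain(sc, bb, excl, model)
      sc_atoms[[key]][s] <- list(sc)
      e <- singleton_energy(sc, bb, excl, model)
      sing[[key]][s, ] <- e
      if (!is.null(unfolded)) {
        eref <- unfolded$e_ref[[aa]] %||% 0
        corr <- unfolded$correction[[aa]] %||% 0
        unfold[[key]][s] <- eref + corr
      }
    }
  }

  ## constant channel: backbone-backbone
  res_aa <- stats::setNames(pos$native, pos$index)
  excl_bb <- exclusion_set(res_aa)
  e_bb <- eval_pairs(pair_list(bb, excl = excl_bb), coord_mat(bb),
                     coord_mat(bb), model$eps_design)
  const <- c(unname(e_bb["vdw"]), unname(e_bb["coulomb"]),
             scale * surface_self_energy(bb, probe))

  ## pairwise blocks within the cutoff
  cb <- lapply(pos$index, function(p) pseudo_cb(template, p))
  pair <- list(); capped <- list()
  if (L > 1) for (ii in 1:(L - 1)) for (jj in (ii + 1):L) {
    pi_ <- pos$index[ii]; pj <- pos$index[jj]
    if (sqrt(sum((cb[[ii]] - cb[[jj]])^2)) > model$cutoff) next
    ki <- as.character(pi_); kj <- as.character(pj)
    ni <- nrow(states[[ki]]); nj <- nrow(states[[kj]])
    blk <- array(0, dim = c(ni, nj, 3))
    for (si in seq_len(ni)) for (sj in seq_len(nj)) {
      sci <- sc_atoms[[ki]][[si]]; scj <- sc_atoms[[kj]][[sj]]
      if (is.null(sci) || is.null(scj)) next
      blk[si, sj, ] <- pair_channels(sci, scj, bb, model,
                                     states[[ki]]$rot[si],
                                     states[[kj]]$rot[sj])
    }
    tot_blk <- blk[, , 1] + blk[, , 2] + blk[, , 3]
    if (any(tot_blk > 100))
      capped[[pair_key(pi_, pj)]] <- which(tot_blk > 100, arr.ind = TRUE)
    pair[[pair_key(pi_, pj)]] <- blk
  }
  em <- pair_energy_matrix(states, sing, unfold, pair, const,
                           positions = pos$index,
                           meta = list(model = model,
                                       template_hash = hash_object(template),
                                       library_hash = hash_object(library),
                                       capped = capped))
  em
}

## Singleton channels of one side chain against the backbone:
## vdW + Coulomb (cross and intra-side-chain) and the surface terms
## that involve this side chain.
singleton_energy <- function(sc, bb, excl, model) {
  if (is.null(sc)) return(c(0, 0, 0))
  e_cross <- eval_pairs(pair_list(sc, bb, excl = excl),
                        coord_mat(sc), coord_mat(bb), model$eps_design)
  e_intra <- eval_pairs(pair_list(sc, excl = excl),
                        coord_mat(sc), coord_mat(sc), model$eps_design)
  surf <- model$surface_scale *
    (surface_self_energy(sc, model$probe_radius) -
     surface_cross_burial(sc, bb, model$probe_radius))
  c(unname(e_cross["vdw"] + e_intra["vdw"]),
    unname(e_cross["coulomb"] + e_intra["coulomb"]),
    surf)
}

## Interaction channels between two placed side chains; with
## relaxation the pair is re-minimized jointly and the entry is the
## difference between the pair-on energy and the isolated energies.
pair_channels <- function(sci, scj, bb, model, rot_i, rot_j) {
  if (model$pair_min_steps > 0 && !is.na(rot_i) && !is.na(rot_j)) {
    return(pair_channels_relaxed(sci, scj, bb, model))
  }
  pl <- pair_list(sci, scj)
  e <- eval_pairs(pl, coord_mat(sci), coord_mat(scj), model$eps_design)
  surf <- -model$surface_scale *
    surface_cross_burial(sci, scj, model$probe_radius)
  c(unname(e["vdw"]), unname(e["coulomb"]), surf)
}

## Conjugate-gradient relaxation of one side chain against the fixed
## backbone (stage 1 of the pairwise protocol).
relax_sidechain <- function(sc, bb, excl, model) {
  pl_cross <- pair_list(sc, bb, excl = excl)
  pl_intra <- pair_list(sc, excl = excl)
  xb <- coord_mat(bb)
  n <- nrow(sc)
  efun <- function(v) {
    x <- matrix(v, n, 3)
    e1 <- eval_pairs(pl_cross, x, xb, model$eps_design)
    e2 <- eval_pairs(pl_intra, x, x, model$eps_design)
    sum(e1) + sum(e2)
  }
  gfun <- function(v) {
    x <- matrix(v, n, 3)
    g1 <- eval_pairs_grad(pl_cross, x, xb, model$eps_design)
    g2 <- eval_pairs_grad(pl_intra, x, x, model$eps_design)
    as.numeric(g1$ga + g2$ga + g2$gb)
  }
  opt <- stats::optim(as.numeric(coord_mat(sc)), efun, gfun,
                      method = "CG",
                      control = list(maxit = model$pair_min_steps))
  x1 <- matrix(opt$par, n, 3)
  sc$x <- x1[, 1]; sc$y <- x1[, 2]; sc$z <- x1[, 3]
  sc
}

## Stage 2: joint relaxation of the pair with interactions on; the
## returned channels are pair-on minus isolated energies, evaluated
## at the final geometry.
pair_channels_relaxed <- function(sci, scj, bb, model) {
  ni <- nrow(sci); nj <- nrow(scj)
  pl_ij <- pair_list(sci, scj)
  xb <- coord_mat(bb)
  ## isolated channels at the stage-1 geometry
  iso <- function(sc) {
    e1 <- eval_pairs(pair_list(sc, bb), coord_mat(sc), xb,
                     model$eps_design)
    surf <- model$surface_scale *
      (surface_self_energy(sc, model$probe_radius) -
       surface_cross_burial(sc, bb, model$probe_radius))
    c(unname(e1["vdw"]), unname(e1["coulomb"]), surf)
  }
  iso_i <- iso(sci); iso_j <- iso(scj)
  pl_i <- pair_list(sci, bb); pl_j <- pair_list(scj, bb)
  efun <- function(v) {
    xi <- matrix(v[seq_len(3 * ni)], ni, 3)
    xj <- matrix(v[-seq_len(3 * ni)], nj, 3)
    sum(eval_pairs(pl_i, xi, xb, model$eps_design)) +
      sum(eval_pairs(pl_j, xj, xb, model$eps_design)) +
      sum(eval_pairs(pl_ij, xi, xj, model$eps_design))
  }
  gfun <- function(v) {
    xi <- matrix(v[seq_len(3 * ni)], ni, 3)
    xj <- matrix(v[-seq_len(3 * ni)], nj, 3)
    gi <- eval_pairs_grad(pl_i, xi, xb, model$eps_design)
    gj <- eval_pairs_grad(pl_j, xj, xb, model$eps_design)
    gij <- eval_pairs_grad(pl_ij, xi, xj, model$eps_design)
    c(as.numeric(gi$ga + gij$ga), as.numeric(gj$ga + gij$gb))
  }
  v0 <- c(as.numeric(coord_mat(sci)), as.numeric(coord_mat(scj)))
  opt <- stats::optim(v0, efun, gfun, method = "CG",
                      control = list(maxit = model$pair_min_steps))
  xi <- matrix(opt$par[seq_len(3 * ni)], ni, 3)
  xj <- matrix(opt$par[-seq_len(3 * ni)], nj, 3)
  si <- sci; si$x <- xi[, 1]; si$y <- xi[, 2]; si$z <- xi[, 3]
  sj <- scj; sj$x <- xj[, 1]; sj$y <- xj[, 2]; sj$z <- xj[, 3]
  e_i <- eval_pairs(pl_i, xi, xb, model$eps_design)
  e_j <- eval_pairs(pl_j, xj, xb, model$eps_design)
  e_ij <- eval_pairs(pl_ij, xi, xj, model$eps_design)
  surf_i <- model$surface_scale *
    (surface_self_energy(si, model$probe_radius) -
     surface_cross_burial(si, bb, model$probe_radius))
  surf_j <- model$surface_scale *
    (surface_self_energy(sj, model$probe_radius) -
     surface_cross_burial(sj, bb, model$probe_radius))
  surf_ij <- -model$surface_scale *
    surface_cross_burial(si, sj, model$probe_radius)
  c(unname(e_i["vdw"] + e_j["vdw"] + e_ij["vdw"]) -
      iso_i[1] - iso_j[1],
    unname(e_i["coulomb"] + e_j["coulomb"] + e_ij["coulomb"]) -
      iso_i[2] - iso_j[2],
    surf_i + surf_j + surf_ij - iso_i[3] - iso_j[3])
}

#' Pairwise interaction energy between two positions' states
#'
#' Convenience wrapper returning the (vdw, coulomb, surface)
#' interaction channels for one state pair, zero beyond the cutoff.
#'
#' @param template a `backbone_template`.
#' @param i,j position indices (i != j).
#' @param aa_i,aa_j types; `rot_i,rot_j` rotamer indices.
#' @param model an [energy_model()].
#' @param library rotamer library.
#' @param parameters a `parameter_set`.
#' @return named numeric length-3 vector, kcal/mol.
#' @export
pair_interaction_energy <- function(template, i, aa_i, rot_i, j, aa_j,
                                    rot_j, model = energy_model(),
                                    library = builtin_rotamer_library(),
                                    parameters = default_parameters()) {
  if (i == j) stop("i and j must differ")
  if (sqrt(sum((pseudo_cb(template, i) - pseudo_cb(template, j))^2)) >
      model$cutoff)
    return(c(vdw = 0, coulomb = 0, surface = 0))
  mk <- function(p, aa, rot) {
    a <- place_rotamer(template, p, aa, rot, library)
    a$resno <- p; a$aa <- aa
    assign_parameters(a[, c("resno", "aa", "name", "element",
                            "x", "y", "z")], parameters)
  }
  sci <- mk(i, aa_i, rot_i); scj <- mk(j, aa_j, rot_j)
  if (model$pair_min_steps > 0) {
    pos <- template$positions
    res_aa <- stats::setNames(pos$native, pos$index)
    res_aa[as.character(i)] <- aa_i; res_aa[as.character(j)] <- aa_j
    excl <- exclusion_set(res_aa)
    bb <- template$bb_atoms
    bb$aa <- pos$native[match(bb$resno, pos$index)]
    bb <- assign_parameters(bb, parameters)
    sci <- relax_sidechain(sci, bb, excl, model)
    scj <- relax_sidechain(scj, bb, excl, model)
    e <- pair_channels_relaxed(sci, scj, bb, model)
  } else {
    pl <- pair_list(sci, scj)
    ev <- eval_pairs(pl, coord_mat(sci), coord_mat(scj),
                     model$eps_design)
    e <- c(unname(ev["vdw"]), unname(ev["coulomb"]),
           -model$surface_scale *
             surface_cross_burial(sci, scj, model$probe_radius))
  }
  stats::setNames(e, c("vdw", "coulomb", "surface"))
}

#' Folding free energy of an assignment from the matrix
#'
#' Sums the constant, singleton and stored pairwise channels for a
#' state assignment and subtracts the unfolded reference:
#' dG = vdw + coulomb + surface - unfolded.  Negative values indicate
#' stable folding.
#'
#' @param em a `pair_energy_matrix`.
#' @param assignment integer vector of state indices, one per position
#'   (in `em$positions` order).
#' @return list of class `fold_energy`: `total`, `vdw`, `coulomb`,
#'   `surface`, `unfolded`, `per_residue`.
#' @export
fold_free_energy <- function(em, assignment) {
  keys <- as.character(em$positions)
  L <- length(keys)
  if (length(assignment) != L)
    stop("assignment length != number of positions")
  ch <- c(vdw = 0, coulomb = 0, surface = 0)
  unf <- 0
  for (ii in seq_len(L)) {
    k <- keys[ii]; s <- assignment[ii]
    if (is.na(s) || s < 1 || s > nrow(em$states[[k]]))
      stop("state ", s, " not in matrix at position ", k)
    ch <- ch + em$sing[[k]][s, ]
    unf <- unf + em$unfold[[k]][s]
  }
  ch <- ch + c(em$const[1], em$const[2], em$const[3])
  if (L > 1) for (ii in 1:(L - 1)) for (jj in (ii + 1):L) {
    blk <- em$pair[[pair_key(em$positions[ii], em$positions[jj])]]
    if (is.null(blk)) next
    ch <- ch + blk[assignment[ii], assignment[jj], ]
  }
  total <- unname(ch[1] + ch[2] + ch[3] - unf)
  structure(list(total = total, vdw = unname(ch[1]),
                 coulomb = unname(ch[2]), surface = unname(ch[3]),
                 unfolded = unf, per_residue = total / L),
            class = "fold_energy")
}

#' @export
print.fold_energy <- function(x, ...) {
  cat(sprintf(paste0("dG_fold = %.3f kcal/mol  (vdw %.3f | coulomb ",
                     "%.3f | surface %.3f | unfolded %.3f)\n"),
              x$total, x$vdw, x$coulomb, x$surface, x$unfolded))
  invisible(x)
}

#' Whole-system CASA energy of an assignment (oracle route)
#'
#' Assembles all atoms for a sequence/rotamer assignment and evaluates
#' the CASA energy directly (no matrix): the independent route used to
#' check matrix fidelity at `pair_min_steps = 0`.
#'
#' @param template a `backbone_template`.
#' @param em a `pair_energy_matrix` (supplies states and unfolded
#'   references).
#' @param assignment state indices per position.
#' @param model an [energy_model()].
#' @param library rotamer library.
#' @param parameters a `parameter_set`.
#' @return list like [fold_free_energy()].
#' @export
direct_fold_energy <- function(template, em, assignment,
                               model = energy_model(),
                               library = builtin_rotamer_library(),
                               parameters = default_parameters()) {
  keys <- as.character(em$positions)
  seq_vec <- character(length(keys))
  rots <- list()
  unf <- 0
  for (ii in seq_along(keys)) {
    st <- em$states[[keys[ii]]][assignment[ii], ]
    seq_vec[ii] <- st$aa
    if (!is.na(st$rot) && AA_N_CHI[[st$aa]] > 0)
      rots[[keys[ii]]] <- rotamer_chis(library, st$aa, st$rot)
    unf <- unf + em$unfold[[keys[ii]]][assignment[ii]]
  }
  atoms <- assemble_atoms(template, sequence = paste(seq_vec, collapse = ""),
                          rotamers = rots, library = library,
                          parameters = parameters)
  e <- system_casa_energy(atoms, model)
  total <- unname(sum(e)) - unf
  list(total = total, vdw = unname(e["vdw"]),
       coulomb = unname(e["coulomb"]), surface = unname(e["surface"]),
       unfolded = unf, per_residue = total / length(keys))
}

#' Random energy matrix (test instrument)
#'
#' Synthesizes a `pair_energy_matrix` with i.i.d. Gaussian singleton
#' and pairwise energies over `n_pos` positions x `types` x `n_rot`
#' rotamers; used to exercise the optimizer against exhaustive
#' enumeration.
#'
#' @param n_pos positions; `types` type labels; `n_rot` rotamers per
#'   type; `sd` energy scale; `seed` RNG seed.
#' @return a `pair_energy_matrix`.
#' @export
random_energy_matrix <- function(n_pos = 3, types = c("A", "S", "V"),
                                 n_rot = 2, sd = 3, seed = 1) {
  with_seed(seed, {
    states <- sing <- unfold <- list()
    for (p in seq_len(n_pos)) {
      k <- as.character(p)
      st <- expand.grid(rot = seq_len(n_rot), aa = types,
                        stringsAsFactors = FALSE)[, c("aa", "rot")]
      states[[k]] <- st
      sing[[k]] <- cbind(vdw = stats::rnorm(nrow(st), 0, sd),
                         coulomb = 0, surface = 0)
      unfold[[k]] <- rep(0, nrow(st))
    }
    pair <- list()
    if (n_pos > 1) for (i in 1:(n_pos - 1)) for (j in (i + 1):n_pos) {
      ni <- nrow(states[[as.character(i)]])
      nj <- nrow(states[[as.character(j)]])
      a <- array(0, dim = c(ni, nj, 3))
      a[, , 1] <- stats::rnorm(ni * nj, 0, sd)
      pair[[pair_key(i, j)]] <- a
    }
    pair_energy_matrix(states, sing, unfold, pair,
                       positions = seq_len(n_pos))
  })
}

#' Exhaustive global minimum of a small matrix (oracle)
#'
#' Enumerates every assignment and returns the minimum-energy one;
#' tractable only for toy systems, used as the optimizer oracle.
#'
#' @param em a `pair_energy_matrix`.
#' @return list: `assignment`, `energy`.
#' @export
enumerate_gmec <- function(em) {
  keys <- as.character(em$positions)
  ns <- vapply(em$states[keys], nrow, integer(1))
  if (prod(ns) > 2e6) stop("state space too large to enumerate")
  grid <- do.call(expand.grid, lapply(ns, seq_len))
  best <- Inf; best_a <- NULL
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    e <- matrix_total(em, a)
    if (e < best) { best <- e; best_a <- a }
  }
  list(assignment = best_a, energy = best)
}

## Fast total energy (scalar) of an assignment.
matrix_total <- function(em, assignment) {
  keys <- as.character(em$positions)
  e <- sum(em$const)
  for (ii in seq_along(keys))
    e <- e + em$tot[[keys[ii]]][assignment[ii]]
  L <- length(keys)
  if (L > 1) for (ii in 1:(L - 1)) {
    for (jj in (ii + 1):L) {
      b <- em$ptot[[pair_key(em$positions[ii], em$positions[jj])]]
      if (!is.null(b)) e <- e + b[assignment[ii], assignment[jj]]
    }
  }
  e
}
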