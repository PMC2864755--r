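## Unfolded-state reference energies.  Each amino-acid type X is
## modelled as the central residue of an Ala-X-Ala tripeptide; the
## reference energy is the minimum CASA energy over a small catalog of
## backbone (phi, psi) conformations crossed with the rotamers of X.
## An optional per-type empirical correction can be calibrated so
## that design reproduces a target amino-acid composition.

## Backbone conformation catalog for the tripeptide scan: alpha helix,
## antiparallel beta, polyproline-II-like, and fully extended.
UNFOLDED_PHIPSI <- list(c(-57, -47), c(-119, 113), c(-75, 145),
                        c(-180, 180))

#' Unfolded-state reference energy of one amino-acid type
#'
#' Minimum over the (phi, psi) catalog x rotamers of X of the CASA
#' energy of the Ala-X-Ala tripeptide.
#'
#' @param aa one-letter type.
#' @param library rotamer library.
#' @param model an [energy_model()].
#' @param catalog list of c(phi, psi) backbone conformations.
#' @param parameters a `parameter_set`.
#' @return kcal/mol (scalar).
#' @export
unfolded_reference_energy <- function(aa, library = builtin_rotamer_library(),
                                      model = energy_model(),
                                      catalog = UNFOLDED_PHIPSI,
                                      parameters = default_parameters()) {
  best <- Inf
  seq_vec <- c("A", aa, "A")
  for (pp in catalog) {
    ppm <- matrix(rep(pp, 3), ncol = 2, byrow = TRUE)
    tpl <- ideal_template(ppm, seq_vec)
    nr <- max(1L, n_rotamers(library, aa))
    for (r in seq_len(nr)) {
      rot_list <- list()
      for (p in 1:3) {
        a2 <- seq_vec[p]
        k <- AA_N_CHI[[a2]]
        rot_list[[as.character(p)]] <-
          if (p == 2 && k > 0) rotamer_chis(library, aa, r)
          else if (k > 0) rep(180, k) else numeric(0)
      }
      atoms <- assemble_atoms(tpl, rotamers = rot_list,
                              parameters = parameters)
      e <- sum(system_casa_energy(atoms, model))
      if (e < best) best <- e
    }
  }
  best
}

#' Unfolded-state reference for a set of types
#'
#' @param types amino-acid types (default all 20).
#' @param correction named numeric vector of empirical per-type
#'   corrections, kcal/mol (default all 0; see
#'   [calibrate_corrections()]).
#' @inheritParams unfolded_reference_energy
#' @return object of class `unfolded_reference`: list with `e_ref`
#'   and `correction` (both named over `types`).
#' @export
unfolded_reference <- function(types = AA_ALPHABET,
                               library = builtin_rotamer_library(),
                               model = energy_model(),
                               catalog = UNFOLDED_PHIPSI,
                               correction = NULL,
                               parameters = default_parameters()) {
  e <- vapply(types, unfolded_reference_energy, numeric(1),
              library = library, model = model, catalog = catalog,
              parameters = parameters)
  corr <- stats::setNames(rep(0, length(types)), types)
  if (!is.null(correction)) corr[names(correction)] <- correction
  structure(list(e_ref = e, correction = corr),
            class = "unfolded_reference")
}

#' @export
print.unfolded_reference <- function(x, ...) {
  cat("Unfolded reference (kcal/mol):\n")
  print(round(x$e_ref + x$correction, 3))
  invisible(x)
}

#' Calibrate empirical composition corrections
#'
#' Iteratively adjusts the per-type unfolded-state correction so that
#' the amino-acid composition of short design runs approaches a
#' target composition: correction(X) += eta * log(f(X) / target(X))
#' per round, with observed frequencies f smoothed by a small
#' pseudocount.
#'
#' @param matrix_fn function(unfolded) -> `pair_energy_matrix`; called
#'   each round so the updated reference enters the singleton terms.
#' @param unfolded starting [unfolded_reference()].
#' @param target named target composition over designable types
#'   (sums to 1).
#' @param eta learning rate (default 0.5).
#' @param rounds maximum calibration rounds (default 5).
#' @param n_cycles design cycles per round (default 50).
#' @param seed RNG seed.
#' @return list: `unfolded` (with calibrated corrections),
#'   `divergence` (KL(designed || target) per round), `composition`
#'   (final observed composition).
#' @export
calibrate_corrections <- function(matrix_fn, unfolded, target,
                                  eta = 0.5, rounds = 5,
                                  n_cycles = 50, seed = 1) {
  if (any(names(target) %in% AA_SPECIAL))
    stop("target composition must not include frozen types (C, G, P)")
  if (abs(sum(target) - 1) > 1e-6)
    stop("target composition must sum to 1")
  types <- names(target)
  kl <- numeric(0)
  comp <- NULL
  for (r in seq_len(rounds)) {
    em <- matrix_fn(unfolded)
    ens <- run_design(em, design_config(n_cycles = n_cycles,
                                        seed = derive_seed(seed, r)))
    seqs <- ens$records$sequence
    counts <- table(factor(unlist(strsplit(seqs, "")), levels = types))
    f <- (as.numeric(counts) + 0.5) / sum(as.numeric(counts) + 0.5)
    names(f) <- types
    comp <- f
    kl <- c(kl, sum(f * log(f / target)))
    if (eta == 0) next
    ## raising a type's correction lowers Delta-G of sequences using
    ## it (the correction is subtracted with e_ref), i.e. favours the
    ## type; over-represented types therefore get their correction
    ## lowered
    upd <- -eta * log(f / target)
    unfolded$correction[types] <- unfolded$correction[types] + upd
  }
  list(unfolded = unfolded, divergence = kl, composition = comp)
}
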