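## Heuristic sequence/rotamer optimization over the precomputed
## energy matrix, plus the restrained, rotamer-only, profile-sampled
## and random-identity sequence generators used in ensemble analyses.

#' Design run configuration
#'
#' @param n_cycles number of independent heuristic cycles.  Full-scale
#'   runs use hundreds of thousands; the desk-scale default is 1000.
#' @param max_passes cap on position sweeps per cycle (default 50).
#' @param seed RNG seed; every cycle derives its own stream from it,
#'   so results are reproducible and order-independent.
#' @param select_k ensemble size to keep (lowest energies; default
#'   `min(1000, n_cycles)`).
#' @param restraint_alphabet optional reduced-alphabet id for
#'   flavor-restrained optimization.
#' @param frozen_overrides optional named map position -> type forced
#'   at that position (e.g. substrate-binding positions reset to
#'   native).
#' @return list of class `design_config`.
#' @export
design_config <- function(n_cycles = 1000, max_passes = 50, seed = 1,
                          select_k = min(1000, n_cycles),
                          restraint_alphabet = NULL,
                          frozen_overrides = NULL) {
  stopifnot(n_cycles >= 1, max_passes >= 1)
  structure(list(n_cycles = n_cycles, max_passes = max_passes,
                 seed = seed, select_k = select_k,
                 restraint_alphabet = restraint_alphabet,
                 frozen_overrides = frozen_overrides),
            class = "design_config")
}

## Allowed state indices per position, honouring frozen_overrides and
## (optionally) a flavor restraint around a start state.
allowed_states <- function(em, config = NULL, flavor_of = NULL,
                           start = NULL) {
  keys <- as.character(em$positions)
  out <- list()
  for (k in keys) {
    st <- em$states[[k]]
    idx <- seq_len(nrow(st))
    ov <- config$frozen_overrides[[k]]
    if (!is.null(ov)) {
      sel <- idx[st$aa == ov]
      if (length(sel) == 0)
        stop("override type ", ov, " has no states at position ", k)
      idx <- sel
    }
    out[[k]] <- idx
  }
  if (!is.null(flavor_of)) {
    ab <- flavor_of
    for (ii in seq_along(keys)) {
      k <- keys[ii]
      st <- em$states[[k]]
      start_aa <- st$aa[start[ii]]
      fl <- ab[[start_aa]]
      sel <- out[[k]][ab[st$aa[out[[k]]]] == fl]
      if (length(sel) == 0) next  # no same-flavor candidate: skip
      out[[k]] <- sel
    }
  }
  out
}

## One greedy sweep pass; returns updated assignment.
sweep_once <- function(em, assignment, allowed) {
  keys <- as.character(em$positions)
  L <- length(keys)
  for (ii in seq_len(L)) {
    k <- keys[ii]
    cand <- allowed[[k]]
    if (length(cand) <= 1) { assignment[ii] <- cand[1]; next }
    ## delta energy of each candidate: singleton + pair terms vs rest
    e <- em$tot[[k]][cand]
    for (jj in seq_len(L)) {
      if (jj == ii) next
      b <- pair_block(em, em$positions[ii], em$positions[jj])
      if (!is.null(b)) e <- e + b[cand, assignment[jj]]
    }
    assignment[ii] <- cand[which.min(e)]  # ties: lowest state index
  }
  assignment
}

#' One heuristic design cycle
#'
#' Starts from a random sequence/rotamer assignment and sweeps the
#' positions in ascending order; at each position the (type, rotamer)
#' state minimizing the total folding free energy given the rest is
#' chosen (ties break to the lowest state index).  Sweeps repeat until
#' a full pass changes nothing or `max_passes` is reached.
#'
#' @param em a `pair_energy_matrix`.
#' @param config a [design_config()].
#' @param rng_seed seed for this cycle's random start.
#' @param flavor_of optional [reduced_alphabet()] restraining each
#'   position to the flavor of its start type.
#' @param start optional start assignment (state indices); random if
#'   NULL.
#' @param fixed_types optional character vector (one per position)
#'   fixing the type at every position (rotamer-only optimization).
#' @return list of class `design_record`: `assignment`, `sequence`,
#'   `rotamers`, `dg_fold`, `breakdown`, `n_passes`.
#' @export
heuristic_cycle <- function(em, config = design_config(),
                            rng_seed = config$seed, flavor_of = NULL,
                            start = NULL, fixed_types = NULL) {
  keys <- as.character(em$positions)
  L <- length(keys)
  allowed <- allowed_states(em, config)
  if (!is.null(fixed_types)) {
    for (ii in seq_len(L)) {
      k <- keys[ii]
      sel <- allowed[[k]][em$states[[k]]$aa[allowed[[k]]] ==
                          fixed_types[ii]]
      if (length(sel) == 0)
        stop("type ", fixed_types[ii], " not available at position ", k)
      allowed[[k]] <- sel
    }
  }
  if (is.null(start)) {
    start <- integer(L)
    with_seed(rng_seed, {
      for (ii in seq_len(L))
        start[ii] <- allowed[[keys[ii]]][
          sample.int(length(allowed[[keys[ii]]]), 1)]
    })
  }
  if (!is.null(flavor_of))
    allowed <- allowed_states(em, config, flavor_of = flavor_of,
                              start = start)
  a <- start
  e_prev <- matrix_total(em, a)
  n_pass <- 0
  repeat {
    n_pass <- n_pass + 1
    a_new <- sweep_once(em, a, allowed)
    e_new <- matrix_total(em, a_new)
    if (identical(a_new, a) || n_pass >= config$max_passes) {
      a <- a_new; e_prev <- e_new
      break
    }
    a <- a_new; e_prev <- e_new
  }
  as_record(em, a, n_pass)
}

as_record <- function(em, a, n_pass = NA_integer_, cycle = NA_integer_) {
  keys <- as.character(em$positions)
  aa <- vapply(seq_along(keys),
               function(ii) em$states[[keys[ii]]]$aa[a[ii]], "")
  rot <- vapply(seq_along(keys),
                function(ii) em$states[[keys[ii]]]$rot[a[ii]],
                integer(1))
  bd <- fold_free_energy(em, a)
  structure(list(assignment = a, sequence = paste(aa, collapse = ""),
                 rotamers = rot, dg_fold = bd$total, breakdown = bd,
                 n_passes = n_pass, cycle_id = cycle),
            class = "design_record")
}

#' @export
print.design_record <- function(x, ...) {
  cat(x$sequence, sprintf(" dG = %.3f kcal/mol (%s passes)\n",
                          x$dg_fold, x$n_passes))
  invisible(x)
}

#' Run a design: many independent heuristic cycles
#'
#' Each cycle gets a seed derived from `config$seed` and its cycle
#' number, so the ensemble is reproducible and independent of
#' execution order.  The `select_k` lowest-energy records are kept,
#' sorted ascending (ties: sequence, then rotamer string).
#'
#' @param em a `pair_energy_matrix`.
#' @param config a [design_config()].
#' @return object of class `design_ensemble`: list with `records`
#'   (data.frame: cycle, sequence, rotamers, dg_fold, vdw, coulomb,
#'   surface, unfolded, n_passes), `config`, `provenance`.
#' @export
run_design <- function(em, config = design_config()) {
  recs <- vector("list", config$n_cycles)
  for (cy in seq_len(config$n_cycles)) {
    r <- heuristic_cycle(em, config,
                         rng_seed = derive_seed(config$seed, cy))
    recs[[cy]] <- data.frame(
      cycle = cy, sequence = r$sequence,
      rotamers = paste(r$rotamers, collapse = ","),
      dg_fold = r$dg_fold, vdw = r$breakdown$vdw,
      coulomb = r$breakdown$coulomb, surface = r$breakdown$surface,
      unfolded = r$breakdown$unfolded, n_passes = r$n_passes,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$dg_fold, tab$sequence, tab$rotamers), ]
  k <- min(config$select_k, nrow(tab))
  tab <- tab[seq_len(k), ]
  rownames(tab) <- NULL
  structure(list(records = tab, config = config,
                 provenance = list(config_hash = hash_object(config),
                                   matrix_hash = hash_object(em))),
            class = "design_ensemble")
}

#' @export
print.design_ensemble <- function(x, ...) {
  cat("Design ensemble:", nrow(x$records), "records | best dG =",
      round(x$records$dg_fold[1], 3), "kcal/mol\n")
  invisible(x)
}

#' Flavor-restrained optimization of a start sequence
#'
#' As [heuristic_cycle()], but each position may only visit types
#' sharing the start type's flavor under `alphabet` (nine classes by
#' default); e.g. a Phe may become Tyr but not Trp.  Positions whose
#' flavor has no designable member keep their start state.
#'
#' @param em a `pair_energy_matrix`.
#' @param start_assignment state indices of the start state.
#' @param config a [design_config()].
#' @param alphabet a [reduced_alphabet()].
#' @return a `design_record`.
#' @export
restrained_cycle <- function(em, start_assignment,
                             config = design_config(),
                             alphabet = reduced_alphabet("nine")) {
  heuristic_cycle(em, config, flavor_of = alphabet,
                  start = start_assignment)
}

#' Rotamer-only optimization of a fixed sequence
#'
#' Sweeps choose the best rotamer per position with the amino-acid
#' types held fixed (the protocol applied to native and
#' profile-sampled sequences before their energies are compared to
#' designed ones).
#'
#' @param em a `pair_energy_matrix`.
#' @param sequence character string over the matrix's state types.
#' @param config a [design_config()].
#' @param rng_seed seed for the random rotamer start.
#' @return a `design_record`.
#' @export
rotamer_only_optimize <- function(em, sequence,
                                  config = design_config(),
                                  rng_seed = config$seed) {
  seq_vec <- strsplit(sequence, "")[[1]]
  if (length(seq_vec) != length(em$positions))
    stop("sequence length != matrix positions")
  heuristic_cycle(em, config, rng_seed = rng_seed,
                  fixed_types = seq_vec)
}

#' Sample sequences from a column profile
#'
#' Independent per-column draws from the profile's (gap-excluded,
#' renormalized) type frequencies: the marginals of the source
#' alignment are preserved but all inter-position correlations are
#' destroyed.  Positions listed in `frozen` are forced to their given
#' type.
#'
#' @param profile L x types frequency matrix (rows sum to 1 over
#'   non-gap types), e.g. from [msa_profile()].
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param frozen optional named character vector position -> type.
#' @return character vector of sequences.
#' @export
sample_from_profile <- function(profile, n, seed = 1, frozen = NULL) {
  L <- nrow(profile)
  types <- colnames(profile)
  keep <- setdiff(types, "-")
  with_seed(derive_seed(seed, "profile_sample"), {
    out <- matrix("", n, L)
    for (l in seq_len(L)) {
      f <- profile[l, keep]
      if (sum(f) <= 0) stop("column ", l, " has no residue mass")
      f <- f / sum(f)
      out[, l] <- sample(keep, n, replace = TRUE, prob = f)
    }
    if (!is.null(frozen))
      for (k in names(frozen)) out[, as.integer(k)] <- frozen[[k]]
    apply(out, 1, paste, collapse = "")
  })
}

#' Random sequences at a target identity to the template
#'
#' Each sequence keeps the native type at `preserve` positions and at
#' enough additional random positions to reach the target identity;
#' all other positions draw uniformly from the 19 non-native types
#' (C, G and P are excluded at designable positions).
#'
#' @param template a `backbone_template`.
#' @param target_identity percent identity (0 < t <= 100).
#' @param n batch size.
#' @param seed RNG seed.
#' @param preserve integer positions always kept native (e.g.
#'   conserved cysteines); frozen template positions are always
#'   preserved.
#' @return character vector of sequences.
#' @export
random_identity_sequences <- function(template, target_identity, n,
                                      seed = 1, preserve = integer(0)) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target identity must be in (0, 100]")
  pos <- template$positions
  L <- nrow(pos)
  fixed <- union(pos$index[!pos$designable], preserve)
  fixed_ii <- match(fixed, pos$index)
  n_keep_total <- round(target_identity / 100 * L)
  if (n_keep_total < length(fixed))
    stop("target identity below the preserved-only identity")
  free_ii <- setdiff(seq_len(L), fixed_ii)
  n_extra <- n_keep_total - length(fixed_ii)
  with_seed(derive_seed(seed, "random_identity"), {
    vapply(seq_len(n), function(s) {
      v <- pos$native
      mut_ii <- sample(free_ii, length(free_ii) - n_extra)
      for (ii in mut_ii) {
        allowed <- setdiff(AA_DESIGNABLE, pos$native[ii])
        v[ii] <- sample(allowed, 1)
      }
      paste(v, collapse = "")
    }, character(1))
  })
}

#' Mean identity per energy bin
#'
#' Bins ensemble records by folding free energy (default 10 kcal/mol
#' windows) and reports the per-bin mean identity to a reference
#' sequence.
#'
#' @param ensemble a `design_ensemble` (or its records data.frame).
#' @param reference reference sequence (e.g. the native template
#'   sequence).
#' @param bin_width bin width, kcal/mol (default 10).
#' @return data.frame: `bin_lo`, `bin_hi`, `n`, `mean_identity`.
#' @export
identity_vs_energy <- function(ensemble, reference, bin_width = 10) {
  recs <- if (inherits(ensemble, "design_ensemble")) ensemble$records
          else ensemble
  if (nrow(recs) == 0) stop("empty ensemble")
  ids <- vapply(recs$sequence, identity_score, numeric(1),
                seq_b = reference, USE.NAMES = FALSE)
  lo <- floor(min(recs$dg_fold) / bin_width) * bin_width
  bins <- floor((recs$dg_fold - lo) / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(bin_lo = lo + b * bin_width,
               bin_hi = lo + (b + 1) * bin_width,
               n = sum(sel), mean_identity = mean(ids[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Write a design ensemble to FASTA and TSV
#'
#' FASTA headers carry the record's energy; the TSV holds the full
#' component breakdown.  Output is byte-stable for a fixed ensemble.
#'
#' @param ensemble a `design_ensemble`.
#' @param fasta,tsv output paths (NULL to skip either).
#' @return invisible list of written paths.
#' @export
write_ensemble <- function(ensemble, fasta = NULL, tsv = NULL) {
  recs <- ensemble$records
  if (!is.null(fasta)) {
    nm <- sprintf("design_%05d dg_fold=%.4f", recs$cycle, recs$dg_fold)
    write_fasta(stats::setNames(recs$sequence, nm), fasta)
  }
  if (!is.null(tsv))
    utils::write.table(recs, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(fasta = fasta, tsv = tsv))
}
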