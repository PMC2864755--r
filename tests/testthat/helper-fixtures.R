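## Shared fixtures, built once per test session and cached.

.fix_cache <- new.env(parent = emptyenv())

fix_cached <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

## 8-residue helix with a mixed sequence (no frozen positions).
fix_helix <- function() fix_cached("helix", function()
  make_structure("helix", 8, sequence = "ASLVKDEF", seed = 2))

## 6-residue strand containing a frozen Gly.
fix_strand_g <- function() fix_cached("strand_g", function()
  make_structure("strand", 6, sequence = "ASVGLA", seed = 3))

## Rigid-rotamer energy model without a cutoff (oracle conditions).
fix_model_rigid <- function() energy_model(pair_min_steps = 0,
                                           cutoff = 1e6)

## Small energy matrix over 3 types on the frozen-Gly strand.
fix_matrix_small <- function() fix_cached("em_small", function()
  build_energy_matrix(fix_strand_g()$template,
                      builtin_rotamer_library(),
                      fix_model_rigid(), unfolded = NULL,
                      allowed_types = c("A", "S", "V")))

## Random 20-atom clusters with a nonbonded-contact minimum
## separation, emulating heavy-atom packing densities.
random_cluster <- function(n = 20, dmin = 3.5, box = 12, seed = 1) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    p <- runif(3, 0, box)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3,
                                       byrow = TRUE))^2))) >= dmin)
      pts <- rbind(pts, p)
  }
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             radius = runif(n, 1.5, 1.9))
}

## Peaked per-column distributions over a type set: a conserved-ish
## synthetic family profile.
peaked_columns <- function(L, types, seed = 1) {
  set.seed(seed)
  lapply(seq_len(L), function(l) {
    f <- rep(1e-6, 20)
    names(f) <- AA_ALPHABET
    picks <- sample(types, min(3, length(types)))
    f[picks] <- c(0.6, 0.25, 0.15)[seq_along(picks)]
    f / sum(f)
  })
}
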