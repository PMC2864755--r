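## Synthetic fixtures: ideal-geometry structures, planted-correlation
## alignments, and homologue/decoy search databases.  Everything the
## test-suite and examples need is generated here deterministically
## from a seed -- no external downloads.

## Ideal backbone geometry (Angstrom / degrees).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_c_n_ca = 121.7, ang_n_ca_c = 111.2,
                ang_ca_c_n = 116.2, ang_ca_c_o = 120.8, omega = 180)

phi_psi_for <- function(kind, length) {
  helix <- c(-57, -47); strand <- c(-119, 113)
  switch(kind,
    helix = matrix(rep(helix, length), ncol = 2, byrow = TRUE),
    strand = matrix(rep(strand, length), ncol = 2, byrow = TRUE),
    hairpin = {
      if (length < 6) stop("hairpin needs length >= 6")
      n1 <- floor((length - 2) / 2)
      n2 <- length - 2 - n1
      rbind(matrix(rep(strand, n1), ncol = 2, byrow = TRUE),
            matrix(c(-60, -30, -90, 0), ncol = 2, byrow = TRUE),
            matrix(rep(strand, n2), ncol = 2, byrow = TRUE))
    },
    stop("unknown fixture kind '", kind, "'"))
}


## Build a backbone_template with ideal peptide geometry at the given
## per-residue (phi, psi) values; side-chain chis default to 180 and
## native C/P side chains are frozen at that conformation.
ideal_template <- function(pp, seq_vec) {
  L <- base::length(seq_vec)
  g <- BB_GEOM
  N <- matrix(NA_real_, L, 3); CA <- matrix(NA_real_, L, 3)
  C <- matrix(NA_real_, L, 3); O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  if (L > 1) for (i in 2:L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$c_n, g$ang_ca_c_n, pp[i - 1, 2])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$ca_c, g$ang_n_ca_c, pp[i, 1])
  }
  for (i in 1:L)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, pp[i, 2] + 180)
  bb_rows <- list(); frozen <- list(); chis <- list()
  for (i in 1:L) {
    aa <- seq_vec[i]
    h <- if (aa != "P")
      N[i, ] + 0.98 * unit(unit(N[i, ] - CA[i, ]) + unit(N[i, ] - C[i, ]))
    nm <- c("N", if (aa != "P") "H", "CA", "C", "O")
    xyz <- rbind(N[i, ], if (aa != "P") h, CA[i, ], C[i, ], O[i, ])
    bb_rows[[i]] <- data.frame(resno = i, name = nm,
                               element = substr(nm, 1, 1),
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               stringsAsFactors = FALSE)
    k <- AA_N_CHI[[aa]]
    ch <- if (k > 0) rep(180, k) else numeric(0)
    if (k > 0) chis[[as.character(i)]] <- ch
    if (aa %in% AA_SPECIAL && aa != "G") {
      sc <- build_sidechain(aa, N[i, ], CA[i, ], C[i, ], ch)
      frozen[[as.character(i)]] <- sc[, c("name", "element", "x", "y", "z")]
    }
  }
  bb <- do.call(rbind, bb_rows)
  positions <- data.frame(index = 1:L, native = seq_vec,
                          stringsAsFactors = FALSE)
  backbone_template(positions, bb, frozen, chain = "A",
                    native_chis = chis)
}

#' Generate an ideal-geometry structure fixture
#'
#' Builds a backbone with ideal peptide geometry at canonical phi/psi
#' (helix -57/-47, strand -119/113, or a two-strand hairpin), places
#' side chains from the built-in rotamer library, optionally jitters
#' all coordinates with Gaussian noise, and returns both the in-memory
#' template and a PDB file.
#'
#' @param kind `"helix"`, `"strand"` or `"hairpin"`.
#' @param length number of residues (>= 2).
#' @param sequence one-letter string (default poly-Ala).
#' @param seed RNG seed (used for noise).
#' @param noise_sigma coordinate jitter standard deviation, Angstrom.
#' @param path output PDB path (default: tempfile).
#' @return list with `template` (a `backbone_template`), `path` (PDB
#'   file), and `spec` (the arguments).
#' @export
make_structure <- function(kind = c("helix", "strand", "hairpin"),
                           length = 10,
                           sequence = strrep("A", length),
                           seed = 1, noise_sigma = 0,
                           path = tempfile(fileext = ".pdb")) {
  kind <- match.arg(kind)
  if (length < 2) stop("length must be >= 2")
  seq_vec <- strsplit(sequence, "")[[1]]
  if (base::length(seq_vec) != length)
    stop("sequence length != length")
  pp <- phi_psi_for(kind, length)
  tpl <- ideal_template(pp, seq_vec)
  if (noise_sigma > 0) {
    bb <- tpl$bb_atoms
    with_seed(derive_seed(seed, "structure_noise"), {
      bb$x <- bb$x + stats::rnorm(nrow(bb), 0, noise_sigma)
      bb$y <- bb$y + stats::rnorm(nrow(bb), 0, noise_sigma)
      bb$z <- bb$z + stats::rnorm(nrow(bb), 0, noise_sigma)
    })
    tpl <- backbone_template(tpl$positions[, c("index", "native")], bb,
                             tpl$frozen, chain = tpl$chain,
                             native_chis = tpl$native_chis)
  }
  write_pdb(tpl, path)
  list(template = tpl, path = path,
       spec = list(kind = kind, length = length, sequence = sequence,
                   seed = seed, noise_sigma = noise_sigma))
}

#' Generate a planted-correlation multiple sequence alignment
#'
#' Draws `n_sequences` of length `length`.  Columns are sampled
#' independently from per-column background distributions, except:
#' coupled position pairs are drawn jointly from a supplied joint
#' distribution, and subfamily-defining patterns overwrite their
#' positions according to mixture labels.  The ground truth (coupled
#' pairs, subfamily labels, patterns) is returned for assertions.
#'
#' @param n_sequences number of sequences.
#' @param length alignment columns.
#' @param background either a single named frequency vector over
#'   amino-acid types, or a list of per-column vectors.
#' @param coupled list of couplings, each
#'   `list(i =, j =, joint = matrix)` with the joint distribution's
#'   dimnames giving the types.
#' @param subfamilies optional `list(weights =, patterns = list)`;
#'   each pattern is `list(positions =, types =)`.
#' @param gap_rate per-cell probability of a gap.
#' @param seed RNG seed.
#' @return list `msa` (an [msa] object), `truth` (list with
#'   `coupled`, `labels`, `patterns`).
#' @export
make_planted_msa <- function(n_sequences, length,
                             background = NULL, coupled = list(),
                             subfamilies = NULL, gap_rate = 0,
                             seed = 1) {
  if (is.null(background)) background <- aa_background()
  cols <- if (is.list(background)) background
          else rep(list(background), length)
  if (base::length(cols) != length)
    stop("need one background distribution per column")
  for (cp in coupled) {
    jt <- cp$joint
    if (abs(sum(jt) - 1) > 1e-8)
      stop("coupling joint distribution must sum to 1")
  }
  labels <- NULL
  with_seed(derive_seed(seed, "planted_msa"), {
    m <- matrix(NA_character_, n_sequences, length)
    for (l in seq_len(length)) {
      f <- cols[[l]] / sum(cols[[l]])
      m[, l] <- sample(names(f), n_sequences, replace = TRUE, prob = f)
    }
    for (cp in coupled) {
      jt <- cp$joint
      cells <- expand.grid(a = rownames(jt), b = colnames(jt),
                           stringsAsFactors = FALSE)
      pick <- sample(nrow(cells), n_sequences, replace = TRUE,
                     prob = as.vector(jt))
      m[, cp$i] <- cells$a[pick]
      m[, cp$j] <- cells$b[pick]
    }
    if (!is.null(subfamilies)) {
      w <- subfamilies$weights
      if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
      labels <- sample(seq_along(w), n_sequences, replace = TRUE, prob = w)
      for (s in seq_along(w)) {
        pat <- subfamilies$patterns[[s]]
        rows <- which(labels == s)
        for (k in seq_along(pat$positions))
          m[rows, pat$positions[k]] <- pat$types[k]
      }
    }
    if (gap_rate > 0) {
      gaps <- matrix(stats::runif(n_sequences * length) < gap_rate,
                     n_sequences, length)
      m[gaps] <- "-"
    }
  })
  out_msa <- msa(apply(m, 1, paste, collapse = ""))
  list(msa = out_msa,
       truth = list(coupled = coupled, labels = labels,
                    patterns = subfamilies$patterns))
}

#' Generate a labelled homologue/decoy search database
#'
#' True targets are sampled from a source alignment or sequence set
#' (gaps stripped, optional point mutations); decoys are either
#' residue shuffles of true targets or i.i.d. draws from the
#' background composition.  Labels are returned for exact
#' recall/false-positive scoring.
#'
#' @param source an [msa], or character vector of sequences.
#' @param n_true number of true targets.
#' @param n_decoys number of decoys.
#' @param decoy_model `"shuffle"` or `"background"`.
#' @param mutation_rate per-residue substitution probability applied
#'   to true targets.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return list `sequences` (named character vector), `labels`
#'   (logical: TRUE = homologue), `path` (FASTA or NULL).
#' @export
make_search_database <- function(source, n_true, n_decoys,
                                 decoy_model = c("shuffle", "background"),
                                 mutation_rate = 0, seed = 1,
                                 path = NULL) {
  decoy_model <- match.arg(decoy_model)
  seqs <- if (inherits(source, "msa")) msa_sequences(source) else source
  seqs <- gsub("-", "", seqs)
  if (n_true > base::length(seqs))
    stop("n_true exceeds available source sequences")
  bg <- aa_background()
  with_seed(derive_seed(seed, "search_db"), {
    idx <- sample(base::length(seqs), n_true)
    true_seqs <- seqs[idx]
    if (mutation_rate > 0) {
      true_seqs <- vapply(true_seqs, function(s) {
        v <- strsplit(s, "")[[1]]
        hit <- stats::runif(base::length(v)) < mutation_rate
        v[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    decoys <- character(0)
    if (n_decoys > 0) {
      decoys <- vapply(seq_len(n_decoys), function(k) {
        if (decoy_model == "shuffle") {
          s <- seqs[[1 + (k - 1) %% base::length(seqs)]]
          paste(sample(strsplit(s, "")[[1]]), collapse = "")
        } else {
          n <- nchar(seqs[[1 + (k - 1) %% base::length(seqs)]])
          paste(sample(names(bg), n, replace = TRUE, prob = bg),
                collapse = "")
        }
      }, character(1))
    }
  })
  all_seqs <- c(true_seqs, decoys)
  names(all_seqs) <- c(sprintf("true_%03d", seq_len(n_true)),
                       if (n_decoys > 0)
                         sprintf("decoy_%03d", seq_len(n_decoys)))
  labels <- c(rep(TRUE, n_true), rep(FALSE, n_decoys))
  names(labels) <- names(all_seqs)
  if (!is.null(path)) write_fasta(all_seqs, path)
  list(sequences = all_seqs, labels = labels, path = path)
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences) %||% sprintf("seq_%d", seq_along(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences))
    writeLines(c(paste0(">", nm[i]), sequences[[i]]), con)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
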