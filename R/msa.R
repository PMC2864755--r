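## Multiple sequence alignments and ensemble statistics: identity and
## BLOSUM-profile similarity scores, reduced-alphabet positional
## entropies, mutual-information covariance matrices, and correlated
## flavor-pattern extraction.

#' Construct an MSA
#'
#' @param sequences character vector of equal-length aligned sequences
#'   over the 20 types plus the gap character `-`.
#' @param ids optional sequence names.
#' @return object of class `msa`: list with `seqs` (character matrix
#'   n x L) and `ids`.
#' @export
msa <- function(sequences, ids = names(sequences)) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must have equal lengths")
  m <- do.call(rbind, strsplit(sequences, ""))
  bad <- !m %in% c(AA_ALPHABET, "-", "X")
  if (any(bad))
    stop("unexpected characters in alignment: ",
         paste(unique(m[bad]), collapse = ", "))
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sequences))
  structure(list(seqs = m, ids = ids), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", nrow(x$seqs), "sequences x", ncol(x$seqs), "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file into an MSA
#' @param path aligned FASTA file.
#' @return an `msa`.
#' @export
read_msa <- function(path) {
  s <- read_fasta(path)
  msa(toupper(s), ids = names(s))
}

#' Sequences of an MSA
#' @param x an `msa`.
#' @return character vector.
#' @export
msa_sequences <- function(x)
  stats::setNames(apply(x$seqs, 1, paste, collapse = ""), x$ids)

#' Number of columns of an MSA
#' @param x an `msa`.
#' @export
msa_length <- function(x) ncol(x$seqs)

#' Per-column frequency profile
#'
#' @param x an `msa`, a character matrix, or a character vector of
#'   equal-length (ungapped or gapped) sequences.
#' @param pseudocount added to every cell before normalization
#'   (default 0).
#' @param gaps include the gap symbol as a 21st column (default TRUE).
#' @return L x types matrix of frequencies; rows sum to 1.
#' @export
msa_profile <- function(x, pseudocount = 0, gaps = TRUE) {
  m <- as_seq_matrix(x)
  types <- if (gaps) c(AA_ALPHABET, "-") else AA_ALPHABET
  prof <- t(apply(m, 2, function(col) {
    if (!gaps) col <- col[col != "-"]
    cnt <- table(factor(col, levels = types)) + pseudocount
    as.numeric(cnt) / sum(cnt)
  }))
  colnames(prof) <- types
  prof
}

as_seq_matrix <- function(x) {
  if (inherits(x, "msa")) return(x$seqs)
  if (is.matrix(x)) return(x)
  if (inherits(x, "design_ensemble")) x <- x$records$sequence
  do.call(rbind, strsplit(x, ""))
}

#' Percent identity between two ungapped sequences
#'
#' @param seq_a,seq_b equal-length sequences.
#' @return 100 * matches / length.
#' @export
identity_score <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  100 * sum(a == b) / length(a)
}

#' Mean identity of an ensemble to a reference
#' @param sequences character vector (or `design_ensemble`).
#' @param reference reference sequence.
#' @return mean percent identity.
#' @export
mean_identity <- function(sequences, reference) {
  if (inherits(sequences, "design_ensemble"))
    sequences <- sequences$records$sequence
  mean(vapply(sequences, identity_score, numeric(1), seq_b = reference,
              USE.NAMES = FALSE))
}

#' Profile similarity score of a sequence against an MSA
#'
#' S = sum over positions l and types a of f_l(a) * B(seq_l, a),
#' where f_l are the MSA's column frequencies (gaps included as a
#' 21st symbol) and B is the substitution matrix with B(x, gap) =
#' the gap score (-5 by default).
#'
#' @param seq ungapped sequence, length = MSA columns.
#' @param x an `msa` (or precomputed profile matrix with a gap
#'   column).
#' @param matrix 21 x 21 substitution matrix from
#'   [blosum62_matrix()].
#' @return list: `score` (raw sum), `per_column` (length-L vector).
#' @export
similarity_score <- function(seq, x, matrix = blosum62_matrix()) {
  prof <- if (is.matrix(x)) x else msa_profile(x, gaps = TRUE)
  v <- strsplit(seq, "")[[1]]
  if (length(v) != nrow(prof))
    stop("sequence length (", length(v),
         ") != alignment columns (", nrow(prof), ")")
  types <- colnames(prof)
  per <- vapply(seq_along(v), function(l)
    sum(prof[l, ] * matrix[v[l], types]), numeric(1))
  list(score = sum(per), per_column = per)
}

#' Similarity scores for a set of sequences
#' @param sequences character vector (or `design_ensemble`).
#' @inheritParams similarity_score
#' @return numeric vector of raw scores.
#' @export
similarity_scores <- function(sequences, x,
                              matrix = blosum62_matrix()) {
  if (inherits(sequences, "design_ensemble"))
    sequences <- sequences$records$sequence
  prof <- if (is.matrix(x)) x else msa_profile(x, gaps = TRUE)
  vapply(sequences, function(s) similarity_score(s, prof, matrix)$score,
         numeric(1), USE.NAMES = FALSE)
}

#' Overlap of a score sample with a reference score sample
#'
#' Percentage of `scores_a` lying at or above the minimum of
#' `scores_b` (the adopted definition), or the two-sample overlap
#' coefficient of the score distributions (`method = "coefficient"`,
#' estimated from histograms on a common grid).
#'
#' @param scores_a,scores_b numeric samples.
#' @param method `"above_min"` (default) or `"coefficient"`.
#' @return percent in [0, 100].
#' @export
score_overlap <- function(scores_a, scores_b,
                          method = c("above_min", "coefficient")) {
  method <- match.arg(method)
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  if (method == "above_min")
    return(100 * mean(scores_a >= min(scores_b)))
  rng <- range(c(scores_a, scores_b))
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 41)
  ha <- hist(scores_a, breaks = brk, plot = FALSE)$counts
  hb <- hist(scores_b, breaks = brk, plot = FALSE)$counts
  100 * sum(base::pmin(ha / sum(ha), hb / sum(hb)))
}

#' Reduced-alphabet positional entropy
#'
#' S_l = -sum_t f_l(t) ln f_l(t) over the classes of `alphabet`,
#' with gaps excluded and columns renormalized.  The exponentiated
#' entropy e^S is the effective number of classes used at the
#' position (1 = conserved, |alphabet| = uniform).
#'
#' @param x an `msa`, matrix, or sequence vector.
#' @param alphabet a [reduced_alphabet()] (nine classes by default).
#' @param positions optional column subset (e.g. core positions).
#' @param summary `"exp"` (default: mean of e^S over positions) or
#'   `"entropy"` (exp of the mean S).
#' @return list: `S` (per column, nats), `expS`, `mean_exp` (summary),
#'   `excluded` (all-gap columns).
#' @export
positional_entropy <- function(x, alphabet = reduced_alphabet("nine"),
                               positions = NULL,
                               summary = c("exp", "entropy")) {
  summary <- match.arg(summary)
  m <- as_seq_matrix(x)
  L <- ncol(m)
  S <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    col <- m[, l]
    col <- col[col != "-" & col != "X"]
    if (length(col) == 0) next
    cls <- alphabet[col]
    f <- table(cls) / length(cls)
    S[l] <- -sum(f * log(f))
  }
  excluded <- which(is.na(S))
  use <- if (is.null(positions)) seq_len(L) else positions
  use <- setdiff(use, excluded)
  mean_exp <- if (summary == "exp") mean(exp(S[use]))
              else exp(mean(S[use]))
  list(S = S, expS = exp(S), mean_exp = mean_exp, excluded = excluded)
}

#' Mutual-information covariance matrix
#'
#' C_ij = sum_{a,b} P_ij(a,b) ln[P_ij(a,b) / (P_i(a) P_j(b))] over
#' classes of the reduced alphabet, probabilities by counting (gapped
#' rows dropped per column pair); absent types or pairs contribute 0.
#' The diagonal holds the column entropies.
#'
#' @param x an `msa`, matrix, or sequence vector (>= 2 sequences).
#' @param alphabet a [reduced_alphabet()].
#' @return L x L symmetric matrix of class `covariance_matrix`
#'   (nats), attribute `alphabet`.
#' @export
mutual_information_matrix <- function(x,
                                      alphabet = reduced_alphabet("nine")) {
  m <- as_seq_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  L <- ncol(m)
  red <- matrix(alphabet[m], nrow(m), L)
  red[m == "-" | m == "X"] <- NA
  C <- matrix(0, L, L)
  ent <- numeric(L)
  for (l in seq_len(L)) {
    col <- red[, l]; col <- col[!is.na(col)]
    if (length(col) == 0) next
    f <- table(col) / length(col)
    ent[l] <- -sum(f * log(f))
  }
  diag(C) <- ent
  if (L > 1) for (i in 1:(L - 1)) for (j in (i + 1):L) {
    ok <- !is.na(red[, i]) & !is.na(red[, j])
    if (sum(ok) < 2) next
    tab <- table(red[ok, i], red[ok, j])
    pj <- tab / sum(tab)
    pa <- rowSums(pj); pb <- colSums(pj)
    nz <- pj > 0
    mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
    C[i, j] <- C[j, i] <- mi
  }
  structure(C, class = c("covariance_matrix", "matrix", "array"),
            alphabet = attr(alphabet, "id"))
}

#' Most frequent flavor patterns at selected positions
#'
#' Reduces each sequence to its flavor classes at `positions` and
#' returns the `k` most frequent patterns with their ensemble
#' frequencies (ties broken lexicographically).
#'
#' @param x sequences / `msa` / `design_ensemble`.
#' @param positions integer column indices.
#' @param alphabet a [reduced_alphabet()].
#' @param k number of patterns (> 0).
#' @return data.frame of class `pattern_set`: `pattern`
#'   (slash-separated class labels), `frequency`, `count`; attribute
#'   `positions`.
#' @export
top_patterns <- function(x, positions,
                         alphabet = reduced_alphabet("nine"), k = 5) {
  if (k <= 0) stop("k must be positive")
  m <- as_seq_matrix(x)
  if (any(positions < 1 | positions > ncol(m)))
    stop("pattern positions out of range")
  red <- matrix(alphabet[m[, positions, drop = FALSE]], nrow(m))
  pat <- apply(red, 1, paste, collapse = "/")
  tab <- sort(table(pat), decreasing = TRUE)
  ord <- base::order(-as.numeric(tab), names(tab))
  tab <- tab[ord]
  k <- min(k, length(tab))
  out <- data.frame(pattern = names(tab)[seq_len(k)],
                    frequency = as.numeric(tab)[seq_len(k)] / nrow(m),
                    count = as.numeric(tab)[seq_len(k)],
                    stringsAsFactors = FALSE)
  structure(out, positions = positions,
            alphabet = attr(alphabet, "id"),
            class = c("pattern_set", "data.frame"))
}

#' Subset sequences matching (or not matching) a flavor pattern
#'
#' @param x sequences / `msa` / `design_ensemble`.
#' @param pattern slash-separated class labels (a `pattern` entry of
#'   [top_patterns()]), or NULL with `complement_of` to select
#'   sequences matching none of a list of patterns.
#' @param positions the pattern's positions.
#' @param alphabet a [reduced_alphabet()].
#' @param complement_of optional character vector of patterns; when
#'   given, returns sequences matching none of them.
#' @return logical vector (selection mask) with the matching
#'   sequences as attribute `sequences`.
#' @export
subset_by_pattern <- function(x, pattern = NULL, positions,
                              alphabet = reduced_alphabet("nine"),
                              complement_of = NULL) {
  m <- as_seq_matrix(x)
  red <- matrix(alphabet[m[, positions, drop = FALSE]], nrow(m))
  pat <- apply(red, 1, paste, collapse = "/")
  sel <- if (!is.null(pattern)) pat == pattern
         else !pat %in% complement_of
  seqs <- apply(m[sel, , drop = FALSE], 1, paste, collapse = "")
  structure(sel, sequences = seqs)
}

#' Core positions of a template by relative accessibility
#'
#' A position is "core" when its side-chain accessible area in the
#' native structure is below `threshold` times the side chain's
#' isolated-residue accessible area.
#'
#' @param template a `backbone_template`.
#' @param threshold relative accessibility cutoff (default 0.2).
#' @param library rotamer library used to place missing side chains.
#' @param parameters a `parameter_set`.
#' @param probe probe radius, A.
#' @return integer vector of core position indices.
#' @export
core_positions <- function(template, threshold = 0.2,
                           library = builtin_rotamer_library(),
                           parameters = default_parameters(),
                           probe = 1.4) {
  atoms <- assemble_atoms(template, library = library,
                          parameters = parameters)
  areas <- sasa_exact(atoms, probe)
  out <- integer(0)
  for (p in template$positions$index) {
    sel <- atoms$resno == p & atoms$group == "sc"
    if (!any(sel)) next
    iso <- sasa_exact(atoms[sel, , drop = FALSE], probe)
    rel <- sum(areas[sel]) / max(sum(iso), 1e-9)
    if (rel < threshold) out <- c(out, p)
  }
  out
}
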