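## Position-specific scoring matrices and an internal profile search.
## PSSM scores are half-bit log-odds with pseudocounts against a fixed
## background; the search scores every database sequence by its best
## ungapped window and converts scores to E-values with a
## Karlin-Altschul style Gumbel null fitted to shuffled-database
## scores, so the whole retrieval protocol runs offline.

#' Build a PSSM from aligned sequences
#'
#' Per column: p_a = (c_a + beta * q_a) / (N + beta);
#' score = 2 * log2(p_a / q_a) (half-bits), kept unrounded internally.
#'
#' @param sequences character vector of aligned, equal-length
#'   sequences (gaps allowed; gap characters do not count).
#' @param background named background frequencies (default
#'   [aa_background()]).
#' @param pseudocount_weight beta > 0 (default 1).
#' @return object of class `pssm`: list with `scores` (L x 20,
#'   half-bits), `probs`, `consensus`, `background`, `beta`,
#'   `n_sequences`, `source_hash`.
#' @export
build_pssm <- function(sequences, background = aa_background(),
                       pseudocount_weight = 1) {
  if (length(sequences) < 1) stop("need at least one sequence")
  if (pseudocount_weight <= 0)
    stop("pseudocount_weight must be > 0 (beta = 0 gives infinite ",
         "log-odds for unobserved types)")
  if (any(background <= 0)) stop("zero background frequency")
  background <- background[AA_ALPHABET] / sum(background[AA_ALPHABET])
  m <- as_seq_matrix(sequences)
  L <- ncol(m)
  probs <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (l in seq_len(L)) {
    col <- m[, l]; col <- col[col %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    probs[l, ] <- (as.numeric(cnt) +
                   pseudocount_weight * background) /
                  (length(col) + pseudocount_weight)
  }
  scores <- 2 * log2(sweep(probs, 2, background, "/"))
  consensus <- AA_ALPHABET[apply(probs, 1, which.max)]
  structure(list(scores = scores, probs = probs,
                 consensus = paste(consensus, collapse = ""),
                 background = background, beta = pseudocount_weight,
                 n_sequences = length(sequences),
                 source_hash = hash_object(sequences)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM:", nrow(x$scores), "columns x 20 types | consensus",
      x$consensus, "\n")
  invisible(x)
}

#' Export a PSSM
#'
#' Dialects: `"ascii-pssm"` (search-tool style ASCII layout with the
#' consensus sequence and rounded integer half-bit scores),
#' `"tsv"` (L rows x 20 unrounded score columns), `"aligned-fasta"`
#' (re-emits the per-column most probable sequence set is not
#' possible from a profile, so this dialect writes the consensus;
#' pass the source sequences to export them instead).
#'
#' @param pssm a `pssm`.
#' @param path output file.
#' @param dialect one of `"ascii-pssm"`, `"tsv"`, `"aligned-fasta"`.
#' @param sequences source sequences for `"aligned-fasta"`.
#' @return `path`, invisibly.
#' @export
export_pssm <- function(pssm, path,
                        dialect = c("ascii-pssm", "tsv",
                                    "aligned-fasta"),
                        sequences = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- data.frame(position = seq_len(nrow(pssm$scores)),
                      consensus = strsplit(pssm$consensus, "")[[1]],
                      pssm$scores, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (dialect == "ascii-pssm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# half-bit position-specific scoring matrix",
                 paste0("# consensus ", pssm$consensus),
                 paste(c("pos", "aa", AA_ALPHABET), collapse = " ")),
               con)
    cons <- strsplit(pssm$consensus, "")[[1]]
    for (l in seq_len(nrow(pssm$scores)))
      writeLines(paste(c(l, cons[l],
                         round(pssm$scores[l, ])), collapse = " "),
                 con)
  } else {
    if (is.null(sequences))
      stop("aligned-fasta export needs the source sequences")
    write_fasta(stats::setNames(sequences,
                                sprintf("seq_%04d",
                                        seq_along(sequences))), path)
  }
  invisible(path)
}

#' Read a TSV-exported PSSM
#' @param path file written by [export_pssm()] with `dialect = "tsv"`.
#' @return a `pssm` (scores and consensus only).
#' @export
read_pssm_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  scores <- as.matrix(tab[, AA_ALPHABET])
  dimnames(scores) <- list(NULL, AA_ALPHABET)
  structure(list(scores = scores, probs = NULL,
                 consensus = paste(tab$consensus, collapse = ""),
                 background = aa_background(), beta = NA,
                 n_sequences = NA, source_hash = NA),
            class = "pssm")
}

## Best ungapped-window score of a PSSM against one sequence.
best_window_score <- function(scores, seq_vec) {
  L <- nrow(scores)
  n <- length(seq_vec)
  if (n < L) return(NA_real_)
  col <- match(seq_vec, AA_ALPHABET)
  best <- -Inf
  for (off in 0:(n - L)) {
    idx <- col[(off + 1):(off + L)]
    ok <- !is.na(idx)
    s <- sum(scores[cbind(which(ok), idx[ok])])
    if (s > best) best <- s
  }
  best
}

## Calibrate the score null: empirical survival within the observed
## range, and an extreme-value (Gumbel-type, asymptotically
## exponential) tail fitted by maximum likelihood to the exceedances
## over a high threshold (top `tail_frac` of the null sample).
fit_score_null <- function(x, tail_frac = 0.01) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(min(100, n), ceiling(tail_frac * n))
  u <- x[n - k + 1]
  exc <- x[x >= u] - u
  lambda <- max(mean(exc), 1e-6)   # ML rate of the exponential tail
  list(u = u, p_u = k / n, lambda = lambda, sorted = x, n = n)
}

## P(S >= s) under the calibrated null.
null_survival <- function(fit, s) {
  vapply(s, function(v) {
    if (v <= fit$u) {
      (fit$n - findInterval(v - 1e-12, fit$sorted)) / fit$n
    } else {
      fit$p_u * exp(-(v - fit$u) / fit$lambda)
    }
  }, numeric(1))
}

#' Search a sequence database with a PSSM
#'
#' Every target is scored by its best ungapped window; scores are
#' converted to E-values E(s) = N * P(S >= s) under a Gumbel null
#' fitted by maximum likelihood to best-window scores of
#' residue-shuffled copies of the database (`n_shuffles` per target,
#' seeded).  Hits with E <= `e_threshold` are returned sorted by
#' E-value.
#'
#' @param pssm a `pssm`.
#' @param database named character vector of sequences, or a FASTA
#'   path.
#' @param e_threshold E-value cutoff (default 0.1).
#' @param seed RNG seed for the shuffled null.
#' @param n_shuffles shuffles per target for the null fit (default 20).
#' @param null_fit optionally reuse a fit from a previous call
#'   (list `mu`, `beta`).
#' @return data.frame of class `search_hits`: `id`, `score`
#'   (half-bits), `evalue`; attributes `null_fit`, `n_database`,
#'   `n_skipped` (targets shorter than the profile).
#' @export
profile_search <- function(pssm, database, e_threshold = 0.1,
                           seed = 1, n_shuffles = 20,
                           null_fit = NULL) {
  if (is.character(database) && length(database) == 1 &&
      file.exists(database))
    database <- read_fasta(database)
  if (length(database) == 0) stop("empty database")
  sc <- pssm$scores
  tv <- strsplit(unname(database), "")
  raw <- vapply(tv, function(v) best_window_score(sc, v), numeric(1))
  n_skip <- sum(is.na(raw))
  if (all(is.na(raw))) {
    warning("profile is longer than every database sequence")
    out <- data.frame(id = character(0), score = numeric(0),
                      evalue = numeric(0))
    return(structure(out, class = c("search_hits", "data.frame"),
                     null_fit = NULL, n_database = length(database),
                     n_skipped = n_skip))
  }
  if (is.null(null_fit)) {
    null_scores <- numeric(0)
    with_seed(derive_seed(seed, "search_null"), {
      for (r in seq_len(n_shuffles)) {
        shuf <- lapply(tv, function(v) v[sample.int(length(v))])
        ns <- vapply(shuf, function(v) best_window_score(sc, v),
                     numeric(1))
        null_scores <- c(null_scores, ns[is.finite(ns)])
      }
    })
    null_fit <- fit_score_null(null_scores)
  }
  pval <- null_survival(null_fit, raw)
  ev <- length(database) * pval
  keep <- which(!is.na(raw) & ev <= e_threshold)
  out <- data.frame(id = names(database)[keep], score = raw[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out <- out[base::order(out$evalue, -out$score, out$id), ]
  rownames(out) <- NULL
  structure(out, class = c("search_hits", "data.frame"),
            null_fit = null_fit, n_database = length(database),
            n_skipped = n_skip)
}

#' Pattern-subset retrieval experiment
#'
#' For each flavor pattern: repeatedly sample `sample_size` ensemble
#' sequences matching the pattern, build a PSSM, search the database,
#' and record the union of retrieved targets.  An extra subset of
#' sequences matching no pattern is included, plus a pooled-ensemble
#' control whose number of repeats matches the total subset queries.
#' True/false positives are counted against the database labels.
#'
#' @param sequences ensemble sequences (or `design_ensemble`).
#' @param patterns a `pattern_set` from [top_patterns()].
#' @param database named character vector (homologues + decoys).
#' @param labels named logical vector: TRUE = true homologue.
#' @param alphabet the [reduced_alphabet()] of the patterns.
#' @param sample_size sequences per query profile (default 50;
#'   sampled with replacement if a subset is smaller).
#' @param repeats repeats per subset (default 10).
#' @param e_threshold retrieval E-value threshold (default 1).
#' @param seed RNG seed.
#' @return list of class `retrieval_report`: `per_subset`
#'   (data.frame: subset, n_subset, tp, fp), `cumulative` (tp, fp of
#'   the union over subsets), `pooled` (control tp, fp).
#' @export
pattern_retrieval_experiment <- function(sequences, patterns, database,
                                         labels,
                                         alphabet = reduced_alphabet("nine"),
                                         sample_size = 50, repeats = 10,
                                         e_threshold = 1, seed = 1) {
  if (nrow(patterns) == 0) stop("empty pattern list")
  if (inherits(sequences, "design_ensemble"))
    sequences <- sequences$records$sequence
  positions <- attr(patterns, "positions")
  subsets <- list()
  for (r in seq_len(nrow(patterns))) {
    sel <- subset_by_pattern(sequences, patterns$pattern[r], positions,
                             alphabet)
    subsets[[patterns$pattern[r]]] <- attr(sel, "sequences")
  }
  none <- subset_by_pattern(sequences, NULL, positions, alphabet,
                            complement_of = patterns$pattern)
  subsets[["none"]] <- attr(none, "sequences")
  ## one shared null fit (same database throughout)
  base_pssm <- build_pssm(sequences[seq_len(min(50, length(sequences)))])
  null0 <- profile_search(base_pssm, database, e_threshold = Inf,
                          seed = derive_seed(seed, "null"))
  run_queries <- function(seq_pool, n_rep, tag) {
    found <- character(0)
    for (r in seq_len(n_rep)) {
      s <- derive_seed(seed, paste0(tag, "_", r))
      pick <- with_seed(s, sample(length(seq_pool),
                                  min(sample_size, length(seq_pool)),
                                  replace = length(seq_pool) <
                                    sample_size))
      ps <- build_pssm(seq_pool[pick])
      hits <- profile_search(ps, database, e_threshold = e_threshold,
                             seed = s,
                             null_fit = attr(null0, "null_fit"))
      found <- union(found, hits$id)
    }
    found
  }
  per <- list(); cum <- character(0)
  for (nm in names(subsets)) {
    pool <- subsets[[nm]]
    if (length(pool) == 0) next
    found <- run_queries(pool, repeats, nm)
    per[[nm]] <- data.frame(subset = nm, n_subset = length(pool),
                            tp = sum(labels[found]),
                            fp = sum(!labels[found]),
                            stringsAsFactors = FALSE)
    cum <- union(cum, found)
  }
  pooled_found <- run_queries(sequences,
                              repeats * length(per), "pooled")
  structure(list(
    per_subset = do.call(rbind, per),
    cumulative = c(tp = sum(labels[cum]), fp = sum(!labels[cum])),
    pooled = c(tp = sum(labels[pooled_found]),
               fp = sum(!labels[pooled_found]))),
    class = "retrieval_report")
}

#' @export
print.retrieval_report <- function(x, ...) {
  print(x$per_subset, row.names = FALSE)
  cat("cumulative: TP", x$cumulative["tp"], "FP", x$cumulative["fp"],
      "| pooled control: TP", x$pooled["tp"], "FP", x$pooled["fp"],
      "\n")
  invisible(x)
}
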