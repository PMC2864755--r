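## Amino-acid constants shared across the package.

#' Standard amino-acid one-letter codes
#'
#' The 20 standard types, alphabetical by one-letter code.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Types never introduced by design: special backbone/topology roles.
AA_SPECIAL <- c("C", "G", "P")

#' Amino-acid types allowed at designable positions
#'
#' All 20 types minus Cys, Gly and Pro.  Cysteine (disulfides), glycine
#' (backbone flexibility) and proline (backbone geometry) have effects
#' on the folded and unfolded states that a fixed-backbone rotamer
#' model does not capture, so they are kept at native positions only
#' and never introduced elsewhere.
#' @export
AA_DESIGNABLE <- setdiff(AA_ALPHABET, AA_SPECIAL)

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- structure(names(AA_THREE), names = AA_THREE)

## Number of side-chain chi dihedrals per type.
AA_N_CHI <- c(A = 0L, C = 1L, D = 2L, E = 3L, F = 2L, G = 0L, H = 2L,
              I = 2L, K = 4L, L = 2L, M = 3L, N = 2L, P = 0L, Q = 3L,
              R = 4L, S = 1L, T = 1L, V = 1L, W = 2L, Y = 2L)

#' Reduced amino-acid alphabets
#'
#' Physicochemical groupings ("flavors") of the 20 amino acids obtained
#' from cluster analysis of the BLOSUM62 matrix and of residue-residue
#' contact energies.  Two reductions are provided: nine classes
#' \{LVIMC\} \{FY\} \{W\} \{G\} \{A\} \{STP\} \{EDNQ\} \{KR\} \{H\}
#' and six classes
#' \{LVIMC\} \{FYW\} \{G\} \{ASTP\} \{EDNQ\} \{KRH\},
#' plus the identity mapping over 20 types.
#'
#' @param id one of `"nine"`, `"six"`, `"identity20"`.
#' @return An object of class `reduced_alphabet`: a named character
#'   vector mapping each one-letter type to a class label, with
#'   attributes `id` and `classes`.
#' @examples
#' ab <- reduced_alphabet("nine")
#' ab[["F"]]  # "FY"
#' @export
reduced_alphabet <- function(id = c("nine", "six", "identity20")) {
  id <- match.arg(id)
  groups <- switch(id,
    nine = c("LVIMC", "FY", "W", "G", "A", "STP", "EDNQ", "KR", "H"),
    six  = c("LVIMC", "FYW", "G", "ASTP", "EDNQ", "KRH"),
    identity20 = AA_ALPHABET)
  map <- character(0)
  for (g in groups) {
    members <- strsplit(g, "")[[1]]
    map[members] <- g
  }
  map <- map[AA_ALPHABET]
  stopifnot(!anyNA(map))
  structure(map, id = id, classes = groups, class = "reduced_alphabet")
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("Reduced alphabet '", attr(x, "id"), "': ",
      paste(attr(x, "classes"), collapse = " "), "\n", sep = "")
  invisible(x)
}

## Map a character vector / matrix of one-letter codes to class labels.
reduce_types <- function(x, alphabet) {
  out <- alphabet[x]
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Background amino-acid frequencies
#'
#' Robinson & Robinson background frequencies over the 20 standard
#' types, as used by common database-search statistics.  Normalised to
#' sum to one.
#' @return Named numeric vector over [AA_ALPHABET].
#' @export
aa_background <- function() {
  bg <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295,
          F = 0.03856, G = 0.07377, H = 0.02199, I = 0.05142,
          K = 0.05744, L = 0.09019, M = 0.02243, N = 0.04487,
          P = 0.05203, Q = 0.04264, R = 0.05129, S = 0.07120,
          T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  bg / sum(bg)
}

#' BLOSUM62 substitution matrix with gap column
#'
#' The standard BLOSUM62 integer matrix restricted to the 20 amino
#' acids, extended with a gap symbol `-` whose score against anything
#' is `gap_score`.
#'
#' @param gap_score score of any residue (or gap) against a gap
#'   (default -5).
#' @return 21 x 21 symmetric integer matrix with dimnames over
#'   `c(AA_ALPHABET, "-")`.
#' @export
blosum62_matrix <- function(gap_score = -5) {
  b <- get_blosum62_raw()
  b <- b[AA_ALPHABET, AA_ALPHABET]
  out <- matrix(gap_score, 21, 21,
                dimnames = list(c(AA_ALPHABET, "-"), c(AA_ALPHABET, "-")))
  out[AA_ALPHABET, AA_ALPHABET] <- b
  out
}

get_blosum62_raw <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix layout (comment
#' lines starting with `#`, a header row of single-letter columns,
#' then one labelled row per letter).
#'
#' @param path file path.
#' @param gap_score score used for gap pairings if the file has no `*`
#'   column (default -5).
#' @return 21 x 21 matrix as in [blosum62_matrix()].
#' @export
read_substitution_matrix <- function(path, gap_score = -5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(vals) <- list(labels, header)
  keep <- intersect(AA_ALPHABET, labels)
  if (length(keep) < 20)
    stop("substitution matrix is missing amino acids: ",
         paste(setdiff(AA_ALPHABET, labels), collapse = ", "))
  out <- matrix(gap_score, 21, 21,
                dimnames = list(c(AA_ALPHABET, "-"), c(AA_ALPHABET, "-")))
  out[AA_ALPHABET, AA_ALPHABET] <- vals[AA_ALPHABET, AA_ALPHABET]
  if (!isTRUE(all.equal(out, t(out))))
    stop("substitution matrix is not symmetric")
  out
}
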