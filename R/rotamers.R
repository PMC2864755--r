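## Rotamer libraries.  A rotamer is a vector of side-chain chi angles
## (degrees, in (-180, 180]).  The built-in minimal library puts each
## chi on the staggered -60/60/180 grid; any published library can be
## converted to the TSV dialect and loaded instead.

#' Built-in chi-grid rotamer library
#'
#' Every rotatable chi takes the staggered values -60, 60, 180; a type
#' with k chi angles gets 3^k rotamers (Leu: 9; Lys/Arg: 81).  Ala and
#' Gly have a single chi-less rotamer.
#'
#' @param chi_values grid values per chi (default `c(-60, 60, 180)`).
#' @param types amino-acid types to include (default all 20).
#' @return A `rotamer_library`: named list mapping type -> numeric
#'   matrix with one row per rotamer and one column per chi.
#' @export
builtin_rotamer_library <- function(chi_values = c(-60, 60, 180),
                                    types = AA_ALPHABET) {
  lib <- lapply(types, function(aa) {
    k <- AA_N_CHI[[aa]]
    if (k == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
    grid <- do.call(expand.grid, rep(list(chi_values), k))
    m <- as.matrix(grid)
    dimnames(m) <- list(NULL, paste0("chi", seq_len(k)))
    m
  })
  names(lib) <- types
  structure(lib, class = "rotamer_library")
}

#' Load a rotamer library from TSV
#'
#' Dialect: header `aa_type chi1 chi2 chi3 chi4`; one row per rotamer;
#' unused chi columns empty or NA.  When `path` is `NULL` the built-in
#' grid library is returned.
#'
#' @param path TSV file, or `NULL` for the built-in library.
#' @return A `rotamer_library`.
#' @export
load_rotamer_library <- function(path = NULL) {
  if (is.null(path)) return(builtin_rotamer_library())
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (!"aa_type" %in% names(tab))
    stop("rotamer TSV must have an aa_type column")
  chi_cols <- intersect(paste0("chi", 1:4), names(tab))
  lib <- list()
  for (i in seq_len(nrow(tab))) {
    aa <- tab$aa_type[i]
    if (!aa %in% AA_ALPHABET)
      stop("line ", i + 1, ": unknown amino-acid type '", aa, "'")
    k <- AA_N_CHI[[aa]]
    chis <- suppressWarnings(as.numeric(tab[i, chi_cols]))
    chis <- chis[!is.na(chis)]
    if (length(chis) != k)
      stop("line ", i + 1, ": ", aa, " needs ", k, " chi value(s), got ",
           length(chis))
    if (any(chis <= -180 | chis > 180))
      stop("line ", i + 1, ": chi out of range (-180, 180]")
    lib[[aa]] <- rbind(lib[[aa]], chis)
  }
  lib <- lapply(lib, function(m) {
    rownames(m) <- NULL
    if (ncol(m) > 0) colnames(m) <- paste0("chi", seq_len(ncol(m)))
    m
  })
  ## chi-less types always have their single implicit rotamer
  for (aa in intersect(c("A", "G"), unique(tab$aa_type)))
    lib[[aa]] <- matrix(numeric(0), nrow = 1, ncol = 0)
  structure(lib, class = "rotamer_library")
}

#' Write a rotamer library to TSV
#' @param library a `rotamer_library`.
#' @param path output file.
#' @export
write_rotamer_library <- function(library, path) {
  rows <- list()
  for (aa in names(library)) {
    m <- library[[aa]]
    for (r in seq_len(nrow(m))) {
      chis <- rep(NA_real_, 4)
      if (ncol(m) > 0) chis[seq_len(ncol(m))] <- m[r, ]
      rows[[length(rows) + 1]] <- data.frame(aa_type = aa,
        chi1 = chis[1], chi2 = chis[2], chi3 = chis[3], chi4 = chis[4])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of rotamers available for a type
#' @param library a `rotamer_library`; `aa` one-letter type.
#' @param aa one-letter type.
#' @return integer count.
#' @export
n_rotamers <- function(library, aa) {
  m <- library[[aa]]
  if (is.null(m)) 0L else nrow(m)
}

#' Chi angles of one rotamer
#' @param library a `rotamer_library`.
#' @param aa one-letter type; `r` rotamer row index.
#' @param r rotamer index.
#' @return numeric chi vector (degrees).
#' @export
rotamer_chis <- function(library, aa, r) {
  m <- library[[aa]]
  if (is.null(m) || r > nrow(m)) stop("no rotamer ", r, " for type ", aa)
  as.numeric(m[r, ])
}
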