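## Force-field parameter tables: per-(residue, atom) partial charge,
## Lennard-Jones parameters, solvation radius and solvation atom
## class.  The built-in set follows the united-atom, polar-hydrogen
## convention (extended aliphatic carbons, explicit O-H/N-H/S-H
## hydrogens); values are canonical molecular-mechanics magnitudes.
## Alternative tables can be loaded from TSV.

#' Atomic solvation coefficients by atom class
#'
#' kcal/mol/A^2: carbon and sulfur 0.012; oxygen and nitrogen -0.06;
#' hydrogen 0; atoms of ionized groups -0.15.
#' @export
SOLVATION_SIGMA <- c(carbon_sulfur = 0.012,
                     oxygen_nitrogen = -0.06,
                     hydrogen = 0.0,
                     ionized = -0.15)

## Per-element Lennard-Jones defaults: well depth (kcal/mol), half
## distance at the minimum (A), and solvation radius (A).
LJ_BY_ELEMENT <- data.frame(
  element = c("C", "N", "O", "S", "H"),
  lj_epsilon = c(0.120, 0.2384, 0.1591, 0.043, 0.0498),
  lj_rmin = c(2.10, 1.60, 1.60, 1.89, 0.80),
  radius = c(1.90, 1.70, 1.60, 1.90, 1.00),
  stringsAsFactors = FALSE)

element_class <- function(el) {
  c(C = "carbon_sulfur", S = "carbon_sulfur",
    N = "oxygen_nitrogen", O = "oxygen_nitrogen",
    H = "hydrogen")[el]
}

#' Built-in force-field parameter set
#'
#' One row per (residue, atom) covering every atom any topology can
#' place: partial charge (e), LJ well depth (kcal/mol), LJ half-rmin
#' (A), solvation radius (A), solvation atom class and coefficient
#' (kcal/mol/A^2).
#'
#' @return A `parameter_set`: data.frame with columns `aa`, `atom`,
#'   `element`, `charge`, `lj_epsilon`, `lj_rmin`, `radius`, `class`,
#'   `sigma_solv`.
#' @export
default_parameters <- function() {
  if (!is.null(.topo_cache$params)) return(.topo_cache$params)
  rows <- list()
  for (aa in AA_ALPHABET) {
    bb <- backbone_atoms(aa)
    bb$cls <- NA_character_
    sc <- residue_topology(aa)$atoms
    sc <- if (nrow(sc) > 0) sc[, c("name", "element", "charge", "cls")] else NULL
    tab <- rbind(bb[, c("name", "element", "charge", "cls")], sc)
    tab$aa <- aa
    rows[[aa]] <- tab
  }
  tab <- do.call(rbind, rows)
  tab$class <- ifelse(is.na(tab$cls), element_class(tab$element), tab$cls)
  m <- match(tab$element, LJ_BY_ELEMENT$element)
  out <- data.frame(aa = tab$aa, atom = tab$name, element = tab$element,
                    charge = tab$charge,
                    lj_epsilon = LJ_BY_ELEMENT$lj_epsilon[m],
                    lj_rmin = LJ_BY_ELEMENT$lj_rmin[m],
                    radius = LJ_BY_ELEMENT$radius[m],
                    class = tab$class,
                    sigma_solv = unname(SOLVATION_SIGMA[tab$class]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("parameter_set", "data.frame")
  .topo_cache$params <- out
  out
}

#' Load a parameter set from TSV
#'
#' The TSV dialect has a header line with the columns of
#' [default_parameters()]; `sigma_solv` may be omitted, in which case
#' class defaults are applied (carbon_sulfur 0.012, oxygen_nitrogen
#' -0.06, hydrogen 0, ionized -0.15 kcal/mol/A^2).
#'
#' @param path TSV file path.
#' @return A `parameter_set`.
#' @export
load_parameters <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("aa", "atom", "element", "charge", "lj_epsilon", "lj_rmin",
            "radius", "class")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("parameter TSV missing columns: ", paste(miss, collapse = ", "))
  bad <- !tab$class %in% names(SOLVATION_SIGMA)
  if (any(bad))
    stop("unknown atom class: ", paste(unique(tab$class[bad]), collapse = ", "))
  if (is.null(tab$sigma_solv))
    tab$sigma_solv <- unname(SOLVATION_SIGMA[tab$class])
  if (any(tab$lj_epsilon < 0)) stop("negative LJ well depth")
  if (any(tab$radius <= 0)) stop("non-positive solvation radius")
  class(tab) <- c("parameter_set", "data.frame")
  tab
}

#' Write a parameter set to TSV
#' @param params a `parameter_set`.
#' @param path output file.
#' @export
write_parameters <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach force-field parameters to an atom table
#'
#' Joins on (aa, atom name); errors if any atom fails to resolve to
#' exactly one parameter row.
#' @param atoms data.frame with columns `aa`, `name`.
#' @param params a `parameter_set`.
#' @return `atoms` with parameter columns appended.
#' @export
assign_parameters <- function(atoms, params) {
  key_a <- paste(atoms$aa, atoms$name)
  key_p <- paste(params$aa, params$atom)
  if (anyDuplicated(key_p))
    stop("parameter set has duplicate rows")
  m <- match(key_a, key_p)
  if (anyNA(m)) {
    bad <- unique(key_a[is.na(m)])
    stop("no parameters for atom(s): ", paste(bad, collapse = ", "))
  }
  atoms$charge <- params$charge[m]
  atoms$lj_epsilon <- params$lj_epsilon[m]
  atoms$lj_rmin <- params$lj_rmin[m]
  atoms$radius <- params$radius[m]
  atoms$class <- params$class[m]
  atoms$sigma_solv <- params$sigma_solv[m]
  atoms
}
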