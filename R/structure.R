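## Backbone templates and PDB I/O.  A template is the fixed backbone
## of one chain plus per-position native type and designability flags.
## Native Cys/Gly/Pro positions are frozen (side chains kept at input
## coordinates, type never mutated); all other positions are
## designable with allowed types = 20 minus {C, G, P}.

#' Construct a backbone template
#'
#' @param positions data.frame with columns `index`, `native`
#'   (one-letter codes).
#' @param bb_atoms data.frame with columns `resno`, `name`, `element`,
#'   `x`, `y`, `z` holding backbone atoms (N, H, CA, C, O).
#' @param frozen named list: position index (as character) ->
#'   data.frame of frozen native side-chain atoms (`name`, `element`,
#'   `x`, `y`, `z`).
#' @param chain chain identifier.
#' @param native_chis optional named list: position -> numeric chi
#'   vector measured from the input structure.
#' @return An object of class `backbone_template`.
#' @export
backbone_template <- function(positions, bb_atoms, frozen = list(),
                              chain = "A", native_chis = list()) {
  positions$designable <- !positions$native %in% AA_SPECIAL
  need_frozen <- positions$index[!positions$designable &
                                 positions$native != "G"]
  miss <- setdiff(as.character(need_frozen), names(frozen))
  if (length(miss) > 0)
    stop("frozen position(s) without native side chain: ",
         paste(miss, collapse = ", "))
  obj <- list(positions = positions, bb_atoms = bb_atoms,
              frozen = frozen, chain = chain, native_chis = native_chis)
  class(obj) <- "backbone_template"
  obj
}

#' @export
print.backbone_template <- function(x, ...) {
  cat("Backbone template: chain", x$chain, "|", nrow(x$positions),
      "positions |", sum(x$positions$designable), "designable\n")
  cat("Sequence:", template_sequence(x), "\n")
  invisible(x)
}

#' Native sequence of a template
#' @param template a `backbone_template`.
#' @return one-letter string.
#' @export
template_sequence <- function(template)
  paste(template$positions$native, collapse = "")

#' Number of positions
#' @param template a `backbone_template`.
#' @export
template_length <- function(template) nrow(template$positions)

#' Backbone coordinates of one atom at one position
#' @param template a `backbone_template`.
#' @param index position index; `name` atom name (N/H/CA/C/O).
#' @param name atom name.
#' @return numeric 3-vector, or NULL if absent.
#' @export
bb_coord <- function(template, index, name) {
  a <- template$bb_atoms
  i <- which(a$resno == index & a$name == name)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

## Ideal side-chain anchor (CB, or CA for Gly) used by the residue
## pair cutoff.
pseudo_cb <- function(template, index) {
  aa <- template$positions$native[template$positions$index == index]
  n <- bb_coord(template, index, "N")
  ca <- bb_coord(template, index, "CA")
  cc <- bb_coord(template, index, "C")
  if (identical(aa, "G")) return(ca)
  place_atom(cc, n, ca, 1.53, 110.5, CB_DIH)
}

#' Read a PDB file into a backbone template
#'
#' Parses single-model ATOM records of one chain, resolves alternate
#' locations to the highest occupancy, rebuilds a missing backbone O
#' from N/CA/C geometry, places the amide hydrogen, and freezes native
#' Cys/Gly/Pro side chains at their input coordinates.  Native side
#' chains of designable positions are recorded as measured chi angles.
#'
#' @param path PDB file.
#' @param parameters a `parameter_set` (default [default_parameters()]).
#' @param chain chain to select (default: first chain in the file).
#' @return A `backbone_template`.
#' @export
read_pdb <- function(path, parameters = default_parameters(),
                     chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain | is.na(at$chain), ]
  ## resolve altlocs: keep highest occupancy per (resno, elety)
  at$o[is.na(at$o)] <- 1
  ord <- order(at$resno, at$elety, -at$o)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$resno, at$elety)), ]
  at <- at[order(at$resno), ]

  resnos <- unique(at$resno)
  pos_rows <- list(); bb_rows <- list(); frozen <- list(); chis <- list()
  for (rn in resnos) {
    res <- at[at$resno == rn, ]
    resid <- res$resid[1]
    if (!resid %in% names(AA_ONE))
      stop("unknown residue name '", resid, "' at position ", rn)
    aa <- AA_ONE[[resid]]
    getc <- function(nm) {
      i <- which(res$elety == nm)
      if (length(i) == 0) NULL else c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
    }
    for (nm in c("N", "CA", "C"))
      if (is.null(getc(nm)))
        stop("missing backbone atom ", nm, " in residue ", resid, " ", rn)
    n <- getc("N"); ca <- getc("CA"); cc <- getc("C")
    o <- getc("O")
    if (is.null(o))  # rebuild carbonyl O in the N-CA-C plane
      o <- place_atom(n, ca, cc, 1.23, 120.5, 180)
    h <- getc("H") %||% getc("HN")
    if (is.null(h) && aa != "P")
      h <- n + 0.98 * unit(unit(n - ca) + unit(n - cc))
    nm_bb <- c("N", if (aa != "P") "H", "CA", "C", "O")
    xyz_bb <- rbind(n, if (aa != "P") h, ca, cc, o)
    bb_rows[[as.character(rn)]] <- data.frame(
      resno = rn, name = nm_bb,
      element = substr(nm_bb, 1, 1),
      x = xyz_bb[, 1], y = xyz_bb[, 2], z = xyz_bb[, 3],
      stringsAsFactors = FALSE)
    pos_rows[[as.character(rn)]] <- data.frame(index = rn, native = aa,
                                               stringsAsFactors = FALSE)
    sc_names <- sidechain_atom_names(aa)
    heavy <- sc_names[!startsWith(sc_names, "H")]
    if (aa %in% AA_SPECIAL && aa != "G") {
      have <- heavy %in% res$elety
      if (!all(have)) {
        ## rebuild frozen side chain from measured chis where possible
        ch <- measure_chis(aa, getc)
        if (anyNA(ch)) stop("frozen residue ", resid, " ", rn,
                            " has an incomplete side chain")
        frozen[[as.character(rn)]] <-
          build_sidechain(aa, n, ca, cc, ch)[, c("name", "element",
                                                 "x", "y", "z")]
      } else {
        keep <- res[res$elety %in% sc_names, ]
        fr <- data.frame(name = keep$elety,
                         element = substr(keep$elety, 1, 1),
                         x = keep$x, y = keep$y, z = keep$z,
                         stringsAsFactors = FALSE)
        ## add any missing polar hydrogens by topology
        miss_h <- setdiff(sc_names, fr$name)
        if (length(miss_h) > 0) {
          ch <- measure_chis(aa, getc)
          built <- build_sidechain(aa, n, ca, cc, ch)
          add <- built[built$name %in% miss_h,
                       c("name", "element", "x", "y", "z")]
          fr <- rbind(fr, add)
        }
        ## keep topology order
        fr <- fr[match(sc_names, fr$name), ]
        frozen[[as.character(rn)]] <- fr
      }
    }
    if (AA_N_CHI[[aa]] > 0) {
      ch <- measure_chis(aa, getc)
      if (!anyNA(ch)) chis[[as.character(rn)]] <- ch
    }
  }
  positions <- do.call(rbind, pos_rows)
  rownames(positions) <- NULL
  bb <- do.call(rbind, bb_rows)
  rownames(bb) <- NULL
  backbone_template(positions, bb, frozen, chain = chain,
                    native_chis = chis)
}

#' Write a template (with side chains) to PDB
#'
#' @param template a `backbone_template`.
#' @param path output file.
#' @param sequence optional full sequence (default native).
#' @param rotamers optional list: position index -> chi vector for the
#'   side chains; defaults to recorded native chis.
#' @param library rotamer library used when `rotamers` gives indices.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(template, path, sequence = NULL, rotamers = NULL,
                      library = NULL) {
  atoms <- assemble_atoms(template, sequence = sequence,
                          rotamers = rotamers, library = library,
                          parameters = NULL)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  three <- AA_THREE[atoms$aa]
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   resid = three, elety = atoms$name,
                   chain = rep(template$chain, nrow(atoms)),
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  invisible(path)
}

#' Build side-chain atoms for a rotamer at a template position
#'
#' Places the side chain of type `aa` at position `index` from internal
#' coordinates with the chi angles of `rot`; the backbone is untouched.
#'
#' @param template a `backbone_template`.
#' @param index position index.
#' @param aa amino-acid type to place.
#' @param rot numeric chi vector, or a rotamer row index into `library`.
#' @param library rotamer library (needed when `rot` is an index).
#' @return data.frame of side-chain atoms (`name`, `element`,
#'   `charge`, `x`, `y`, `z`).
#' @export
place_rotamer <- function(template, index, aa, rot, library = NULL) {
  p <- template$positions
  row <- p[p$index == index, ]
  if (nrow(row) == 0) stop("no position ", index, " in template")
  if (row$designable) {
    if (aa %in% AA_SPECIAL)
      stop(aa, " is not allowed at designable position ", index)
  } else if (aa != row$native) {
    stop("position ", index, " is frozen as ", row$native)
  }
  chis <- if (!is.null(library)) rotamer_chis(library, aa, rot)
          else as.numeric(rot)
  n <- bb_coord(template, index, "N")
  ca <- bb_coord(template, index, "CA")
  cc <- bb_coord(template, index, "C")
  build_sidechain(aa, n, ca, cc, chis)
}

#' Assemble the full atom set for a sequence/rotamer assignment
#'
#' Concatenates backbone atoms, frozen native side chains, and built
#' side chains for every designable position, in residue order.
#'
#' @param template a `backbone_template`.
#' @param sequence character string (length = template length) or
#'   `NULL` for the native sequence.
#' @param rotamers `NULL` (use recorded native chis, else first
#'   library rotamer), a list position -> chi vector, or an integer
#'   vector of rotamer indices into `library`.
#' @param library rotamer library (required for integer `rotamers`).
#' @param parameters `parameter_set` to attach, or `NULL` to skip.
#' @return data.frame: `resno`, `aa`, `name`, `element`, `group`
#'   (bb/sc), `x`, `y`, `z` (+ parameter columns when attached).
#' @export
assemble_atoms <- function(template, sequence = NULL, rotamers = NULL,
                           library = NULL,
                           parameters = default_parameters()) {
  pos <- template$positions
  L <- nrow(pos)
  seq_vec <- if (is.null(sequence)) pos$native
             else strsplit(sequence, "")[[1]]
  if (length(seq_vec) != L) stop("sequence length != template length")
  bad <- which(!pos$designable & seq_vec != pos$native)
  if (length(bad) > 0)
    stop("frozen position(s) mutated: ",
         paste(pos$index[bad], collapse = ", "))
  bad <- which(pos$designable & seq_vec %in% AA_SPECIAL)
  if (length(bad) > 0)
    stop("C/G/P introduced at designable position(s): ",
         paste(pos$index[bad], collapse = ", "))
  out <- list()
  for (i in seq_len(L)) {
    idx <- pos$index[i]
    aa <- seq_vec[i]
    bb <- template$bb_atoms[template$bb_atoms$resno == idx, ]
    bb$aa <- aa; bb$group <- "bb"
    out[[length(out) + 1]] <- bb[, c("resno", "aa", "name", "element",
                                     "group", "x", "y", "z")]
    key <- as.character(idx)
    sc <- NULL
    if (!pos$designable[i] && aa != "G") {
      sc <- template$frozen[[key]]
    } else if (pos$designable[i] || aa == pos$native[i]) {
      k <- AA_N_CHI[[aa]]
      chis <-
        if (is.list(rotamers)) rotamers[[key]]
        else if (is.numeric(rotamers) && !is.null(library))
          rotamer_chis(library, aa, rotamers[i])
        else template$native_chis[[key]]
      if (is.null(chis) && k > 0) {
        chis <- if (!is.null(library)) rotamer_chis(library, aa, 1)
                else rep(180, k)
      }
      if (k == 0) chis <- numeric(0)
      if (aa != "G")
        sc <- build_sidechain(aa,
                              bb_coord(template, idx, "N"),
                              bb_coord(template, idx, "CA"),
                              bb_coord(template, idx, "C"),
                              chis)[, c("name", "element", "x", "y", "z")]
    }
    if (!is.null(sc) && nrow(sc) > 0) {
      sc$resno <- idx; sc$aa <- aa; sc$group <- "sc"
      out[[length(out) + 1]] <- sc[, c("resno", "aa", "name", "element",
                                       "group", "x", "y", "z")]
    }
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  if (!is.null(parameters)) atoms <- assign_parameters(atoms, parameters)
  atoms
}

#' Measure chi angles of a placed side chain
#'
#' @param aa type.
#' @param atoms data.frame of side-chain atoms (`name`, `x`, `y`, `z`).
#' @param n_xyz,ca_xyz,c_xyz backbone coordinates.
#' @return numeric chi vector.
#' @export
sidechain_chis <- function(aa, atoms, n_xyz, ca_xyz, c_xyz) {
  getter <- function(nm) {
    if (nm == "N") return(n_xyz)
    if (nm == "CA") return(ca_xyz)
    if (nm == "C") return(c_xyz)
    i <- which(atoms$name == nm)
    if (length(i) == 0) NULL else c(atoms$x[i[1]], atoms$y[i[1]],
                                    atoms$z[i[1]])
  }
  measure_chis(aa, getter)
}
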