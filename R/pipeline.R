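## Pipeline driver: wires the modules into the full workflow
## (prepare -> matrix -> design -> analyze -> pssm -> search) with a
## declarative config, per-stage manifests and provenance hashes.
## The `designkit` script under inst/cli/ is a thin wrapper over
## run_pipeline() and the individual operations.

#' Pipeline run configuration
#'
#' @param pdb input PDB path (or NULL to generate a fixture).
#' @param out_dir output directory.
#' @param seed top-level seed; every stage derives named substreams.
#' @param rotamers,parameters optional TSV paths (NULL = built-ins).
#' @param msa optional aligned FASTA of natural homologues.
#' @param database optional FASTA search database.
#' @param model an [energy_model()].
#' @param allowed_types candidate types at designable positions.
#' @param n_cycles,select_k design scale (desk-scale defaults).
#' @param e_threshold retrieval E-value threshold.
#' @param fixture fixture spec list(kind, length, sequence) used when
#'   `pdb` is NULL.
#' @return list of class `run_config`.
#' @export
run_config <- function(pdb = NULL, out_dir = "designkit_run", seed = 1,
                       rotamers = NULL, parameters = NULL, msa = NULL,
                       database = NULL, model = energy_model(pair_min_steps = 0),
                       allowed_types = c("A", "S", "V", "D"),
                       n_cycles = 200, select_k = 200,
                       e_threshold = 0.1,
                       fixture = list(kind = "hairpin", length = 8,
                                      sequence = NULL)) {
  for (p in c(pdb, rotamers, parameters, msa, database))
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  structure(as.list(environment()), class = "run_config")
}

stage_manifest <- function(dir, stage, inputs, outputs, seed) {
  man <- list(stage = stage, seed = seed,
              inputs = lapply(inputs, function(f)
                if (file.exists(f)) unname(hash_file(f)) else NA),
              outputs = lapply(outputs, function(f)
                if (file.exists(f)) unname(hash_file(f)) else NA),
              version = as.character(utils::packageVersion("designkit")))
  jsonlite::write_json(man, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

manifest_ok <- function(dir, stage) {
  f <- file.path(dir, paste0(stage, ".manifest.json"))
  if (!file.exists(f)) return(FALSE)
  man <- jsonlite::read_json(f)
  all(vapply(names(man$outputs), function(o)
    file.exists(file.path(dir, basename(o))) ||
    file.exists(o), logical(1)))
}

#' Run the design pipeline
#'
#' Executes the requested stages in order; each stage writes its
#' artifacts and a manifest (input/output hashes, seed, version) into
#' the output directory.  Completed stages (valid manifest and
#' outputs) are skipped unless `force = TRUE`.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("prepare", "matrix", "design", "analyze", "pssm", "search")`.
#' @param force recompute even if manifests are present.
#' @return the output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config,
                         stages = c("prepare", "matrix", "design",
                                    "analyze", "pssm", "search"),
                         force = FALSE) {
  all_stages <- c("prepare", "matrix", "design", "analyze", "pssm",
                  "search")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir <- config$out_dir
  lib <- if (is.null(config$rotamers)) builtin_rotamer_library()
         else load_rotamer_library(config$rotamers)
  params <- if (is.null(config$parameters)) default_parameters()
            else load_parameters(config$parameters)
  paths <- list(pdb = file.path(dir, "prepared.pdb"),
                matrix = file.path(dir, "energy_matrix.json"),
                fasta = file.path(dir, "ensemble.fasta"),
                tsv = file.path(dir, "ensemble.tsv"),
                stats = file.path(dir, "analysis.tsv"),
                mi = file.path(dir, "covariance.tsv"),
                pssm = file.path(dir, "profile.pssm"),
                pssm_tsv = file.path(dir, "profile.tsv"),
                hits = file.path(dir, "hits.tsv"))

  need <- function(st) st %in% stages && (force || !manifest_ok(dir, st))

  tpl <- NULL
  get_template <- function() {
    if (!is.null(tpl)) return(tpl)
    if (file.exists(paths$pdb)) return(read_pdb(paths$pdb, params))
    stop("missing upstream artifact for this stage: run 'prepare'")
  }

  if (need("prepare")) {
    if (is.null(config$pdb)) {
      fx <- config$fixture
      len <- fx$length %||% 8
      sq <- fx$sequence %||% strrep("A", len)
      made <- make_structure(fx$kind %||% "hairpin", len, sq,
                             seed = derive_seed(config$seed, "fixture"),
                             path = paths$pdb)
      tpl <- made$template
    } else {
      tpl <- read_pdb(config$pdb, params)
      write_pdb(tpl, paths$pdb)
    }
    stage_manifest(dir, "prepare", c(config$pdb), c(paths$pdb),
                   config$seed)
  }
  em <- NULL
  if (need("matrix")) {
    tpl <- get_template()
    unf <- unfolded_reference(types = unique(c(config$allowed_types,
                                               tpl$positions$native)),
                              library = lib, model = config$model,
                              parameters = params)
    em <- build_energy_matrix(tpl, lib, config$model, unf,
                              allowed_types = config$allowed_types,
                              parameters = params)
    write_energy_matrix(em, paths$matrix)
    stage_manifest(dir, "matrix", c(paths$pdb), c(paths$matrix),
                   config$seed)
  }
  ens <- NULL
  if (need("design")) {
    if (is.null(em)) em <- read_energy_matrix(paths$matrix)
    cfg <- design_config(n_cycles = config$n_cycles,
                         seed = derive_seed(config$seed, "design"),
                         select_k = config$select_k)
    ens <- run_design(em, cfg)
    write_ensemble(ens, fasta = paths$fasta, tsv = paths$tsv)
    stage_manifest(dir, "design", c(paths$matrix),
                   c(paths$fasta, paths$tsv), config$seed)
  }
  if (need("analyze")) {
    tpl <- get_template()
    if (is.null(ens)) {
      if (!file.exists(paths$tsv))
        stop("missing upstream artifact for 'analyze': run 'design'")
      recs <- utils::read.table(paths$tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      seqs <- recs$sequence
    } else seqs <- ens$records$sequence
    native <- template_sequence(tpl)
    ent <- positional_entropy(seqs)
    mi <- mutual_information_matrix(seqs)
    stats <- data.frame(
      metric = c("n_sequences", "mean_identity_pct",
                 "mean_exp_entropy_nine", "max_offdiag_mi_nats"),
      value = c(length(seqs), mean_identity(seqs, native),
                ent$mean_exp,
                max(mi[upper.tri(mi)], 0)))
    utils::write.table(stats, paths$stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(round(unclass(mi), 6), paths$mi, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    stage_manifest(dir, "analyze", c(paths$tsv),
                   c(paths$stats, paths$mi), config$seed)
  }
  ps <- NULL
  if (need("pssm")) {
    if (is.null(ens)) {
      recs <- utils::read.table(paths$tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      seqs <- recs$sequence
    } else seqs <- ens$records$sequence
    ps <- build_pssm(seqs)
    export_pssm(ps, paths$pssm, "ascii-pssm")
    export_pssm(ps, paths$pssm_tsv, "tsv")
    stage_manifest(dir, "pssm", c(paths$tsv),
                   c(paths$pssm, paths$pssm_tsv), config$seed)
  }
  if (need("search")) {
    if (is.null(ps)) ps <- read_pssm_tsv(paths$pssm_tsv)
    if (is.null(config$database)) {
      ## no database given: search the ensemble itself as a smoke run
      recs <- utils::read.table(paths$tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      db <- stats::setNames(recs$sequence,
                            sprintf("design_%05d", recs$cycle))
    } else db <- read_fasta(config$database)
    hits <- profile_search(ps, db, e_threshold = config$e_threshold,
                           seed = derive_seed(config$seed, "search"))
    utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_manifest(dir, "search", c(paths$pssm_tsv), c(paths$hits),
                   config$seed)
  }
  invisible(dir)
}

#' Serialize an energy matrix to a JSON container
#'
#' Text-based container: a JSON header (positions, states, model,
#' provenance hashes) plus flattened numeric payloads.
#'
#' @param em a `pair_energy_matrix`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_energy_matrix <- function(em, path) {
  obj <- list(
    positions = em$positions,
    states = lapply(em$states, function(s) list(aa = s$aa, rot = s$rot)),
    sing = lapply(em$sing, function(m) as.numeric(m)),
    unfold = em$unfold,
    pair = lapply(em$pair, function(a) list(dim = dim(a),
                                            val = as.numeric(a))),
    const = em$const,
    meta = list(model = unclass(em$meta$model),
                template_hash = em$meta$template_hash,
                library_hash = em$meta$library_hash))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an energy matrix written by [write_energy_matrix()]
#' @param path JSON container path.
#' @return a `pair_energy_matrix`.
#' @export
read_energy_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- as.character(obj$positions)
  states <- lapply(obj$states, function(s)
    data.frame(aa = s$aa, rot = s$rot, stringsAsFactors = FALSE))
  sing <- lapply(keys, function(k)
    matrix(obj$sing[[k]], ncol = 3,
           dimnames = list(NULL, c("vdw", "coulomb", "surface"))))
  names(sing) <- keys
  unfold <- lapply(obj$unfold, as.numeric)
  pair <- lapply(obj$pair, function(p) array(p$val, dim = p$dim))
  md <- obj$meta$model
  model <- energy_model(md$eps_design, md$eps_prep, md$surface_scale,
                        md$probe_radius, md$cutoff, md$pair_min_steps)
  pair_energy_matrix(states[keys], sing, unfold[keys], pair,
                     const = as.numeric(obj$const),
                     positions = as.integer(obj$positions),
                     meta = list(model = model,
                                 template_hash = obj$meta$template_hash,
                                 library_hash = obj$meta$library_hash))
}
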