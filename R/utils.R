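## Small internal utilities: deterministic seed streams and content
## hashing for provenance manifests.

#' Derive a child RNG seed from a base seed and a stream label
#'
#' Deterministic mixing of a base seed with a numeric or character
#' stream label; the result stays below 2^31 - 1 so it is always a
#' valid R seed.  All randomness in the package flows from one
#' top-level seed through named substreams built with this function.
#'
#' @param seed integer base seed.
#' @param stream integer or character substream label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  if (is.character(stream))
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  h <- (as.double(seed) %% 2147483647)
  h <- (h * 48271 + as.double(stream) * 16807 + 12345) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## md5 of an arbitrary R object via its serialization to a temp file.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

hash_file <- function(path) unname(tools::md5sum(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
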