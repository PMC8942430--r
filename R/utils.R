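# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are bit-reproducible without clobbering
# the session stream. seed = NULL uses (and advances) the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split semicolon-joined annotation strings into a character vector; NA and ""
# mean "no annotation".
split_terms <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0) return(character(0))
  unique(unlist(strsplit(x, ";", fixed = TRUE), use.names = FALSE))
}

join_terms <- function(x) {
  if (length(x) == 0 || all(is.na(x))) NA_character_ else paste(x, collapse = ";")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
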