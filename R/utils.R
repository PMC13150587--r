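# Run code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Atomic file write: materialize via `writer(tmp)` then rename, so failed
# stages never leave partial outputs.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write ", path, call. = FALSE)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}
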