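#' @keywords internal
"_PACKAGE"

## Deterministic 31-bit sub-stream seeds. A single user-facing seed fans out
## to per-entity seeds (per subject, per trial, per fold) so that any stage
## rerun in isolation reproduces exactly the same draws.
substream_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  key <- paste(c(as.character(seed), parts), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483563
  as.integer(h + 1L)  # keep strictly positive, < 2^31
}

## Cheap stable hash of an R object (used to stamp pipeline artifacts).
config_hash <- function(x) {
  key <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2147483629
  sprintf("%08x", as.integer(h))
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values (NaN/Inf/NA)")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
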