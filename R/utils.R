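# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic sub-seed from a master seed and a string key, so per-trait
# results are reproducible in any execution order. Always < 2^31.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(as.character(key))) h <- (h * 31 + code) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h + 1)
}

# Small FNV-1a-style hash of an R object's deparsed form; used only to
# fingerprint configurations in provenance blocks (no digest pkg available).
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_chemophylo <- function(...) stop(..., call. = FALSE)
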