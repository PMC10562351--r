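# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and integer offsets
#'
#' Mixes the arguments with a multiplicative-congruential step so that
#' distinct (module, site, round, ...) coordinates get well-separated seeds
#' while staying inside the 32-bit range `set.seed()` accepts.
#'
#' @param master integer master seed.
#' @param ... further integer offsets identifying the consumer.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 69069 + abs(p) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to
# fingerprint feature registries and experiment configs (artifacts from
# different configurations must not be mixed).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    # keep arithmetic in double to avoid integer overflow, fold back to 32 bits
    h <- (abs(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a finite numeric scalar", name)
  }
}
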