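# Internal helpers shared across modules.

# Deterministic 31-bit substream seed from a master seed and a key string.
# FNV-1a over the key bytes, mixed with the master seed; keeps per-subject
# streams independent of cohort size and group order.
derive_seed <- function(master_seed, ...) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  key <- paste(c(...), collapse = "\r")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- xor32(h, b)
    # 16777619 * h mod 2^32, split so every product stays exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 4294967296
  }
  h <- xor32(h %% 2147483647, master_seed %% 2147483647)
  as.integer(h %% 2147483629 + 1)
}

# Evaluate `expr` under a local, seeded RNG without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_samples <- function(x, name = "samples") {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
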