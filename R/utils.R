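# Internal helpers shared across modules.

# Normalize a category label: trim, collapse internal whitespace, case-fold.
norm_label <- function(x) {
  x <- trimws(x)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream untouched".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# 32-bit FNV-1a hash of a string, as 8 hex digits. Used for stable quiz ids;
# no cryptographic strength needed, only determinism across sessions.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  prime <- 16777619
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor2_32(h, b)
    # multiply mod 2^32 without losing precision: split into 16-bit halves
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# XOR for doubles holding 32-bit unsigned values (bitwXor needs < 2^31).
bitwXor2_32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# First index of the maximum -- ties resolved by position, i.e. declaration
# order when the vector is in declaration order.
which_max_first <- function(x) which.max(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursively turn scalar NAs into NULL so auto_unboxed JSON writes `null`
# rather than the string "NA".
na_to_null <- function(x) {
  if (is.list(x)) return(lapply(x, na_to_null))
  if (length(x) == 1L && !is.data.frame(x) && is.na(x)) return(NULL)
  x
}
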