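# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Splitmix-style integer hash used to derive independent per-run seeds from a
#' single master seed, so any cell of an experiment can be re-run in isolation.
#' The result is always a non-negative integer below 2^31.
#'
#' @param seed Master seed (integer).
#' @param k Index of the child stream (integer, >= 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, k) {
  # 64-bit arithmetic is emulated in double precision; all intermediates stay
  # below 2^52 so the mixing is exact.
  x <- (as.numeric(seed) + 1) * 2654435769 + (as.numeric(k) + 1) * 40503
  x <- x %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# Canonical string key for a set of feature indices (order-free).
set_key <- function(s) {
  if (length(s) == 0L) return("")
  paste(sort(as.integer(s)), collapse = ",")
}

# Canonical key for a pair {a,b} given conditioning set s (order-free in both).
pair_key <- function(a, b, s) {
  paste0(set_key(c(a, b)), "|", set_key(s))
}

# Enumerate all subsets of size k of the (sorted) vector v, in lexicographic
# order over sorted indices. Returns a list of integer vectors.
subsets_of_size <- function(v, k) {
  v <- sort(as.integer(v))
  if (k == 0L) return(list(integer(0)))
  if (k > length(v)) return(list())
  if (length(v) == 1L) return(list(v))   # combn(scalar, k) would misread v
  utils::combn(v, k, simplify = FALSE)
}

# Mixed-radix cell encoding: rows of `vals` (matrix, 0-based) against `arities`.
# Returns a 1-based double vector of cell ids in [1, prod(arities)].
encode_cells <- function(vals, arities) {
  if (!is.matrix(vals)) vals <- matrix(vals, ncol = length(arities))
  mult <- cumprod(c(1, arities[-length(arities)]))
  as.vector(vals %*% mult) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
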