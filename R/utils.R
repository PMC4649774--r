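#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results invariant to the order in which substreams are consumed.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  val <- (as.double(seed) * 48271 + h * 16807 + as.double(index) * 69621) %% 2147483399
  as.integer(val) + 1L
}

# exp-normalized rows of a matrix of log-weights
softmax_rows <- function(logw) {
  m <- apply(logw, 1L, max)
  w <- exp(logw - m)
  w / rowSums(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..k (k small; used for label alignment and its tests)
permutations_k <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_k(k - 1L)
  res <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      r <- r + 1L
      res[r, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  res
}
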