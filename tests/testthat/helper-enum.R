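# Independent brute-force enumerator over the FULL latent space (z and s),
# written with plain elementwise loops and its own probability arithmetic so
# it shares no code path with fit_exact (which enumerates z only and
# marginalizes s analytically) or with log_joint (vectorized).
brute_posterior <- function(x, params) {
  N <- nrow(x); J <- ncol(x); K <- params$K
  all_vec <- function(base, len) {
    n <- base^len
    m <- matrix(0L, n, len)
    for (r in seq_len(n)) {
      t <- r - 1L
      for (p in seq_len(len)) {
        m[r, p] <- t %% base
        t <- t %/% base
      }
    }
    m
  }
  zs <- all_vec(K, J) + 1L
  ss <- all_vec(2L, N * K)
  mem <- matrix(0, J, K)
  sen <- matrix(0, N, K)
  tot <- 0
  for (a in seq_len(nrow(zs))) {
    z <- zs[a, ]
    for (b in seq_len(nrow(ss))) {
      s <- matrix(ss[b, ], N, K)
      pr <- 1
      for (j in seq_len(J)) pr <- pr * params$pi[z[j]]
      for (i in seq_len(N)) for (k in seq_len(K)) {
        pr <- pr * if (s[i, k] == 1L) params$theta[k] else 1 - params$theta[k]
      }
      for (i in seq_len(N)) for (j in seq_len(J)) {
        if (is.na(x[i, j])) next
        p1 <- if (s[i, z[j]] == 1L) params$p_pos else params$p_neg
        pr <- pr * if (x[i, j] == 1L) p1 else 1 - p1
      }
      tot <- tot + pr
      for (j in seq_len(J)) mem[j, z[j]] <- mem[j, z[j]] + pr
      sen <- sen + s * pr
    }
  }
  list(membership = mem / tot, sensitization = sen / tot,
       log_evidence = log(tot))
}

# small deterministic binary block matrix: `blocks` children-groups x
# component-groups, each diagonal block all-positive
block_matrix <- function(children_per_block, comps_per_block, K) {
  N <- children_per_block * K
  J <- comps_per_block * K
  x <- matrix(0L, N, J)
  for (k in seq_len(K)) {
    rows <- (k - 1) * children_per_block + seq_len(children_per_block)
    cols <- (k - 1) * comps_per_block + seq_len(comps_per_block)
    x[rows, cols] <- 1L
  }
  dimnames(x) <- list(paste0("S", seq_len(N)), paste0("C", seq_len(J)))
  x
}
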