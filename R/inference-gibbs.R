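# Collapsed Gibbs sampler for the fixed-parameter model: the child
# sensitization indicators are marginalized analytically given z (as in the
# exact enumerator), and the sampler moves one component assignment at a
# time. Posterior marginals are Rao-Blackwellized: membership accumulates
# the full conditional of each z_j, sensitization accumulates
# P(s_ik = 1 | z, x) at every retained sweep. Unlike deterministic
# mean-field, the sampler does not commit to a single mode, so its marginals
# converge to the exact ones on ambiguous instances.
gibbs_fixed <- function(x, config, params, seed,
                        n_sweeps = 4000L, burn_in = 500L) {
  set.seed(seed)
  N <- nrow(x); J <- ncol(x); K <- params$K
  ll <- emission_loglik(x, params)
  A <- ll$pos; B <- ll$neg
  lth1 <- log(params$theta); lth0 <- log1p(-params$theta)
  lpi <- log(params$pi)
  la2 <- function(a, b) { h <- pmax(a, b); h + log(exp(a - h) + exp(b - h)) }

  z <- sample.int(K, J, replace = TRUE)
  SA <- matrix(0, N, K); SB <- matrix(0, N, K)
  for (k in seq_len(K)) {
    idx <- z == k
    if (any(idx)) {
      SA[, k] <- rowSums(A[, idx, drop = FALSE])
      SB[, k] <- rowSums(B[, idx, drop = FALSE])
    }
  }
  lm <- la2(matrix(lth1, N, K, byrow = TRUE) + SA,
            matrix(lth0, N, K, byrow = TRUE) + SB)
  mem <- matrix(0, J, K)
  sens <- matrix(0, N, K)
  kept <- 0L
  for (sweep in seq_len(n_sweeps)) {
    for (j in seq_len(J)) {
      ko <- z[j]
      SA0 <- SA[, ko] - A[, j]
      SB0 <- SB[, ko] - B[, j]
      lm0 <- la2(lth1[ko] + SA0, lth0[ko] + SB0)
      base <- colSums(lm)
      base[ko] <- sum(lm0)
      tot0 <- sum(base)
      logp <- numeric(K)
      cand <- vector("list", K)
      for (k in seq_len(K)) {
        sa <- if (k == ko) SA0 else SA[, k]
        sb <- if (k == ko) SB0 else SB[, k]
        cl <- la2(lth1[k] + sa + A[, j], lth0[k] + sb + B[, j])
        cand[[k]] <- cl
        logp[k] <- lpi[k] + tot0 - base[k] + sum(cl)
      }
      p <- exp(logp - max(logp)); p <- p / sum(p)
      kn <- sample.int(K, 1L, prob = p)
      if (sweep > burn_in) mem[j, ] <- mem[j, ] + p
      if (kn != ko) {
        SA[, ko] <- SA0; SB[, ko] <- SB0
        SA[, kn] <- SA[, kn] + A[, j]; SB[, kn] <- SB[, kn] + B[, j]
        lm[, ko] <- lm0
        lm[, kn] <- cand[[kn]]
        z[j] <- kn
      }
    }
    # Metropolis label-permutation move: single-site updates cannot jump
    # between permutation-related basins, which otherwise traps the chain
    if (K > 1L) {
      perm <- sample.int(K)
      if (any(perm != seq_len(K))) {
        lm_new <- matrix(0, N, K)
        for (k in seq_len(K)) {
          lm_new[, perm[k]] <- la2(lth1[perm[k]] + SA[, k],
                                   lth0[perm[k]] + SB[, k])
        }
        nk <- tabulate(z, K)
        dlog <- sum(lm_new) - sum(lm) + sum(nk * (lpi[perm] - lpi[seq_len(K)]))
        if (log(stats::runif(1L)) < dlog) {
          z <- perm[z]
          SA[, perm] <- SA; SB[, perm] <- SB
          lm <- lm_new
        }
      }
    }
    if (sweep > burn_in) {
      a <- matrix(lth1, N, K, byrow = TRUE) + SA
      b <- matrix(lth0, N, K, byrow = TRUE) + SB
      sens <- sens + stats::plogis(a - b)
      kept <- kept + 1L
    }
  }
  list(membership = mem / kept, sensitization = sens / kept,
       n_sweeps = n_sweeps, burn_in = burn_in)
}
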