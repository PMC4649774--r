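#' Exact posterior marginals by enumeration (small instances)
#'
#' Sums the joint probability over every component-to-cluster assignment z.
#' Given z (and fixed parameters) the child sensitization indicators are
#' conditionally independent across children and clusters, so they are
#' marginalized analytically rather than enumerated, which keeps the cost at
#' K^J rather than K^J * 2^(N*K). With `params = NULL` the conjugate priors
#' in `config` are integrated analytically instead (Dirichlet-multinomial
#' over z, Beta-binomial over sensitization and per-component emissions),
#' which requires enumerating each cluster's sensitization column (2^N terms)
#' and forbids missing cells.
#'
#' Guards: J <= 10, N <= 10, K <= 3 (the K^J enumeration bound); larger
#' instances are refused.
#'
#' @param x Integer observation matrix (children x components), 0/1 or 0..3.
#' @param config A `model_config`.
#' @param params A `model_params` for fixed-parameter enumeration, or `NULL`
#'   to integrate the conjugate priors.
#' @return A `posterior_summary` with exact `membership` (J x K) and
#'   `sensitization` (N x K) marginals and the log marginal likelihood
#'   (`log_evidence`).
#' @export
fit_exact <- function(x, config, params = NULL) {
  stopifnot(inherits(config, "model_config"))
  mode <- if (is.null(params)) config$emission_mode else params$emission_mode
  x <- as_latent_input(x, mode)
  N <- nrow(x); J <- ncol(x); K <- config$K
  if (J > 10L || N > 10L || K > 3L) {
    stop(sprintf(paste0("instance too large for exact enumeration: require ",
                        "J <= 10, N <= 10, K <= 3 (got J=%d, N=%d, K=%d)"),
                 J, N, K))
  }
  zz <- z_configs(K, J)
  if (is.null(params)) {
    res <- exact_integrated(x, config, zz)
  } else {
    if (params$K != K) stop("params K does not match config K")
    res <- exact_fixed(x, params, zz)
  }
  new_posterior_summary(membership = res$membership,
                        sensitization = res$sensitization,
                        x = x, K = K, method = "exact",
                        log_evidence = res$log_evidence)
}

# all K^J cluster assignments, one row per configuration
z_configs <- function(K, J) {
  n <- K^J
  m <- matrix(0L, n, J)
  t <- 0:(n - 1)
  for (j in seq_len(J)) {
    m[, j] <- (t %% K) + 1L
    t <- t %/% K
  }
  m
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

exact_fixed <- function(x, params, zz) {
  N <- nrow(x); J <- ncol(x); K <- params$K
  ll <- emission_loglik(x, params)
  lth1 <- log(params$theta); lth0 <- log1p(-params$theta)
  lpi <- log(params$pi)
  nz <- nrow(zz)
  logw <- numeric(nz)
  for (t in seq_len(nz)) {
    z <- zz[t, ]
    lm <- 0
    for (k in seq_len(K)) {
      idx <- z == k
      SA <- if (any(idx)) rowSums(ll$pos[, idx, drop = FALSE]) else numeric(N)
      SB <- if (any(idx)) rowSums(ll$neg[, idx, drop = FALSE]) else numeric(N)
      hi <- pmax(lth1[k] + SA, lth0[k] + SB)
      lm <- lm + sum(hi + log(exp(lth1[k] + SA - hi) + exp(lth0[k] + SB - hi)))
    }
    logw[t] <- sum(lpi[z]) + lm
  }
  lZ <- logsumexp(logw)
  w <- exp(logw - lZ)
  membership <- matrix(0, J, K)
  sens <- matrix(0, N, K)
  for (t in seq_len(nz)) {
    z <- zz[t, ]
    for (k in seq_len(K)) {
      idx <- z == k
      membership[idx, k] <- membership[idx, k] + w[t]
      SA <- if (any(idx)) rowSums(ll$pos[, idx, drop = FALSE]) else numeric(N)
      SB <- if (any(idx)) rowSums(ll$neg[, idx, drop = FALSE]) else numeric(N)
      a <- lth1[k] + SA; b <- lth0[k] + SB
      hi <- pmax(a, b)
      sens[, k] <- sens[, k] + w[t] * exp(a - hi) / (exp(a - hi) + exp(b - hi))
    }
  }
  list(membership = membership, sensitization = sens, log_evidence = lZ)
}

exact_integrated <- function(x, config, zz) {
  if (anyNA(x)) stop("integrated exact enumeration does not support missing cells")
  N <- nrow(x); J <- ncol(x); K <- config$K
  C <- if (config$emission_mode == "binary") 2L else 4L
  prior_pos <- if (C == 2L) c(config$b_pos, config$a_pos) else config$dir_pos
  prior_neg <- if (C == 2L) c(config$b_neg, config$a_neg) else config$dir_neg
  # enumerate sensitization columns once: 2^N rows
  S <- z_configs(2L, N) - 1L
  n1 <- rowSums(S)
  ltheta <- lbeta(config$a_theta + n1, config$b_theta + N - n1) -
    lbeta(config$a_theta, config$b_theta)
  # per-category counts among sensitized children, for every component and
  # every candidate sensitization column: list over categories of 2^N x J
  cnt_pos <- lapply(0:(C - 1L), function(c) S %*% (x == c))
  cnt_all <- lapply(0:(C - 1L), function(c) colSums(x == c))
  ldirmult_ratio <- function(counts, prior) {
    # counts: 2^N x J matrix per category in a list; returns 2^N x J log terms
    tot <- Reduce(`+`, counts)
    out <- lgamma(sum(prior)) - lgamma(sum(prior) + tot)
    for (c in seq_along(prior)) {
      out <- out + lgamma(prior[c] + counts[[c]]) - lgamma(prior[c])
    }
    out
  }
  pos_term <- ldirmult_ratio(cnt_pos, prior_pos)
  neg_counts <- lapply(seq_len(C), function(c) {
    sweep(-cnt_pos[[c]], 2L, cnt_all[[c]], `+`)
  })
  neg_term <- ldirmult_ratio(neg_counts, prior_neg)
  percomp <- pos_term + neg_term # 2^N x J: log emission evidence for comp j
                                 # if its cluster's sensitization column is S[r, ]

  nz <- nrow(zz)
  lz_prior <- function(z) {
    nk <- tabulate(z, K)
    lgamma(K * config$alpha) - K * lgamma(config$alpha) +
      sum(lgamma(config$alpha + nk)) - lgamma(K * config$alpha + J)
  }
  cluster_lw <- function(z, k) {
    idx <- z == k
    ltheta + if (any(idx)) rowSums(percomp[, idx, drop = FALSE]) else 0
  }
  # two passes so that per-configuration cluster weights need not be stored
  logw <- numeric(nz)
  for (t in seq_len(nz)) {
    z <- zz[t, ]
    logw[t] <- lz_prior(z) +
      sum(vapply(seq_len(K), function(k) logsumexp(cluster_lw(z, k)), 0))
  }
  lZ <- logsumexp(logw)
  w <- exp(logw - lZ)
  membership <- matrix(0, J, K)
  sens <- matrix(0, N, K)
  for (t in seq_len(nz)) {
    z <- zz[t, ]
    for (k in seq_len(K)) {
      membership[z == k, k] <- membership[z == k, k] + w[t]
      lw <- cluster_lw(z, k)
      pk <- exp(lw - logsumexp(lw))
      sens[, k] <- sens[, k] + w[t] * as.vector(crossprod(S, pk))
    }
  }
  list(membership = membership, sensitization = sens, log_evidence = lZ)
}
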