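#' Approximate posterior inference by mean-field variational Bayes
#'
#' Fits the component-group model with coordinate-ascent variational
#' inference over a fully factorized family: categorical factors for the
#' component cluster assignments, Bernoulli factors for child sensitization,
#' and (unless parameters are fixed) Dirichlet/Beta factors for the mixing
#' weights, sensitization prevalences, and emission distributions. The
#' objective (evidence lower bound) is non-decreasing across iterations
#' within a restart; the best of `n_restarts` seeded restarts by final
#' objective is returned.
#'
#' @param x Integer observation matrix (children x components), 0/1 in binary
#'   mode, 0..3 in quaternary mode; `NA` cells are ignored.
#' @param config A `model_config`.
#' @param seed Master seed; restart r uses a seed derived from `(seed, r)`.
#' @param n_restarts Number of random restarts (default from `config`).
#' @param params Optional fixed `model_params`: inference then runs over the
#'   latent variables only (used for oracle comparisons).
#' @param canonical Relabel clusters into the canonical reporting order
#'   (descending number of hard-assigned components, ties broken by smallest
#'   component index). Default `TRUE`.
#' @param method `"vb"` (default; deterministic, fast, the cohort-scale
#'   workhorse) or `"gibbs"` (collapsed Gibbs with Rao-Blackwellized
#'   marginals, fixed parameters only). Mean-field factors are mode-seeking
#'   and overconfident where the true posterior is ambiguous; the sampler
#'   trades runtime for marginals that converge to the exact ones, and is
#'   the method validated against [fit_exact()] at oracle accuracy.
#' @param n_sweeps,burn_in Gibbs controls.
#' @return A `posterior_summary`: `membership` (J x K), `sensitization`
#'   (N x K), and for `"vb"` the objective value and trace (`elbo`,
#'   `elbo_trace`), `converged`, `n_iter`, `seed`, `restart_elbos`.
#' @export
fit_approximate <- function(x, config, seed = 1L,
                            n_restarts = config$n_restarts,
                            params = NULL, canonical = TRUE,
                            method = c("vb", "gibbs"),
                            n_sweeps = 4000L, burn_in = 500L) {
  stopifnot(inherits(config, "model_config"))
  method <- match.arg(method)
  mode <- if (is.null(params)) config$emission_mode else params$emission_mode
  xm <- as_latent_input(x, mode)
  if (method == "gibbs") {
    if (is.null(params)) stop("method = 'gibbs' requires fixed params")
    g <- gibbs_fixed(xm, config, params, seed = derive_seed(seed, "gibbs"),
                     n_sweeps = n_sweeps, burn_in = burn_in)
    ps <- new_posterior_summary(membership = g$membership,
                                sensitization = g$sensitization,
                                x = xm, K = config$K, method = "gibbs",
                                n_sweeps = g$n_sweeps, burn_in = g$burn_in,
                                seed = seed)
    return(if (canonical) canonicalize_labels(ps) else ps)
  }
  best <- NULL
  restart_elbos <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    # odd restarts seed the responsibilities from a k-means split of the
    # component profiles (strong, well-separated basins); even restarts use
    # symmetric Dirichlet noise (unbiased exploration)
    fit <- vb_once(xm, config, params,
                   seed = derive_seed(seed, "vb-restart", r),
                   init = if (r %% 2L == 1L) "kmeans" else "random")
    restart_elbos[r] <- fit$elbo
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  if (!best$converged) {
    warning("variational fit did not converge within ", config$max_iter,
            " iterations (relative tolerance ", config$tol, ")")
  }
  ps <- new_posterior_summary(membership = best$phi,
                              sensitization = best$r,
                              x = xm, K = config$K, method = "variational",
                              elbo = best$elbo, elbo_trace = best$trace,
                              converged = best$converged,
                              n_iter = best$n_iter, seed = seed,
                              restart_elbos = restart_elbos,
                              emission = best$emission)
  if (canonical) ps <- canonicalize_labels(ps) else ps
}

vb_once <- function(x, config, params, seed, init = "random") {
  set.seed(seed)
  N <- nrow(x); J <- ncol(x); K <- config$K
  C <- if ((if (is.null(params)) config$emission_mode else params$emission_mode)
           == "binary") 2L else 4L
  fixed <- !is.null(params)
  # mixture classes over z: K clusters plus an optional background class in
  # which no child is sensitized (its sensitization column is fixed at 0)
  noise <- !fixed && config$noise_class
  Kz <- K + as.integer(noise)
  # category indicators (NA cells are zero everywhere)
  Xc <- lapply(0:(C - 1L), function(c) {
    m <- matrix(0, N, J)
    m[which(!is.na(x) & x == c)] <- 1
    m
  })
  prior_pos <- if (C == 2L) c(config$b_pos, config$a_pos) else config$dir_pos
  prior_neg <- if (C == 2L) c(config$b_neg, config$a_neg) else config$dir_neg

  # --- initialization ---------------------------------------------------
  phi <- t(vapply(seq_len(J), function(j) rdirichlet1(rep(3, Kz)), numeric(Kz)))
  if (init == "kmeans" && J > K && K > 1L) {
    prof <- t(x); prof[is.na(prof)] <- 0
    km <- tryCatch(stats::kmeans(prof, centers = K, nstart = 2L),
                   error = function(e) NULL)
    if (!is.null(km)) {
      phi <- matrix((1 - 0.85) / (Kz - 1), J, Kz)
      phi[cbind(seq_len(J), km$cluster)] <- 0.85
    }
  }
  if (Kz == 1L) phi <- matrix(1, J, 1L)
  pos01 <- matrix(0, N, J); pos01[which(!is.na(x) & x >= 1L)] <- 1
  obs01 <- matrix(0, N, J); obs01[which(!is.na(x))] <- 1
  phik <- phi[, seq_len(K), drop = FALSE]
  denom <- obs01 %*% phik
  r <- (pos01 %*% phik) / ifelse(denom > 0, denom, 1)
  r[denom == 0] <- 0.5
  r <- pmin(pmax(r, 0.02), 0.98)
  # sensitization column of the background class is identically zero
  rz <- function(r) if (noise) cbind(r, 0) else r

  expectations <- function(phi, r) {
    if (fixed) {
      ll <- emission_loglik(x, params)
      list(A = ll$pos, B = ll$neg,
           elnpi = log(params$pi),
           elnth1 = log(params$theta), elnth0 = log1p(-params$theta),
           kl = 0)
    } else {
      w <- rz(r) %*% t(phi) # N x J: P(child i sensitized to comp j's class)
      kl <- 0
      if (config$emission_scope == "per_component") {
        apos <- matrix(0, J, C); aneg <- matrix(0, J, C)
        for (c in seq_len(C)) {
          npos <- colSums(w * Xc[[c]])
          nall <- colSums(Xc[[c]])
          apos[, c] <- prior_pos[c] + npos
          aneg[, c] <- prior_neg[c] + (nall - npos)
        }
        Epos <- digamma(apos) - digamma(rowSums(apos))
        Eneg <- digamma(aneg) - digamma(rowSums(aneg))
        A <- matrix(0, N, J); B <- matrix(0, N, J)
        for (c in seq_len(C)) {
          A <- A + Xc[[c]] * matrix(Epos[, c], N, J, byrow = TRUE)
          B <- B + Xc[[c]] * matrix(Eneg[, c], N, J, byrow = TRUE)
        }
        for (j in seq_len(J)) {
          kl <- kl + dirichlet_kl(apos[j, ], prior_pos) +
            dirichlet_kl(aneg[j, ], prior_neg)
        }
      } else {
        apos <- prior_pos; aneg <- prior_neg
        for (c in seq_len(C)) {
          npos <- sum(w * Xc[[c]])
          apos[c] <- apos[c] + npos
          aneg[c] <- aneg[c] + (sum(Xc[[c]]) - npos)
        }
        Epos <- digamma(apos) - digamma(sum(apos))
        Eneg <- digamma(aneg) - digamma(sum(aneg))
        A <- matrix(0, N, J); B <- matrix(0, N, J)
        for (c in seq_len(C)) {
          A <- A + Xc[[c]] * Epos[c]
          B <- B + Xc[[c]] * Eneg[c]
        }
        kl <- dirichlet_kl(apos, prior_pos) + dirichlet_kl(aneg, prior_neg)
      }
      ath <- config$a_theta + colSums(r)
      bth <- config$b_theta + N - colSums(r)
      api <- config$alpha + colSums(phi)
      kl <- kl + dirichlet_kl(api, rep(config$alpha, Kz)) +
        sum(vapply(seq_len(K), function(k) {
          dirichlet_kl(c(ath[k], bth[k]), c(config$a_theta, config$b_theta))
        }, 0))
      list(A = A, B = B,
           elnpi = digamma(api) - digamma(sum(api)),
           elnth1 = digamma(ath) - digamma(ath + bth),
           elnth0 = digamma(bth) - digamma(ath + bth),
           kl = kl)
    }
  }

  emission_means <- function(phi, r) {
    if (fixed) return(list(pos = NULL, neg = NULL))
    w <- rz(r) %*% t(phi)
    apos <- matrix(0, J, C); aneg <- matrix(0, J, C)
    for (c in seq_len(C)) {
      npos <- colSums(w * Xc[[c]])
      nall <- colSums(Xc[[c]])
      if (config$emission_scope == "per_component") {
        apos[, c] <- prior_pos[c] + npos
        aneg[, c] <- prior_neg[c] + (nall - npos)
      } else {
        apos[, c] <- prior_pos[c] + sum(npos)
        aneg[, c] <- prior_neg[c] + sum(nall - npos)
      }
    }
    list(pos = apos / rowSums(apos), neg = aneg / rowSums(aneg))
  }

  trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    e <- expectations(phi, r)
    # q(s)
    logit <- matrix(e$elnth1 - e$elnth0, N, K, byrow = TRUE) +
      (e$A - e$B) %*% phi[, seq_len(K), drop = FALSE]
    r <- stats::plogis(logit)
    # q(z)
    lphi <- matrix(e$elnpi, J, Kz, byrow = TRUE) +
      t(e$A) %*% rz(r) + t(e$B) %*% (1 - rz(r))
    phi <- softmax_rows(lphi)
    # objective with expectations consistent with current (phi, r)
    e <- expectations(phi, r)
    elik <- sum(phi * (t(e$A) %*% rz(r) + t(e$B) %*% (1 - rz(r))))
    ez <- sum(phi * matrix(e$elnpi, J, Kz, byrow = TRUE))
    es <- sum(r * matrix(e$elnth1, N, K, byrow = TRUE) +
                (1 - r) * matrix(e$elnth0, N, K, byrow = TRUE))
    hz <- -sum(phi * log(pmax(phi, 1e-300)))
    hs <- -sum(r * log(pmax(r, 1e-300)) + (1 - r) * log(pmax(1 - r, 1e-300)))
    elbo <- elik + ez + es + hz + hs - e$kl
    trace <- c(trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) <= config$tol * (abs(elbo_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (it >= config$max_iter) break
    elbo_prev <- elbo
  }
  em <- emission_means(phi, r)
  list(phi = phi, r = r, elbo = trace[length(trace)], trace = trace,
       converged = converged, n_iter = it, emission = em)
}

dirichlet_kl <- function(a, b) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

new_posterior_summary <- function(membership, sensitization, x, K, method,
                                  ...) {
  rownames(membership) <- colnames(x) %||% paste0("C", seq_len(nrow(membership)))
  cn <- paste0("CG", seq_len(K))
  if (ncol(membership) == K + 1L) cn <- c(cn, "noise")
  colnames(membership) <- cn
  rownames(sensitization) <- rownames(x) %||% paste0("S", seq_len(nrow(sensitization)))
  colnames(sensitization) <- paste0("CG", seq_len(K))
  structure(c(list(membership = membership, sensitization = sensitization,
                   K = K, method = method), list(...)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary: %d components x %d clusters, %d children; %s>\n",
              nrow(x$membership), x$K, nrow(x$sensitization), x$method))
  if (!is.null(x$elbo)) cat(sprintf("  objective: %.4f (converged: %s)\n",
                                    x$elbo, isTRUE(x$converged)))
  if (!is.null(x$log_evidence)) cat(sprintf("  log evidence: %.6f\n", x$log_evidence))
  invisible(x)
}

# Canonical reporting order: clusters sorted by descending number of
# hard-assigned components; ties broken by the smallest index among each
# cluster's components. Empty clusters come last; a background "noise"
# class keeps its position after the K clusters.
canonicalize_labels <- function(ps) {
  hard <- max.col(ps$membership, ties.method = "first")
  cnt <- tabulate(hard, ps$K)
  first_idx <- vapply(seq_len(ps$K), function(k) {
    i <- which(hard == k)
    if (length(i)) min(i) else Inf
  }, 0)
  ord <- order(-cnt, first_idx)
  permute_posterior(ps, ord)
}

# permute the K cluster labels (any trailing noise column stays in place)
permute_posterior <- function(ps, perm) {
  K <- ps$K
  full <- c(perm, setdiff(seq_len(ncol(ps$membership)), seq_len(K)))
  cn <- colnames(ps$membership)
  ps$membership <- ps$membership[, full, drop = FALSE]
  colnames(ps$membership) <- cn
  ps$sensitization <- ps$sensitization[, perm, drop = FALSE]
  colnames(ps$sensitization) <- paste0("CG", seq_len(K))
  ps
}

#' Align cluster labels between two posterior summaries
#'
#' Mixture posteriors are invariant to cluster relabelling, so summaries from
#' different runs must be aligned before comparison. Finds the permutation of
#' `b`'s clusters maximizing the summed membership agreement with `a`
#' (exact assignment search over the K! permutations; K is small here).
#'
#' @param a,b `posterior_summary` objects with equal J, N and K.
#' @return List with `permutation` (b's column k maps from `permutation[k]`)
#'   and `aligned` (the permuted copy of `b`).
#' @export
align_labels <- function(a, b) {
  if (a$K != b$K) stop("K mismatch between posterior summaries")
  if (nrow(a$membership) != nrow(b$membership) ||
      nrow(a$sensitization) != nrow(b$sensitization)) stop("dimension mismatch")
  # match component rows by name when both sides carry names, so summaries
  # fitted on column-permuted copies of the same matrix are comparable
  ra <- rownames(a$membership); rb <- rownames(b$membership)
  if (!is.null(ra) && !is.null(rb) && setequal(ra, rb) && !all(ra == rb)) {
    b$membership <- b$membership[match(ra, rb), , drop = FALSE]
  }
  ka <- seq_len(a$K)
  M <- crossprod(a$membership[, ka, drop = FALSE],
                 b$membership[, ka, drop = FALSE]) # K x K agreement
  perms <- permutations_k(a$K)
  score <- apply(perms, 1L, function(p) sum(M[cbind(seq_len(a$K), p)]))
  best <- perms[which.max(score), ]
  list(permutation = best, aligned = permute_posterior(b, best))
}

#' Write posterior summary tables
#'
#' Emits membership and sensitization marginals as TSV plus a JSON
#' diagnostics sidecar (objective, convergence, seed, restarts).
#'
#' @param ps A `posterior_summary`.
#' @param dir Output directory (created if needed).
#' @export
write_posterior_summary <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(ps$membership, file.path(dir, "membership.tsv"), "component")
  write_matrix_tsv(ps$sensitization, file.path(dir, "sensitization.tsv"), "subject")
  diag <- ps[setdiff(names(ps), c("membership", "sensitization"))]
  diag$elbo_trace <- NULL
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
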