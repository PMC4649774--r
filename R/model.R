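#' Model configuration for the component-group latent variable model
#'
#' The generative model: each allergen component j belongs to one of K latent
#' clusters, z_j ~ Categorical(pi) with pi ~ Dirichlet(alpha); each child i is
#' sensitized or not to each cluster k, s_ik ~ Bernoulli(theta_k) with
#' theta_k ~ Beta(a_theta, b_theta); the observed test x_ij depends only on
#' z_j and s_i,z_j. In binary mode x_ij ~ Bernoulli(p_pos) when the child is
#' sensitized to the component's cluster and Bernoulli(p_neg) otherwise, with
#' Beta priors keeping p_pos high and p_neg low. In quaternary mode the two
#' Bernoullis are replaced by 4-category emissions over
#' \{no, low, medium, high\} with Dirichlet priors, the sensitized one
#' placing its mass on the higher categories.
#'
#' @param K Number of clusters (default 3).
#' @param alpha Symmetric Dirichlet concentration for the mixing weights.
#' @param a_theta,b_theta Beta hyperparameters for per-cluster sensitization
#'   prevalence.
#' @param a_pos,b_pos Beta hyperparameters for the positive-test probability
#'   given sensitized (binary mode).
#' @param a_neg,b_neg Beta hyperparameters given not sensitized.
#' @param emission_mode `"binary"` or `"quaternary"`.
#' @param emission_scope `"per_component"` (default: each component has its
#'   own emission probabilities under the shared priors) or `"shared"` (one
#'   emission distribution for all components). Per-component emissions let a
#'   component whose positives do not align with any cluster shrink toward
#'   the nonsensitized prior and come out with diffuse membership instead of
#'   being forced into the least-bad cluster.
#' @param dir_pos,dir_neg Length-4 Dirichlet hyperparameters for the
#'   quaternary emissions (sensitized / not sensitized).
#' @param noise_class Include a background class alongside the K clusters:
#'   a component in it is positive only at its nonsensitized emission rate
#'   for every child (no sensitization pattern). Components whose positives
#'   do not align with any cluster's sensitized children gravitate there
#'   instead of being forced into the least-bad cluster, and come out
#'   unassigned ("non-CG"). Used by the full-Bayes variational fit; ignored
#'   when parameters are fixed.
#' @param max_iter,tol Variational convergence controls: stop when the
#'   relative change in the objective falls below `tol` or after `max_iter`
#'   iterations.
#' @param n_restarts Random restarts for approximate inference.
#' @return A list with class `"model_config"`.
#' @export
model_config <- function(K = 3L, alpha = 1,
                         a_theta = 1, b_theta = 4,
                         a_pos = 4, b_pos = 2,
                         a_neg = 1, b_neg = 30,
                         emission_mode = c("binary", "quaternary"),
                         emission_scope = c("per_component", "shared"),
                         dir_pos = c(2, 3, 5, 2),
                         dir_neg = c(29, 1, 0.7, 0.3),
                         noise_class = TRUE,
                         max_iter = 2000L, tol = 1e-8,
                         n_restarts = 10L) {
  emission_mode <- match.arg(emission_mode)
  emission_scope <- match.arg(emission_scope)
  hp <- c(alpha, a_theta, b_theta, a_pos, b_pos, a_neg, b_neg, dir_pos, dir_neg)
  stopifnot(K >= 1L, all(hp > 0), length(dir_pos) == 4L, length(dir_neg) == 4L)
  if (a_pos / (a_pos + b_pos) <= a_neg / (a_neg + b_neg)) {
    stop("prior mean of sensitized emission must exceed the nonsensitized one")
  }
  mean_hi <- function(d) sum(d[2:4]) / sum(d)
  if (mean_hi(dir_pos) <= mean_hi(dir_neg)) {
    stop("quaternary sensitized prior must place more mass on categories >= low")
  }
  structure(list(K = as.integer(K), alpha = alpha,
                 a_theta = a_theta, b_theta = b_theta,
                 a_pos = a_pos, b_pos = b_pos, a_neg = a_neg, b_neg = b_neg,
                 emission_mode = emission_mode, emission_scope = emission_scope,
                 dir_pos = dir_pos, dir_neg = dir_neg,
                 noise_class = isTRUE(noise_class),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts)),
            class = "model_config")
}

#' Serialize / restore a model configuration
#' @param config A `model_config`.
#' @param path File path; `.json` writes JSON, anything else YAML.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_config, x)
}

#' Fixed model parameters
#'
#' @param pi K-vector of mixing weights (simplex).
#' @param theta K-vector of per-cluster sensitization probabilities.
#' @param p_pos,p_neg Emission probability of a positive test given sensitized
#'   / not sensitized (binary mode), or length-4 simplexes over the
#'   categories (quaternary mode).
#' @param emission_mode `"binary"` or `"quaternary"`.
#' @export
model_params <- function(pi, theta, p_pos, p_neg,
                         emission_mode = c("binary", "quaternary")) {
  emission_mode <- match.arg(emission_mode)
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(pi > 0),
            all(theta > 0 & theta < 1), length(theta) == length(pi))
  if (emission_mode == "binary") {
    stopifnot(length(p_pos) == 1L, length(p_neg) == 1L,
              p_pos > 0, p_pos < 1, p_neg > 0, p_neg < 1, p_pos >= p_neg)
  } else {
    stopifnot(length(p_pos) == 4L, length(p_neg) == 4L,
              abs(sum(p_pos) - 1) < 1e-8, abs(sum(p_neg) - 1) < 1e-8,
              all(p_pos > 0), all(p_neg > 0))
  }
  structure(list(pi = pi, theta = theta, p_pos = p_pos, p_neg = p_neg,
                 emission_mode = emission_mode, K = length(pi)),
            class = "model_params")
}

# per-cell log emission probabilities under sensitized / nonsensitized state.
# x: integer matrix, 0/1 (binary) or 0..3 (quaternary); NA -> 0 contribution.
emission_loglik <- function(x, params) {
  if (params$emission_mode == "binary") {
    lp <- c(log1p(-params$p_pos), log(params$p_pos))
    ln <- c(log1p(-params$p_neg), log(params$p_neg))
  } else {
    lp <- log(params$p_pos)
    ln <- log(params$p_neg)
  }
  A <- matrix(0, nrow(x), ncol(x))
  B <- matrix(0, nrow(x), ncol(x))
  ok <- !is.na(x)
  A[ok] <- lp[x[ok] + 1L]
  B[ok] <- ln[x[ok] + 1L]
  list(pos = A, neg = B)
}

#' Log joint probability of data and latent state under fixed parameters
#'
#' Computes log p(z | pi) + log p(s | theta) + log p(x | z, s, emissions).
#' Missing cells of `x` contribute nothing.
#'
#' @param x Binary (or quaternary-coded 0..3) integer matrix, children in
#'   rows, components in columns.
#' @param state List with `z` (length-J integer cluster assignment, 1..K) and
#'   `s` (N-by-K binary matrix).
#' @param params A `model_params`.
#' @param config A `model_config` (supplies K for validation).
#' @return Scalar log probability.
#' @export
log_joint <- function(x, state, params, config = NULL) {
  x <- as_latent_input(x, params$emission_mode)
  K <- params$K
  if (!is.null(config) && config$K != K) stop("config K does not match params K")
  z <- as.integer(state$z)
  s <- state$s
  if (length(z) != ncol(x)) stop("length(z) must equal ncol(x)")
  if (!all(dim(s) == c(nrow(x), K))) stop("s must be N x K")
  if (!all(z >= 1L & z <= K)) stop("z values must lie in 1..K")
  if (!all(s %in% c(0, 1))) stop("s must be binary")

  ll <- emission_loglik(x, params)
  # component state per cell: s_{i, z_j}
  s_cell <- s[, z, drop = FALSE]
  lp_x <- sum(s_cell * ll$pos + (1 - s_cell) * ll$neg)
  lp_z <- sum(log(params$pi)[z])
  lp_s <- sum(s * rep(log(params$theta), each = nrow(s)) +
                (1 - s) * rep(log1p(-params$theta), each = nrow(s)))
  lp_x + lp_z + lp_s
}

# validate/coerce an observation matrix for the latent model
as_latent_input <- function(x, emission_mode) {
  m <- unclass(x)
  if (!is.matrix(m)) stop("x must be a matrix")
  storage.mode(m) <- "integer"
  vals <- m[!is.na(m)]
  top <- if (emission_mode == "binary") 1L else 3L
  if (length(vals) && (min(vals) < 0L || max(vals) > top)) {
    stop("x has values outside 0..", top, " for ", emission_mode, " mode")
  }
  m
}

#' Ancestral sample from the generative model
#'
#' Draws parameters from the priors in `config`, then latents and data,
#' reproducibly under `seed`. Useful for prior-predictive checks and small
#' oracle instances.
#'
#' @param config A `model_config`.
#' @param N,J Numbers of children and components.
#' @param seed Integer seed.
#' @param params Optional fixed `model_params`; when supplied only the
#'   latents and data are drawn.
#' @return List with `params`, `state` (z, s) and `x`.
#' @export
sample_from_prior <- function(config, N, J, seed = 1L, params = NULL) {
  stopifnot(inherits(config, "model_config"), N >= 1L, J >= 1L)
  set.seed(derive_seed(seed, "prior"))
  K <- config$K
  if (is.null(params)) {
    pi <- rdirichlet1(rep(config$alpha, K))
    theta <- stats::rbeta(K, config$a_theta, config$b_theta)
    if (config$emission_mode == "binary") {
      p_pos <- stats::rbeta(1L, config$a_pos, config$b_pos)
      p_neg <- stats::rbeta(1L, config$a_neg, config$b_neg)
      if (p_neg > p_pos) { tmp <- p_pos; p_pos <- p_neg; p_neg <- tmp }
    } else {
      p_pos <- rdirichlet1(config$dir_pos)
      p_neg <- rdirichlet1(config$dir_neg)
    }
    theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    params <- model_params(pi, theta, p_pos, p_neg, config$emission_mode)
  }
  z <- sample.int(K, J, replace = TRUE, prob = params$pi)
  s <- matrix(stats::rbinom(N * K, 1L, rep(params$theta, each = N)), N, K)
  x <- matrix(NA_integer_, N, J)
  for (j in seq_len(J)) {
    sj <- s[, z[j]]
    if (params$emission_mode == "binary") {
      pr <- ifelse(sj == 1L, params$p_pos, params$p_neg)
      x[, j] <- stats::rbinom(N, 1L, pr)
    } else {
      x[, j] <- ifelse(sj == 1L,
                       sample.int(4L, N, replace = TRUE, prob = params$p_pos),
                       sample.int(4L, N, replace = TRUE, prob = params$p_neg)) - 1L
    }
  }
  rownames(x) <- paste0("S", seq_len(N))
  colnames(x) <- paste0("C", seq_len(J))
  list(params = params, state = list(z = z, s = s), x = x)
}

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  if (sum(g) == 0) g <- a / sum(a) # degenerate guard
  g / sum(g)
}
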