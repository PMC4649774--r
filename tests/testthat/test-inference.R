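test_that("exact single-observation posteriors reproduce Bayes' rule", {
  cfg <- model_config(K = 1L)
  par <- model_params(pi = 1, theta = 0.5, p_pos = 0.8, p_neg = 0.1)
  ex1 <- fit_exact(matrix(1L, 1, 1), cfg, par)
  expect_equal(ex1$sensitization[1, 1], 0.5 * 0.8 / (0.5 * 0.8 + 0.5 * 0.1))
  ex0 <- fit_exact(matrix(0L, 1, 1), cfg, par)
  expect_equal(ex0$sensitization[1, 1], 0.5 * 0.2 / (0.5 * 0.2 + 0.5 * 0.9))
})

test_that("exact marginals agree with an independent full enumerator", {
  cfg <- model_config(K = 2L)
  par <- model_params(pi = c(0.6, 0.4), theta = c(0.45, 0.2),
                      p_pos = 0.85, p_neg = 0.07)
  for (sd in 1:3) {
    sim <- sample_from_prior(cfg, N = 4, J = 4, seed = 300 + sd, params = par)
    ex <- fit_exact(sim$x, cfg, par)
    br <- brute_posterior(sim$x, par)
    expect_lt(max(abs(ex$membership - br$membership)), 1e-10)
    expect_lt(max(abs(ex$sensitization - br$sensitization)), 1e-10)
    expect_equal(ex$log_evidence, br$log_evidence, tolerance = 1e-10)
  }
})

test_that("exact enumeration refuses oversized instances, naming the bound", {
  cfg <- model_config(K = 2L)
  par <- model_params(pi = c(0.5, 0.5), theta = c(0.3, 0.3),
                      p_pos = 0.8, p_neg = 0.1)
  expect_error(fit_exact(matrix(0L, 11, 4), cfg, par), "N <= 10")
  expect_error(fit_exact(matrix(0L, 4, 11), cfg, par), "J <= 10")
})

test_that("membership rows sum to one and sensitization stays in [0,1]", {
  cfg <- model_config(K = 3L)
  sim <- sample_from_prior(cfg, N = 30, J = 12, seed = 5,
                           params = model_params(pi = c(0.4, 0.3, 0.3),
                                                 theta = c(0.5, 0.3, 0.2),
                                                 p_pos = 0.85, p_neg = 0.03))
  ps <- fit_approximate(sim$x, cfg, seed = 1, n_restarts = 4)
  expect_equal(unname(rowSums(ps$membership)), rep(1, 12), tolerance = 1e-8)
  expect_true(all(ps$sensitization >= 0 & ps$sensitization <= 1))
})

test_that("posterior s is monotone in the data under exact inference", {
  # flipping one cell from 0 to 1 for a cluster-k component must strictly
  # increase that child's P(s_ik = 1 | x)
  cfg <- model_config(K = 2L)
  par <- model_params(pi = c(0.5, 0.5), theta = c(0.4, 0.3),
                      p_pos = 0.8, p_neg = 0.1)
  sim <- sample_from_prior(cfg, N = 4, J = 5, seed = 17, params = par)
  x <- sim$x
  cell <- which(x == 0L, arr.ind = TRUE)[1, ]
  ex0 <- fit_exact(x, cfg, par)
  x2 <- x
  x2[cell[1], cell[2]] <- 1L
  ex1 <- fit_exact(x2, cfg, par)
  # average over the component's cluster membership: both cluster marginals
  # weighted; check the dominant cluster of that component
  k <- which.max(ex0$membership[cell[2], ])
  expect_gt(ex1$sensitization[cell[1], k], ex0$sensitization[cell[1], k])
})

test_that("variational objective is non-decreasing within a restart", {
  cfg <- model_config(K = 2L)
  sim <- sample_from_prior(cfg, N = 25, J = 10, seed = 9,
                           params = model_params(pi = c(0.5, 0.5),
                                                 theta = c(0.5, 0.25),
                                                 p_pos = 0.9, p_neg = 0.05))
  ps <- fit_approximate(sim$x, cfg, seed = 4, n_restarts = 1)
  expect_true(all(diff(ps$elbo_trace) > -1e-6 * (abs(ps$elbo) + 1)))
})

test_that("K = 1 gives membership exactly one and seeded runs are identical", {
  cfg1 <- model_config(K = 1L, noise_class = FALSE)
  x <- matrix(rbinom(40, 1, 0.4), 8, 5)
  ps <- fit_approximate(x, cfg1, seed = 2, n_restarts = 2)
  expect_true(all(ps$membership == 1))

  cfg <- model_config(K = 2L)
  a <- fit_approximate(x, cfg, seed = 31, n_restarts = 3)
  b <- fit_approximate(x, cfg, seed = 31, n_restarts = 3)
  expect_identical(a$membership, b$membership)
  expect_identical(a$sensitization, b$sensitization)
})

test_that("noise-free blocks are recovered with near-certain memberships", {
  x <- block_matrix(4, 3, 3) # 12 children x 9 components, 3 perfect blocks
  cfg <- model_config(K = 3L)
  ps <- fit_approximate(x, cfg, seed = 6, n_restarts = 6)
  expect_true(all(apply(ps$membership[, 1:3], 1, max) > 0.99))
  hard <- apply(ps$membership[, 1:3], 1, which.max)
  expect_equal(length(unique(hard[1:3])), 1L)
  expect_equal(length(unique(hard[4:6])), 1L)
  expect_equal(length(unique(hard[7:9])), 1L)
  expect_equal(length(unique(hard[c(1, 4, 7)])), 3L)
  # and the approximate fit agrees with the exact oracle on a 9x9 sub-block
  par <- model_params(pi = rep(1 / 3, 3), theta = rep(1 / 3, 3),
                      p_pos = 0.95, p_neg = 0.02)
  xs <- x[1:9, ]
  ex <- fit_exact(xs, model_config(K = 3L), par)
  ap <- fit_approximate(xs, model_config(K = 3L), seed = 8, params = par,
                        canonical = FALSE, method = "gibbs",
                        n_sweeps = 2000, burn_in = 300)
  al <- align_labels(ex, ap)$aligned
  expect_lt(max(abs(al$membership - ex$membership)), 0.05)
  expect_lt(max(abs(al$sensitization - ex$sensitization)), 0.05)
})

test_that("permuting components permutes memberships and fixes sensitization", {
  cfg <- model_config(K = 2L)
  sim <- sample_from_prior(cfg, N = 20, J = 8, seed = 13,
                           params = model_params(pi = c(0.5, 0.5),
                                                 theta = c(0.5, 0.2),
                                                 p_pos = 0.9, p_neg = 0.05))
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  a <- fit_approximate(sim$x, cfg, seed = 3, n_restarts = 3, canonical = FALSE)
  b <- fit_approximate(sim$x[, perm], cfg, seed = 3, n_restarts = 3,
                       canonical = FALSE)
  al <- align_labels(a, b)
  expect_lt(max(abs(al$aligned$membership[rownames(a$membership), ] -
                      a$membership)), 0.02)
  expect_lt(max(abs(al$aligned$sensitization - a$sensitization)), 0.02)
})

test_that("label alignment recovers planted permutations", {
  cfg <- model_config(K = 3L)
  sim <- sample_from_prior(cfg, N = 15, J = 9, seed = 23,
                           params = model_params(pi = rep(1 / 3, 3),
                                                 theta = c(0.5, 0.3, 0.2),
                                                 p_pos = 0.9, p_neg = 0.05))
  a <- fit_approximate(sim$x, cfg, seed = 2, n_restarts = 3, canonical = FALSE)
  b <- a
  swap <- c(3L, 1L, 2L)
  b$membership[, swap] <- b$membership[, 1:3]
  b$sensitization[, swap] <- b$sensitization[, 1:3]
  al <- align_labels(a, b)
  expect_equal(al$aligned$membership, a$membership)
  expect_equal(al$aligned$sensitization, a$sensitization)
  # identity case
  expect_equal(align_labels(a, a)$permutation, 1:3)
  # alignment never lowers agreement: exhaustive over all 3! permutations
  agree <- function(m1, m2) sum(m1[, 1:3] * m2[, 1:3])
  base <- agree(a$membership, b$membership)
  expect_gte(agree(a$membership, al$aligned$membership), base)
  expect_error(align_labels(a, fit_approximate(sim$x, model_config(K = 2L),
                                               seed = 1, n_restarts = 1)),
               "K mismatch")
})

test_that("exact conjugate-integration marginals obey closed forms and symmetry", {
  cfg <- model_config(K = 1L)
  # single cell, K = 1: evidence and sensitization have closed forms under
  # the conjugate priors: P(x=1) = E[theta]E[p_pos] + E[1-theta]E[p_neg]
  ex <- fit_exact(matrix(1L, 1, 1), cfg)
  Eth <- cfg$a_theta / (cfg$a_theta + cfg$b_theta)
  Epp <- cfg$a_pos / (cfg$a_pos + cfg$b_pos)
  Epn <- cfg$a_neg / (cfg$a_neg + cfg$b_neg)
  ev <- Eth * Epp + (1 - Eth) * Epn
  expect_equal(ex$log_evidence, log(ev), tolerance = 1e-10)
  expect_equal(unname(ex$sensitization[1, 1]), Eth * Epp / ev, tolerance = 1e-10)

  # exchangeable cluster labels: marginal memberships are uniform, yet the
  # model evidence separates block structure from scrambled data
  x <- block_matrix(4, 3, 2)
  cfg2 <- model_config(K = 2L)
  ex2 <- fit_exact(x, cfg2)
  expect_equal(unname(rowSums(ex2$membership)), rep(1, 6), tolerance = 1e-8)
  expect_true(all(abs(ex2$membership - 0.5) < 1e-6))
  set.seed(1)
  xs <- matrix(sample(x), nrow(x))
  ex3 <- fit_exact(xs, cfg2)
  expect_gt(ex2$log_evidence, ex3$log_evidence)
  expect_error(fit_exact(matrix(c(0L, NA), 1), cfg2), "missing")
})

test_that("held-out likelihood comparison prefers the true cluster count", {
  set.seed(77)
  x <- block_matrix(15, 5, 3) # deterministic blocks plus symmetric flip noise
  noise <- matrix(rbinom(length(x), 1, 0.05), nrow(x))
  x <- abs(x - noise)
  cmp <- compare_k(x, model_config(), Ks = c(1, 3), seed = 2, n_restarts = 2)
  expect_equal(cmp$K[which.max(cmp$heldout_loglik)], 3)
})
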