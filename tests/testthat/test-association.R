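make_2x2 <- function(a, b, c, d) {
  # a exposed cases, b exposed non-cases, c unexposed cases, d unexposed non-cases
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(x = matrix(x, ncol = 1, dimnames = list(NULL, "CG1")), y = y)
}

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  t22 <- make_2x2(30, 20, 10, 40)
  res <- fit_binary_outcome(t22$x, t22$y)
  expect_equal(res$or, (30 * 40) / (20 * 10), tolerance = 1e-6)
  # Wald CI from the closed form exp(ln OR +/- 1.96 sqrt(sum of reciprocals))
  se <- sqrt(1 / 30 + 1 / 20 + 1 / 10 + 1 / 40)
  zq <- stats::qnorm(0.975)
  expect_equal(res$ci_lo, exp(log(6) - zq * se), tolerance = 1e-6)
  expect_equal(res$ci_hi, exp(log(6) + zq * se), tolerance = 1e-6)
  expect_equal(res$n, 100)
  expect_false(res$separation)
})

test_that("perfect separation is flagged, not reported as a huge OR", {
  y <- rep(c(0, 1), each = 25)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "CG1"))
  res <- fit_binary_outcome(x, y)
  expect_true(res$separation)
})

test_that("multivariate ORs are invariant to CG column order", {
  set.seed(8)
  s <- matrix(rbinom(300, 1, c(0.3, 0.2, 0.1)), 100, 3, byrow = TRUE,
              dimnames = list(NULL, paste0("CG", 1:3)))
  y <- rbinom(100, 1, plogis(-1 + s %*% c(0.5, 1, 1.5)))
  r1 <- fit_binary_outcome(s, y)
  r2 <- fit_binary_outcome(s[, c(3, 1, 2)], y)
  r2 <- r2[match(r1$cg, r2$cg), ]
  expect_equal(r1$or, r2$or, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("binary-outcome input validation works", {
  s <- matrix(runif(30), 10, 3, dimnames = list(NULL, paste0("CG", 1:3)))
  expect_error(fit_binary_outcome(s, rep(1, 10)), "non-event")
  expect_error(fit_binary_outcome(s * 2, rbinom(10, 1, 0.5)), "\\[0, 1\\]")
})

test_that("continuous model reproduces a two-group mean difference", {
  g <- rep(c(0, 1), each = 40)
  y <- ifelse(g == 1, 90, 96.8)
  # an exactly two-valued outcome makes the fit perfect; lm warns about it
  res <- suppressWarnings(
    fit_continuous_outcome(matrix(g, ncol = 1, dimnames = list(NULL, "CG3")), y))
  expect_equal(res$diff, -6.8, tolerance = 1e-10)
  expect_equal(res$emm_sens, 90, tolerance = 1e-10)
  expect_equal(res$emm_nonsens, 96.8, tolerance = 1e-10)
  expect_error(fit_continuous_outcome(matrix(g, ncol = 1), rep(5, 80)),
               "constant")
})

test_that("estimated marginal means agree with emmeans", {
  set.seed(12)
  calls <- matrix(rbinom(240, 1, 0.3), 80, 3,
                  dimnames = list(NULL, paste0("CG", 1:3)))
  y <- 95 + calls %*% c(-2, 1, -6) + rnorm(80, 0, 5)
  res <- fit_continuous_outcome(calls, as.vector(y))
  df <- data.frame(y = as.vector(y), calls)
  fit <- stats::lm(y ~ CG1 + CG2 + CG3, data = df)
  for (g in paste0("CG", 1:3)) {
    em <- as.data.frame(emmeans::emmeans(fit, g, at = setNames(list(c(0, 1)), g),
                                         cov.reduce = mean,
                                         cov.keep = character(0)))
    expect_equal(res$emm_nonsens[res$cg == g], em$emmean[em[[g]] == 0],
                 tolerance = 1e-8)
    expect_equal(res$emm_sens[res$cg == g], em$emmean[em[[g]] == 1],
                 tolerance = 1e-8)
  }
})

test_that("null simulations keep the estimate near zero with nominal coverage", {
  set.seed(30)
  n <- 2000
  cover <- 0
  diffs <- c()
  for (r in 1:60) {
    calls <- matrix(rbinom(n, 1, 0.3), n, 1, dimnames = list(NULL, "CG1"))
    y <- rnorm(n, 100, 10)
    res <- fit_continuous_outcome(calls, y)
    diffs <- c(diffs, res$diff)
    cover <- cover + (res$ci_lo <= 0 && res$ci_hi >= 0)
  }
  expect_lt(abs(mean(diffs)), 0.5) # well under 0.5 SD units
  expect_gt(cover / 60, 0.85)      # ~95% coverage of zero
})

test_that("subgroup descriptions match hand counts", {
  calls <- rbind(c(1, 0), c(1, 1), c(0, 0), c(0, 0), c(0, 1))
  colnames(calls) <- c("CG1", "CG2")
  sc <- structure(list(scores = calls, calls = calls), class = "child_scores")
  out <- data.frame(current_wheeze = c(1, 0, 0, 0, 1),
                    current_asthma = c(1, 1, 0, 0, 0),
                    current_hayfever = c(0, 0, 0, 0, 0),
                    current_eczema = c(0, 1, 1, 0, 0))
  d <- describe_by_group(sc, out)
  expect_equal(d$n, c(2, 2, 2))
  expect_equal(d$pct_current_asthma[d$group == "CG1"], 100)
  expect_equal(d$pct_current_asthma[d$group == "nonsensitized"], 0)
  expect_equal(d$pct_disease_free[d$group == "nonsensitized"], 50)
  # all disease-free cohort
  out0 <- as.data.frame(matrix(0, 5, 4,
                               dimnames = list(NULL, names(out))))
  d0 <- describe_by_group(sc, out0)
  expect_true(all(d0$pct_disease_free == 100))
})
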