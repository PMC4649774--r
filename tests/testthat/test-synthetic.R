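test_that("generator config calibrates theta and intercepts deterministically", {
  cfg <- generator_config()
  expect_equal(cfg$theta[3], 0.085)
  expect_true(cfg$theta[1] > 0 && cfg$theta[1] < 1)
  # the solved theta makes the expected any-positive fraction exact
  fac <- function(th, m) th * (1 - cfg$p_pos)^m + (1 - th) * (1 - cfg$p_neg)^m
  pnone <- prod(mapply(fac, cfg$theta, cfg$cluster_sizes)) *
    (1 - cfg$weak_rate)^cfg$n_weak * (1 - cfg$rare_rate)^cfg$n_rare
  expect_equal(1 - pnone, 0.479, tolerance = 1e-12)
  # intercept calibration: expected prevalence equals the target
  for (nm in names(cfg$outcome_or)) {
    b0 <- cfg$outcome_intercepts[[nm]]
    betas <- log(cfg$outcome_or[[nm]])
    combos <- expand.grid(0:1, 0:1, 0:1)
    p <- sum(apply(combos, 1, function(s) {
      prod(ifelse(s == 1, cfg$theta, 1 - cfg$theta)) *
        plogis(b0 + sum(betas * s))
    }))
    expect_equal(p, unname(cfg$outcome_prevalence[[nm]]), tolerance = 1e-8)
  }
  expect_error(generator_config(theta = c(NA, 0.9, 0.9)), "unattainable")
})

test_that("cohorts are reproducible under seed and sized as configured", {
  a <- generate_cohort(seed = 42)
  b <- generate_cohort(seed = 42)
  expect_identical(a$binary, b$binary)
  expect_identical(a$outcomes_raw, b$outcomes_raw)
  expect_false(identical(unclass(a$binary), unclass(generate_cohort(seed = 43)$binary)))
  expect_equal(dim(a$binary), c(461L, 76L))
  expect_equal(table(a$component_class)[["weak"]], 10L)
  expect_equal(table(a$component_class)[["rare"]], 5L)
})

test_that("the noise-free limit yields a deterministic block indicator", {
  eps <- 1e-12
  cfg <- generator_config(theta = rep(1 - eps, 3),
                          p_pos = 1 - eps, p_neg = eps,
                          q_pos = c(eps, (1 - eps) * c(0.3, 0.5, 0.2)),
                          n_weak = 0L, n_rare = 0L,
                          any_positive_target = 1 - eps)
  co <- generate_cohort(cfg, seed = 1)
  expect_true(all(unclass(co$binary) == 1L))
  expect_true(all(co$s_true == 1L))
})

test_that("emission rates estimated from truth match the configured rates", {
  cfg <- generator_config()
  co <- generate_cohort(cfg, seed = 11)
  x <- unclass(co$binary)
  clustered <- which(co$z_true > 0)
  scell <- co$s_true[, co$z_true[clustered], drop = FALSE]
  xs <- x[, clustered, drop = FALSE]
  n1 <- sum(scell == 1); n0 <- sum(scell == 0)
  p_pos_hat <- sum(xs[scell == 1]) / n1
  p_neg_hat <- sum(xs[scell == 0]) / n0
  expect_lt(abs(p_pos_hat - cfg$p_pos),
            3 * sqrt(cfg$p_pos * (1 - cfg$p_pos) / n1))
  expect_lt(abs(p_neg_hat - cfg$p_neg),
            3 * sqrt(cfg$p_neg * (1 - cfg$p_neg) / n0))
})

test_that("binarized quaternary data equal the binary matrix and ISU discretizes back", {
  co <- generate_cohort(seed = 13)
  expect_identical(unclass(binarize(co$categorical)), unclass(co$binary))
  expect_identical(unclass(discretize_isu(co$isu)), unclass(co$categorical))
})

test_that("outcome prevalences track their calibration targets", {
  cfg <- generator_config()
  prev <- matrix(0, 40, 4)
  for (i in 1:40) {
    co <- generate_cohort(cfg, seed = 500 + i)
    d <- derive_outcomes(co$outcomes_raw)
    prev[i, ] <- c(mean(d$current_wheeze), mean(d$current_asthma),
                   mean(d$current_hayfever), mean(d$current_eczema))
  }
  targets <- unname(cfg$outcome_prevalence[c("current_wheeze", "current_asthma",
                                             "current_hayfever", "current_eczema")])
  expect_true(all(abs(colMeans(prev) - targets) < 0.02))
})

test_that("derived outcomes reproduce the simulated status exactly", {
  co <- generate_cohort(seed = 19)
  d <- derive_outcomes(co$outcomes_raw)
  # the raw questionnaire fields were constructed so the 2-of-3 rule returns
  # the simulated asthma status and wheeze is the shared question
  expect_identical(d$current_wheeze, co$outcomes_raw$wheeze_12mo)
  two_of_three <- as.integer(co$outcomes_raw$asthma_diagnosis_ever +
                               co$outcomes_raw$wheeze_12mo +
                               co$outcomes_raw$asthma_treatment_12mo >= 2)
  expect_identical(d$current_asthma, two_of_three)
})

test_that("truth sidecar is complete and written files round-trip", {
  co <- generate_cohort(seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(sum(truth$cluster_sizes), sum(co$z_true > 0))
  expect_equal(length(truth$z_true), ncol(co$binary))
  m <- read_isu_matrix(file.path(dir, "isu.tsv"))
  expect_identical(unclass(binarize(m)), unclass(co$binary))
  out <- read_outcomes(file.path(dir, "outcomes.tsv"))
  expect_equal(out$subject, co$outcomes_raw$subject)
})
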