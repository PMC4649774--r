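fake_posterior <- function(mem, sens) {
  igegroup:::new_posterior_summary(membership = mem, sensitization = sens,
                                   x = matrix(0L, nrow(sens), nrow(mem),
                                              dimnames = list(rownames(sens),
                                                              rownames(mem))),
                                   K = ncol(sens), method = "test")
}

test_that("components are assigned only above the membership threshold", {
  mem <- rbind(c(0.95, 0.03, 0.02),
               c(0.60, 0.30, 0.10),
               c(0.10, 0.75, 0.15))
  rownames(mem) <- paste0("c", 1:3)
  sens <- matrix(0.5, 2, 3, dimnames = list(c("s1", "s2"), NULL))
  asg <- assign_components(fake_posterior(mem, sens))
  expect_equal(asg$cg, c("CG1", "non-CG", "CG2"))
  # exactly at the threshold is NOT assigned ("greater than 0.7")
  mem2 <- rbind(c(0.7, 0.2, 0.1)); rownames(mem2) <- "c1"
  expect_equal(assign_components(fake_posterior(mem2, sens[1, , drop = FALSE]))$cg,
               "non-CG")
  # raising the threshold never assigns a previously unassigned component
  for (th in c(0.5, 0.7, 0.9)) {
    lo <- assign_components(fake_posterior(mem, sens), th)
    hi <- assign_components(fake_posterior(mem, sens), th + 0.05)
    expect_true(all(hi$cg[lo$cg == "non-CG"] == "non-CG"))
  }
})

test_that("child scores threshold at >= 0.5 and zero-fill excluded subjects", {
  mem <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05), c(0.05, 0.05, 0.9))
  rownames(mem) <- paste0("c", 1:3)
  sens <- rbind(c(0.92, 0.50, 0.49), c(0.10, 0.51, 0.02))
  rownames(sens) <- c("s1", "s2")
  ps <- fake_posterior(mem, sens)
  asg <- assign_components(ps)
  sc <- score_children(ps, asg, all_subjects = c("s1", "s2", "s3"))
  expect_equal(unname(sc$calls["s1", ]), c(1L, 1L, 0L)) # 0.5 counts as sensitized
  expect_equal(unname(sc$scores["s3", ]), c(0, 0, 0))   # filtered child
  expect_equal(unname(sc$calls["s3", ]), c(0L, 0L, 0L))
  # strict comparator drops the boundary case
  sc2 <- score_children(ps, asg, comparator = ">")
  expect_equal(unname(sc2$calls["s1", ]), c(1L, 0L, 0L))
})

test_that("combination counts partition the cohort", {
  calls <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(0, 0, 0))
  colnames(calls) <- paste0("CG", 1:3)
  cc <- combination_counts(calls)
  expect_equal(unname(as.integer(cc$by_count)), c(1L, 1L, 1L, 1L))
  expect_equal(sum(cc$by_count), nrow(calls))
  expect_equal(unname(as.integer(cc$by_pattern[c("CG1", "CG1+CG2", "CG1+CG2+CG3", "none")])),
               rep(1L, 4))
  # all-zero calls
  cc0 <- combination_counts(matrix(0L, 5, 3, dimnames = list(NULL, paste0("CG", 1:3))))
  expect_equal(unname(as.integer(cc0$by_count["exactly_0"])), 5L)
  # raising the sensitization threshold cannot increase any positive count
  mem <- diag(3) * 0.9 + 0.03; rownames(mem) <- paste0("c", 1:3)
  sens <- matrix(runif(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  ps <- fake_posterior(mem, sens)
  asg <- assign_components(ps)
  lo <- combination_counts(score_children(ps, asg, 0.4))
  hi <- combination_counts(score_children(ps, asg, 0.6))
  expect_true(all(cumsum(rev(as.integer(hi$by_count))) <=
                    cumsum(rev(as.integer(lo$by_count)))))
})

test_that("stability analysis is perfect on a separable cohort", {
  x <- block_matrix(20, 4, 3) # 60 children x 12 components, noise-free
  b <- binarize(isu_matrix(x * 1.0))
  st <- stability_analysis(b, model_config(), n_subsets = 4, subset_size = 40,
                           seed = 5, n_restarts = 3)
  within <- c(st$similarity[1:4, 1:4][upper.tri(diag(4))],
              st$similarity[5:8, 5:8][upper.tri(diag(4))],
              st$similarity[9:12, 9:12][upper.tri(diag(4))])
  between <- st$similarity[1:4, 5:8]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_true(isSymmetric(unname(st$similarity)))
  expect_true(all(diag(st$similarity) == 1))
  expect_error(stability_analysis(b, model_config(), subset_size = 100),
               "exceeds")
})

test_that("stability similarity with a single subset is 0/1-valued", {
  x <- block_matrix(15, 3, 2)
  b <- binarize(isu_matrix(x * 1.0))
  st <- stability_analysis(b, model_config(K = 2), n_subsets = 1,
                           subset_size = 20, seed = 3, n_restarts = 2)
  vals <- st$similarity[!is.na(st$similarity)]
  expect_true(all(vals %in% c(0, 1)))
})

test_that("heatmap ordering groups by CG and is deterministic", {
  x <- block_matrix(6, 3, 2)
  b <- binarize(isu_matrix(x * 1.0))
  mem <- rbind(matrix(rep(c(0.95, 0.03, 0.02), 3), 3, byrow = TRUE),
               matrix(rep(c(0.03, 0.95, 0.02), 3), 3, byrow = TRUE))
  rownames(mem) <- colnames(b)
  sens <- cbind(rep(c(0.9, 0.1), each = 6), rep(c(0.1, 0.9), each = 6), 0.1)
  rownames(sens) <- rownames(b)
  ps <- fake_posterior(mem, sens)
  asg <- assign_components(ps)
  sc <- score_children(ps, asg, all_subjects = rownames(b))
  o1 <- heatmap_order(b, asg, sc)
  o2 <- heatmap_order(b, asg, sc)
  expect_identical(o1, o2)
  # CG1 components precede CG2 components
  expect_equal(o1$component_order[1:3], paste0("C", 1:3))
  # reordered matrix has higher within-block than off-block positivity
  m <- unclass(b)[o1$subject_order, o1$component_order]
  blk1 <- mean(m[1:6, 1:3]); off <- mean(m[1:6, 4:6])
  expect_gt(blk1, off)
})
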