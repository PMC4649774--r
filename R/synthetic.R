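#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the study cohort: 461
#' children; three latent component groups of 27, 7 and 27 components (a
#' pollen-like, a mite-like and a diverse animal/plant/fungal group); 10
#' "weak" components with low unpatterned positivity that should end up
#' unassigned; 5 "rare" components expected to fail the >= 3 positives
#' filter; binary emissions at `p_pos = 0.85` / `p_neg = 0.001`; and
#' clinical outcomes generated from the true latent sensitizations at the
#' published effect sizes (log odds ratios per CG for wheeze, asthma, hay
#' fever and eczema; a -6.8 percentage-point FEV1 shift for CG3; higher
#' exhaled NO in every CG; greater methacholine responsiveness for CG2).
#'
#' Calibration: the sensitization prevalence of the diverse group (CG3) is
#' 0.085, the published prevalence of the group to which fewest children
#' were sensitized, and the pollen-like group's prevalence is solved in
#' closed form so that the expected fraction of children with at least one
#' positive test equals `any_positive_target` (0.479). Binary outcome
#' intercepts are solved numerically so each outcome's expected prevalence
#' matches its target.
#'
#' @param N Number of children (461).
#' @param cluster_sizes Components per latent cluster, `c(27, 7, 27)`.
#' @param n_weak,weak_rate Unclustered low-signal components and their
#'   independent per-cell positivity.
#' @param n_rare,rare_rate Components planted below the prevalence filter
#'   (expected positives `N * rare_rate` < 3).
#' @param theta Per-cluster sensitization probabilities; entries set to `NA`
#'   (default: the first) are solved from `any_positive_target`.
#' @param p_pos,p_neg Positive-test probability given sensitized / not.
#' @param q_pos,q_neg Quaternary category distributions over
#'   \{no, low, medium, high\}, consistent with `p_pos`/`p_neg` marginally.
#' @param any_positive_target Expected fraction of children with >= 1
#'   positive (0.479).
#' @param outcome_or Named list of per-CG odds ratios for each binary
#'   outcome.
#' @param outcome_prevalence Named marginal prevalence targets.
#' @param fev1_mean,fev1_sd,fev1_shift FEV1 percent-predicted model: normal
#'   baseline plus per-CG additive shifts.
#' @param fvc_ratio_mean,fvc_ratio_sd,fvc_ratio_shift FEV1/FVC ratio model.
#' @param eno_logmean,eno_logsd,eno_logshift Log-scale exhaled-NO model (ppb).
#' @param fall_mean,fall_sd,fall_shift Percent FEV1 fall at the final
#'   methacholine stage (truncated at 0); AHR is a fall > 20.
#' @param cum_dose_mg Cumulative methacholine dose (mg) for the
#'   dose-response slope.
#' @return List of class `"generator_config"` with all probabilities
#'   resolved (solved `theta`, per-outcome intercepts).
#' @export
generator_config <- function(N = 461L,
                             cluster_sizes = c(27L, 7L, 27L),
                             n_weak = 10L, weak_rate = 0.025,
                             n_rare = 5L, rare_rate = 0.0005,
                             theta = c(NA, 0.12, 0.085),
                             p_pos = 0.85, p_neg = 0.001,
                             q_pos = c(0.15, 0.25, 0.45, 0.15),
                             q_neg = NULL,
                             any_positive_target = 0.479,
                             outcome_or = list(
                               current_wheeze   = c(1.48, 4.19, 5.44),
                               current_asthma   = c(1.61, 3.60, 8.20),
                               current_hayfever = c(12.79, 2.52, 1.15),
                               current_eczema   = c(1.10, 1.62, 2.00)),
                             outcome_prevalence = c(
                               current_wheeze = 0.20, current_asthma = 0.125,
                               current_hayfever = 0.16, current_eczema = 0.21),
                             fev1_mean = 98, fev1_sd = 11,
                             fev1_shift = c(0, 0, -6.8),
                             fvc_ratio_mean = 0.86, fvc_ratio_sd = 0.055,
                             fvc_ratio_shift = c(0, 0, -0.02),
                             eno_logmean = log(10), eno_logsd = 0.55,
                             eno_logshift = c(0.4, 0.4, 0.6),
                             fall_mean = 10, fall_sd = 8,
                             fall_shift = c(0, 9, 0),
                             cum_dose_mg = 16) {
  K <- length(cluster_sizes)
  stopifnot(all(cluster_sizes >= 1L), length(theta) == K,
            p_pos > 0, p_pos < 1, p_neg > 0, p_neg < 1, p_pos > p_neg,
            abs(sum(q_pos) - 1) < 1e-8, abs(sum(q_pos[2:4]) - p_pos) < 1e-8)
  if (is.null(q_neg)) {
    q_neg <- c(1 - p_neg, p_neg * c(0.6, 0.3, 0.1))
  }
  stopifnot(abs(sum(q_neg) - 1) < 1e-8, abs(sum(q_neg[2:4]) - p_neg) < 1e-8)

  # solve free theta entries so E[any positive] hits the target exactly
  theta <- solve_theta(theta, cluster_sizes, p_pos, p_neg,
                       n_weak, weak_rate, n_rare, rare_rate,
                       any_positive_target)
  stopifnot(all(theta > 0 & theta < 1))

  intercepts <- vapply(names(outcome_or), function(nm) {
    calibrate_intercept(log(outcome_or[[nm]]), theta, outcome_prevalence[[nm]])
  }, 0)

  structure(list(N = as.integer(N), cluster_sizes = as.integer(cluster_sizes),
                 K = K, n_weak = as.integer(n_weak), weak_rate = weak_rate,
                 n_rare = as.integer(n_rare), rare_rate = rare_rate,
                 theta = theta, p_pos = p_pos, p_neg = p_neg,
                 q_pos = q_pos, q_neg = q_neg,
                 any_positive_target = any_positive_target,
                 outcome_or = outcome_or,
                 outcome_prevalence = outcome_prevalence,
                 outcome_intercepts = intercepts,
                 fev1_mean = fev1_mean, fev1_sd = fev1_sd, fev1_shift = fev1_shift,
                 fvc_ratio_mean = fvc_ratio_mean, fvc_ratio_sd = fvc_ratio_sd,
                 fvc_ratio_shift = fvc_ratio_shift,
                 eno_logmean = eno_logmean, eno_logsd = eno_logsd,
                 eno_logshift = eno_logshift,
                 fall_mean = fall_mean, fall_sd = fall_sd, fall_shift = fall_shift,
                 cum_dose_mg = cum_dose_mg),
            class = "generator_config")
}

# Expected P(no positive at all) factorizes over clusters and noise
# components; one unknown theta entry is solved in closed form.
solve_theta <- function(theta, sizes, p_pos, p_neg, n_weak, weak_rate,
                        n_rare, rare_rate, target) {
  fac <- function(th, m) th * (1 - p_pos)^m + (1 - th) * (1 - p_neg)^m
  noise <- (1 - weak_rate)^n_weak * (1 - rare_rate)^n_rare
  free <- which(is.na(theta))
  if (!length(free)) return(theta)
  if (length(free) > 1L) stop("at most one theta entry may be NA")
  known <- prod(vapply(setdiff(seq_along(theta), free),
                       function(k) fac(theta[k], sizes[k]), 0)) * noise
  Cneed <- (1 - target) / known # required value of fac(theta_free, m)
  m <- sizes[free]
  a <- (1 - p_pos)^m; b <- (1 - p_neg)^m
  th <- (b - Cneed) / (b - a)
  if (th <= 0 || th >= 1) {
    stop("any_positive_target unattainable with the given theta entries")
  }
  theta[free] <- th
  theta
}

# Solve the logistic intercept so the expected outcome prevalence over the
# 2^K independent-Bernoulli sensitization combinations hits the target.
calibrate_intercept <- function(betas, theta, target) {
  K <- length(theta)
  combos <- z_configs(2L, K) - 1L
  pcomb <- apply(combos, 1L, function(s) prod(ifelse(s == 1, theta, 1 - theta)))
  lin <- as.vector(combos %*% betas)
  f <- function(b0) sum(pcomb * stats::plogis(b0 + lin)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Generate a synthetic cohort
#'
#' Ancestral sampling from the calibrated structure in `config`: latent
#' sensitizations per child and cluster, a quaternary category matrix (from
#' which the binary matrix and back-mapped pseudo-ISU values are derived,
#' sampling log-uniformly within each ISU bin), weak and rare noise
#' components, and raw outcome fields generated from the true latents. The
#' raw questionnaire fields are constructed so that [derive_outcomes()]
#' reproduces the simulated outcome status exactly (in particular the
#' asthma 2-of-3 rule).
#'
#' @param config A `generator_config`.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return List of class `"synthetic_cohort"`: `isu` (`isu_matrix`),
#'   `categorical`, `binary`, `z_true` (integer; 0 for weak/rare),
#'   `component_class` ("cluster1".."clusterK", "weak", "rare"), `s_true`
#'   (N x K), `outcomes_raw` (data.frame of raw fields), `config`, `seed`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(seed, "cohort"))
  N <- config$N; K <- config$K
  sizes <- config$cluster_sizes
  J <- sum(sizes) + config$n_weak + config$n_rare

  s <- matrix(stats::rbinom(N * K, 1L, rep(config$theta, each = N)), N, K,
              dimnames = list(sprintf("child_%03d", seq_len(N)),
                              paste0("CG", seq_len(K))))

  z_true <- integer(J)
  comp_class <- character(J)
  comp_names <- character(J)
  j0 <- 0L
  for (k in seq_len(K)) {
    idx <- j0 + seq_len(sizes[k])
    z_true[idx] <- k
    comp_class[idx] <- paste0("cluster", k)
    comp_names[idx] <- sprintf("cg%d_comp%02d", k, seq_len(sizes[k]))
    j0 <- j0 + sizes[k]
  }
  if (config$n_weak) {
    idx <- j0 + seq_len(config$n_weak)
    comp_class[idx] <- "weak"
    comp_names[idx] <- sprintf("weak_comp%02d", seq_len(config$n_weak))
    j0 <- j0 + config$n_weak
  }
  if (config$n_rare) {
    idx <- j0 + seq_len(config$n_rare)
    comp_class[idx] <- "rare"
    comp_names[idx] <- sprintf("rare_comp%02d", seq_len(config$n_rare))
  }

  # categorical matrix: clustered components emit q_pos when the child is
  # sensitized to their cluster and q_neg otherwise; weak/rare components
  # are positive independently at their rates, with positives graded like
  # true sensitizations
  qcond <- config$q_pos[2:4] / sum(config$q_pos[2:4])
  cat_m <- matrix(0L, N, J, dimnames = list(rownames(s), comp_names))
  for (j in seq_len(J)) {
    if (z_true[j] > 0L) {
      sj <- s[, z_true[j]]
      cat_m[, j] <- ifelse(sj == 1L,
                           sample.int(4L, N, TRUE, prob = config$q_pos),
                           sample.int(4L, N, TRUE, prob = config$q_neg)) - 1L
    } else {
      rate <- if (comp_class[j] == "weak") config$weak_rate else config$rare_rate
      pos <- stats::rbinom(N, 1L, rate)
      grade <- sample.int(3L, N, TRUE, prob = qcond)
      cat_m[, j] <- pos * grade
    }
  }
  cat_m <- structure(cat_m, class = c("categorical_matrix", "matrix", "array"))
  bin <- binarize(cat_m)

  # pseudo-ISU back-mapping: log-uniform within each category's ISU bin
  bins_lo <- c(0.01, 0.3, 1, 15)
  bins_hi <- c(0.3, 1, 15, 100)
  u <- matrix(stats::runif(N * J), N, J)
  isu <- exp(log(bins_lo)[cat_m + 1L] +
               u * (log(bins_hi) - log(bins_lo))[cat_m + 1L])
  isu[cat_m == 0L & u < 0.5] <- 0 # many true negatives read exactly 0 ISU
  dim(isu) <- c(N, J)
  dimnames(isu) <- dimnames(cat_m)
  isu <- isu_matrix(isu)

  outcomes_raw <- simulate_outcomes(s, config)
  structure(list(isu = isu, categorical = cat_m, binary = bin,
                 z_true = z_true, component_class = comp_class,
                 s_true = s, outcomes_raw = outcomes_raw,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

simulate_outcomes <- function(s, config) {
  N <- nrow(s)
  draw_binary <- function(nm) {
    lin <- config$outcome_intercepts[[nm]] +
      as.vector(s %*% log(config$outcome_or[[nm]]))
    stats::rbinom(N, 1L, stats::plogis(lin))
  }
  wheeze <- draw_binary("current_wheeze")
  asthma <- draw_binary("current_asthma")
  hay <- draw_binary("current_hayfever")
  ecz <- draw_binary("current_eczema")

  # raw questionnaire fields consistent with the 2-of-3 asthma rule and the
  # shared wheeze question
  diag3 <- integer(N); treat <- integer(N)
  a1w1 <- asthma == 1 & wheeze == 1
  diag3[a1w1] <- stats::rbinom(sum(a1w1), 1L, 0.85)
  treat[a1w1] <- ifelse(diag3[a1w1] == 1L,
                        stats::rbinom(sum(a1w1), 1L, 0.6), 1L)
  a1w0 <- asthma == 1 & wheeze == 0
  diag3[a1w0] <- 1L; treat[a1w0] <- 1L # the only 2-of-3 pattern without wheeze
  a0w0 <- asthma == 0 & wheeze == 0
  diag3[a0w0] <- stats::rbinom(sum(a0w0), 1L, 0.05)
  # asthma=0, wheeze=1 leaves diag3 = treat = 0

  shift <- function(v) as.vector(s %*% v)
  fev1 <- stats::rnorm(N, config$fev1_mean + shift(config$fev1_shift),
                       config$fev1_sd)
  fvc <- stats::rnorm(N, config$fvc_ratio_mean + shift(config$fvc_ratio_shift),
                      config$fvc_ratio_sd)
  fall <- pmax(0, stats::rnorm(N, config$fall_mean + shift(config$fall_shift),
                               config$fall_sd))
  eno <- exp(stats::rnorm(N, config$eno_logmean + shift(config$eno_logshift),
                          config$eno_logsd))
  data.frame(subject = rownames(s),
             asthma_diagnosis_ever = diag3,
             wheeze_12mo = wheeze,
             asthma_treatment_12mo = treat,
             hayfever_now = hay,
             itchy_rash_12mo = ecz,
             fev1_pct_pred = round(pmax(fev1, 30), 1),
             fev1_fvc = round(pmin(pmax(fvc, 0.4), 1), 3),
             fev1_fall_pct = round(fall, 2),
             methacholine_cum_dose_mg = config$cum_dose_mg,
             eno_ppb = round(eno, 1),
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits `isu.tsv` (subjects x components), `outcomes.tsv` (raw fields),
#' `catalog.tsv` (component, source, pfam_family, table1_cg) and a
#' `truth.json` sidecar with the ground-truth latents; the sidecar is never
#' read by the pipeline. All files are plain text; sources and protein
#' families in the catalog are synthetic placeholders named after the
#' generating classes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$isu, file.path(dir, "isu.tsv"), "subject")
  utils::write.table(cohort$outcomes_raw, file.path(dir, "outcomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  catalog <- data.frame(component = colnames(cohort$binary),
                        source = paste0("synthetic_", cohort$component_class),
                        pfam_family = paste0("synthfam_", cohort$component_class),
                        table1_cg = ifelse(cohort$z_true > 0,
                                           paste0("CG", cohort$z_true), "non-CG"),
                        stringsAsFactors = FALSE)
  utils::write.table(catalog, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(seed = cohort$seed,
                cluster_sizes = cohort$config$cluster_sizes,
                theta = cohort$config$theta,
                z_true = cohort$z_true,
                component_class = cohort$component_class,
                component = colnames(cohort$binary),
                s_true = cohort$s_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
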