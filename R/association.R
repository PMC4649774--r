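#' Multivariate logistic regression of a binary outcome on CG scores
#'
#' Fits one logistic model with all CG scores entered simultaneously as
#' quantitative predictors (no other covariates by default) and reports, per
#' CG, the odds ratio exp(beta), its Wald 95\% CI exp(beta +/- 1.96 SE) and
#' the two-sided Wald p-value. Subjects with a missing outcome or score are
#' dropped. Complete or quasi-complete separation is flagged rather than
#' reported as a silently huge OR.
#'
#' @param scores A `child_scores` object, or a numeric matrix of scores in
#'   [0, 1] (subjects x CGs).
#' @param outcome 0/1 vector aligned with the score rows.
#' @param outcome_name Label carried into the result rows.
#' @param conf_level Confidence level (default 0.95).
#' @param covariates Optional data.frame of extra adjustment covariates.
#' @return data.frame with one row per CG: `outcome`, `cg`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `n`, `converged`, `separation`.
#' @export
fit_binary_outcome <- function(scores, outcome, outcome_name = "outcome",
                               conf_level = 0.95, covariates = NULL) {
  sm <- if (inherits(scores, "child_scores")) scores$scores else as.matrix(scores)
  stopifnot(nrow(sm) == length(outcome))
  if (any(sm < 0 | sm > 1, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  df <- data.frame(.y = outcome, sm, check.names = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (!any(df$.y == 1) || !any(df$.y == 0)) {
    stop("outcome needs at least one event and one non-event")
  }
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  )
  cf <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  sep <- detect_separation(fit)
  cgs <- colnames(sm)
  rows <- lapply(cgs, function(g) {
    nm <- if (g %in% rownames(cf)) g else paste0("`", g, "`")
    b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    data.frame(outcome = outcome_name, cg = g,
               or = exp(b), ci_lo = exp(b - zq * se), ci_hi = exp(b + zq * se),
               p = 2 * stats::pnorm(-abs(b / se)),
               n = nrow(df), converged = fit$converged, separation = sep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# quasi-complete separation heuristic: fitted probabilities pinned to 0/1 or
# runaway coefficients
detect_separation <- function(fit) {
  mu <- stats::fitted(fit)
  any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)[-1L]) > 15)
}

#' Linear model of a continuous outcome on binary CG calls
#'
#' Fits `outcome ~ call_CG1 + ... + call_CGK` and reports per CG the adjusted
#' mean difference (sensitized minus not), its 95\% CI and p-value, plus
#' estimated marginal means for the sensitized and nonsensitized groups
#' (other CG calls held at their observed means).
#'
#' @param scores A `child_scores` object (its binary `calls` are the
#'   predictors) or a 0/1 matrix.
#' @param outcome Numeric vector aligned with the rows.
#' @param outcome_name Label carried into the result rows.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with columns `outcome`, `cg`, `diff`, `ci_lo`, `ci_hi`,
#'   `p`, `emm_sens`, `emm_nonsens`, `n`.
#' @export
fit_continuous_outcome <- function(scores, outcome, outcome_name = "outcome",
                                   conf_level = 0.95) {
  cm <- if (inherits(scores, "child_scores")) scores$calls else as.matrix(scores)
  stopifnot(nrow(cm) == length(outcome))
  df <- data.frame(.y = outcome, cm, check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L) stop("outcome is constant")
  fit <- stats::lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  cgs <- colnames(cm)
  means <- colMeans(df[, cgs, drop = FALSE])
  base <- stats::coef(fit)[1L] + sum(stats::coef(fit)[cgs] * means)
  rows <- lapply(cgs, function(g) {
    b <- cf[g, "Estimate"]
    # marginal means: set this CG to 1 (or 0), others at observed means
    emm1 <- base + b * (1 - means[g])
    emm0 <- base - b * means[g]
    data.frame(outcome = outcome_name, cg = g,
               diff = b, ci_lo = ci[g, 1L], ci_hi = ci[g, 2L],
               p = cf[g, "Pr(>|t|)"],
               emm_sens = emm1, emm_nonsens = emm0, n = nrow(df),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Descriptive outcome prevalence by sensitization subgroup
#'
#' Tabulates disease prevalence within each CG-sensitized subgroup (a child
#' sensitized to two CGs appears in both) and within the nonsensitized
#' group (no CG call).
#'
#' @param scores A `child_scores` with binary calls.
#' @param outcomes data.frame of derived outcomes (needs the
#'   `current_*` columns of [derive_outcomes()]), rows aligned with the
#'   score rows.
#' @param outcome_cols Binary outcome columns to tabulate.
#' @return data.frame: one row per subgroup with `n`, per-outcome counts and
#'   percentages, and `pct_disease_free`.
#' @export
describe_by_group <- function(scores, outcomes,
                              outcome_cols = c("current_wheeze", "current_asthma",
                                               "current_hayfever", "current_eczema")) {
  calls <- scores$calls
  stopifnot(nrow(calls) == nrow(outcomes))
  outcome_cols <- intersect(outcome_cols, names(outcomes))
  groups <- c(stats::setNames(lapply(colnames(calls), function(g) calls[, g] == 1),
                              colnames(calls)),
              list(nonsensitized = rowSums(calls) == 0))
  rows <- lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    sub <- outcomes[idx, outcome_cols, drop = FALSE]
    n <- sum(idx)
    pct <- vapply(outcome_cols, function(cl) {
      100 * mean(sub[[cl]] == 1, na.rm = TRUE)
    }, 0)
    free <- rowSums(sub == 1, na.rm = TRUE) == 0
    out <- data.frame(group = nm, n = n, t(pct),
                      pct_disease_free = 100 * mean(free),
                      stringsAsFactors = FALSE, row.names = NULL)
    names(out)[3:(2 + length(outcome_cols))] <- paste0("pct_", outcome_cols)
    out
  })
  do.call(rbind, rows)
}
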