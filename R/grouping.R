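#' Assign components to component groups by thresholded membership
#'
#' A component is assigned to the cluster with its maximum posterior
#' membership probability when that probability exceeds
#' `membership_threshold` (strictly greater, per the study rule); otherwise
#' it is labelled `"non-CG"`.
#'
#' @param p A `posterior_summary`.
#' @param membership_threshold Assignment threshold (default 0.7).
#' @return data.frame with columns `component`, `cg` (e.g. "CG1" or
#'   "non-CG") and `max_membership`; the per-CG counts are attached as
#'   attribute `"counts"`.
#' @export
assign_components <- function(p, membership_threshold = 0.7) {
  m <- p$membership[, setdiff(colnames(p$membership), "noise"), drop = FALSE]
  k <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), k)]
  cg <- ifelse(mx > membership_threshold, colnames(m)[k], "non-CG")
  out <- data.frame(component = rownames(m), cg = cg, max_membership = mx,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- table(factor(cg, levels = c(colnames(m), "non-CG")))
  out
}

#' Score each child's sensitization to every component group
#'
#' Quantitative scores are the posterior sensitization probabilities; the
#' binary call uses `score >= sensitization_threshold` (the at-least
#' convention, configurable via `comparator`). Children not present in the
#' posterior (those excluded at filtering for having no positive results)
#' receive score 0 for every CG.
#'
#' @param p A `posterior_summary`.
#' @param assignment Output of [assign_components()]; CGs with no assigned
#'   components are dropped from the score table.
#' @param sensitization_threshold Call threshold (default 0.5).
#' @param all_subjects Optional character vector of the full cohort's subject
#'   IDs (in order); subjects absent from the posterior get score 0.
#' @param comparator `">="` (default) or `">"`.
#' @return List of class `"child_scores"` with `scores` and `calls`
#'   (subjects x CGs matrices) and the threshold used.
#' @export
score_children <- function(p, assignment = NULL, sensitization_threshold = 0.5,
                           all_subjects = NULL, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  sc <- p$sensitization
  keep <- colnames(sc)
  if (!is.null(assignment)) {
    nonempty <- unique(assignment$cg[assignment$cg != "non-CG"])
    keep <- intersect(colnames(sc), nonempty)
    if (!length(keep)) stop("no CG has any assigned component")
    sc <- sc[, keep, drop = FALSE]
  }
  if (!is.null(all_subjects)) {
    full <- matrix(0, length(all_subjects), ncol(sc),
                   dimnames = list(all_subjects, colnames(sc)))
    have <- intersect(all_subjects, rownames(sc))
    full[have, ] <- sc[have, ]
    sc <- full
  }
  calls <- if (comparator == ">=") sc >= sensitization_threshold else
    sc > sensitization_threshold
  structure(list(scores = sc, calls = calls * 1L,
                 threshold = sensitization_threshold, comparator = comparator),
            class = "child_scores")
}

#' Count children by number and combination of CG sensitizations
#'
#' @param scores A `child_scores` object (or a 0/1 calls matrix).
#' @return List with `by_count` (children sensitized to exactly 0..K CGs)
#'   and `by_pattern` (counts of each combination, labels like "CG1+CG3").
#' @export
combination_counts <- function(scores) {
  calls <- if (inherits(scores, "child_scores")) scores$calls else scores
  nk <- rowSums(calls)
  by_count <- table(factor(nk, levels = 0:ncol(calls)))
  names(by_count) <- paste0("exactly_", names(by_count))
  lab <- apply(calls, 1L, function(v) {
    if (!any(v == 1)) "none" else paste(colnames(calls)[v == 1], collapse = "+")
  })
  list(by_count = by_count, by_pattern = table(lab))
}

#' Cluster stability under subject resampling
#'
#' Repeats the whole analysis (subject subsample, component prevalence
#' filter, model fit, thresholded assignment) on random subject subsets and
#' summarizes how often each pair of components lands in the same CG.
#' Pairs are counted only over runs in which both components survived that
#' subset's filter; two components "co-assign" when they carry the same CG
#' label (non-CG never co-assigns).
#'
#' @param b A `binary_matrix` (pre-filter cohort, subjects x components).
#' @param config A `model_config`.
#' @param n_subsets Number of random subsets (default 20).
#' @param subset_size Subjects per subset, sampled without replacement
#'   (default 200).
#' @param seed Master seed.
#' @param min_positive Component filter within each subset (default 3).
#' @param membership_threshold Assignment threshold (default 0.7).
#' @param n_restarts Restarts per subset fit (default 5).
#' @return List of class `"stability_result"`: `similarity` (J x J, `NA`
#'   where a pair never co-occurred), `n_pair_runs`, `assignments`
#'   (components x runs), and settings.
#' @export
stability_analysis <- function(b, config, n_subsets = 20L, subset_size = 200L,
                               seed = 1L, min_positive = 3L,
                               membership_threshold = 0.7, n_restarts = 5L) {
  b <- as_binary_matrix(b)
  N <- nrow(b); J <- ncol(b)
  if (subset_size > N) stop("subset_size (", subset_size,
                            ") exceeds number of subjects (", N, ")")
  comp <- colnames(b)
  assigns <- matrix(NA_character_, J, n_subsets, dimnames = list(comp, NULL))
  co <- matrix(0, J, J, dimnames = list(comp, comp))
  both <- matrix(0, J, J, dimnames = list(comp, comp))
  for (t in seq_len(n_subsets)) {
    set.seed(derive_seed(seed, "stability-subset", t))
    rows <- sort(sample.int(N, subset_size))
    sub <- structure(unclass(b)[rows, , drop = FALSE], class = class(b))
    fc <- filter_components(sub, min_positive)
    fs <- filter_subjects(fc$matrix)
    ps <- fit_approximate(unclass(fs$matrix), config,
                          seed = derive_seed(seed, "stability-fit", t),
                          n_restarts = n_restarts)
    asg <- assign_components(ps, membership_threshold)
    assigns[asg$component, t] <- asg$cg
    present <- comp %in% asg$component
    lab <- assigns[, t]
    assigned <- !is.na(lab) & lab != "non-CG"
    same <- outer(lab, lab, `==`)
    same[is.na(same)] <- FALSE
    same <- same & outer(assigned, assigned, `&`)
    pp <- outer(present, present, `&`)
    both <- both + pp
    co <- co + (same & pp)
  }
  sim <- ifelse(both > 0, co / both, NA_real_)
  diag(sim)[diag(both) > 0] <- 1
  structure(list(similarity = sim, n_pair_runs = both, assignments = assigns,
                 n_subsets = n_subsets, subset_size = subset_size,
                 seed = seed, min_positive = min_positive,
                 membership_threshold = membership_threshold),
            class = "stability_result")
}

#' Deterministic row/column ordering for the sorted sensitization heatmap
#'
#' Components are grouped by CG (non-CG last) and sorted within group by
#' descending positive count; subjects are grouped by their CG-sensitization
#' combination (richer combinations first, patterns ordered as binary codes
#' descending) and sorted within group by descending total positives. Ties
#' fall back to the original order.
#'
#' @param b A `binary_matrix`.
#' @param assignment Output of [assign_components()].
#' @param scores A `child_scores` for the same subjects.
#' @return List with `component_order` and `subject_order` (character
#'   vectors of IDs).
#' @export
heatmap_order <- function(b, assignment, scores) {
  b <- as_binary_matrix(b)
  cg_levels <- c(sort(unique(assignment$cg[assignment$cg != "non-CG"])), "non-CG")
  pos <- colSums(unclass(b) == 1L, na.rm = TRUE)[assignment$component]
  comp_ord <- assignment$component[order(match(assignment$cg, cg_levels), -pos,
                                         seq_along(assignment$component))]
  calls <- scores$calls[rownames(b), , drop = FALSE]
  code <- as.vector(calls %*% (2^((ncol(calls) - 1):0)))
  tot <- rowSums(unclass(b) == 1L, na.rm = TRUE)
  subj_ord <- rownames(b)[order(-code, -tot, seq_len(nrow(b)))]
  list(component_order = comp_ord, subject_order = subj_ord)
}
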