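#' Run the full component-group analysis pipeline
#'
#' Orchestrates prepare (read, discretize, binarize, filter), fit, group,
#' optional stability, and associate, writing per-stage TSV outputs plus a
#' markdown/JSON report to `out_dir`. Every stage is logged with its
#' input/output row counts; all randomness flows from `seed` through named
#' substreams, so identical config and seed give identical outputs.
#'
#' @param isu_file ISU matrix (TSV/CSV, subjects x components).
#' @param outcomes_file Raw outcomes table keyed by subject.
#' @param catalog_file Optional component catalog.
#' @param out_dir Output directory.
#' @param config A `model_config`.
#' @param seed Master seed.
#' @param min_positive Component prevalence filter (default 3).
#' @param membership_threshold,sensitization_threshold Assignment and call
#'   thresholds (0.7 / 0.5).
#' @param stability `TRUE` to run the subsample stability analysis.
#' @param n_subsets,subset_size Stability settings (20 / 200; `subset_size`
#'   is capped at the post-filter subject count).
#' @param verbose Emit progress messages.
#' @return Invisible list with every stage result.
#' @export
run_pipeline <- function(isu_file, outcomes_file, catalog_file = NULL,
                         out_dir, config = model_config(), seed = 1L,
                         min_positive = 3L,
                         membership_threshold = 0.7,
                         sensitization_threshold = 0.5,
                         stability = FALSE, n_subsets = 20L, subset_size = 200L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  for (f in c(isu_file, outcomes_file, catalog_file)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- prepare ----------------------------------------------------------
  isu <- read_isu_matrix(isu_file)
  say("prepare: read %d subjects x %d components", nrow(isu), ncol(isu))
  bin <- binarize(discretize_isu(isu))
  fc <- filter_components(bin, min_positive)
  fs <- filter_subjects(fc$matrix)
  b <- fs$matrix
  say("prepare: %d components retained (%d excluded), %d subjects retained (%d excluded)",
      ncol(b), length(fc$excluded), nrow(b), length(fs$excluded))
  write_matrix_tsv(b, file.path(out_dir, "binary_filtered.tsv"))
  writeLines(fc$excluded, file.path(out_dir, "excluded_components.txt"))
  writeLines(fs$excluded, file.path(out_dir, "excluded_subjects.txt"))

  outcomes_raw <- read_outcomes(outcomes_file)
  if (!is.null(catalog_file)) {
    catalog <- read_component_catalog(catalog_file)
  } else catalog <- NULL
  outcomes <- derive_outcomes(outcomes_raw)
  outcomes <- outcomes[match(rownames(isu), outcomes$subject), , drop = FALSE]
  if (anyNA(outcomes$subject)) stop("association stage prerequisite: outcomes table is missing subjects present in the ISU matrix")
  utils::write.table(outcomes, file.path(out_dir, "outcomes_derived.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- fit --------------------------------------------------------------
  say("fit: variational inference, K=%d, %d restarts, seed %d",
      config$K, config$n_restarts, seed)
  ps <- fit_approximate(unclass(b), config, seed = derive_seed(seed, "fit"))
  write_posterior_summary(ps, out_dir)

  # --- group ------------------------------------------------------------
  asg <- assign_components(ps, membership_threshold)
  scores <- score_children(ps, asg, sensitization_threshold,
                           all_subjects = rownames(isu))
  combos <- combination_counts(scores)
  say("group: %s", paste(names(attr(asg, "counts")), attr(asg, "counts"),
                         sep = "=", collapse = ", "))
  utils::write.table(asg, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(scores$scores, file.path(out_dir, "child_scores.tsv"))
  write_matrix_tsv(scores$calls, file.path(out_dir, "child_calls.tsv"))

  ord <- heatmap_order(b, asg[asg$component %in% colnames(b), ], scores)
  writeLines(ord$component_order, file.path(out_dir, "heatmap_component_order.txt"))
  writeLines(ord$subject_order, file.path(out_dir, "heatmap_subject_order.txt"))

  stab <- NULL
  if (stability) {
    ss <- min(subset_size, nrow(b))
    say("stability: %d subsets of %d subjects", n_subsets, ss)
    stab <- stability_analysis(b, config, n_subsets = n_subsets,
                               subset_size = ss,
                               seed = derive_seed(seed, "stability"),
                               min_positive = min_positive,
                               membership_threshold = membership_threshold)
    write_matrix_tsv(stab$similarity, file.path(out_dir, "similarity.tsv"),
                     "component")
  }

  # --- associate --------------------------------------------------------
  stopifnot(identical(rownames(scores$scores), outcomes$subject))
  bin_out <- c("current_wheeze", "current_asthma", "current_hayfever",
               "current_eczema", "ahr")
  assoc <- do.call(rbind, lapply(intersect(bin_out, names(outcomes)), function(o) {
    fit_binary_outcome(scores, outcomes[[o]], outcome_name = o)
  }))
  cont_out <- c("fev1_pct_pred", "fev1_fvc", "eno_ppb", "drs")
  assoc_cont <- do.call(rbind, lapply(intersect(cont_out, names(outcomes)), function(o) {
    fit_continuous_outcome(scores, outcomes[[o]], outcome_name = o)
  }))
  descr <- describe_by_group(scores, outcomes)
  say("associate: %d binary and %d continuous outcome models",
      length(unique(assoc$outcome)), length(unique(assoc_cont$outcome)))
  utils::write.table(assoc, file.path(out_dir, "associations_binary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assoc_cont, file.path(out_dir, "associations_continuous.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(descr, file.path(out_dir, "described_by_group.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- pipeline_report(asg, catalog, combos, assoc, assoc_cont, stab, seed)
  writeLines(report$markdown, file.path(out_dir, "report.md"))
  jsonlite::write_json(report$json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(binary = b, excluded_components = fc$excluded,
                 excluded_subjects = fs$excluded, posterior = ps,
                 assignment = asg, scores = scores, combinations = combos,
                 stability = stab, associations_binary = assoc,
                 associations_continuous = assoc_cont, described = descr,
                 outcomes = outcomes, seed = seed))
}

pipeline_report <- function(asg, catalog, combos, assoc, assoc_cont, stab, seed) {
  counts <- attr(asg, "counts")
  md <- c("# Component group analysis report", "",
          sprintf("Master seed: %d", seed), "",
          "## Components per group", "",
          paste0("- ", names(counts), ": ", as.integer(counts)))
  if (!is.null(catalog)) {
    merged <- merge(asg, catalog, by = "component", all.x = TRUE)
    md <- c(md, "", "## Assigned components",
            "", "component\tcg\tpfam_family",
            sprintf("%s\t%s\t%s", merged$component, merged$cg,
                    merged$pfam_family %||% ""))
  }
  md <- c(md, "", "## Children per number of CG sensitizations", "",
          paste0("- ", names(combos$by_count), ": ",
                 as.integer(combos$by_count)),
          "", "## Associations (binary outcomes)", "",
          "outcome\tCG\tOR\t95% CI\tp",
          sprintf("%s\t%s\t%.2f\t(%.2f-%.2f)\t%.3g",
                  assoc$outcome, assoc$cg, assoc$or, assoc$ci_lo,
                  assoc$ci_hi, assoc$p),
          "", "## Associations (continuous outcomes)", "",
          "outcome\tCG\tdiff\t95% CI\tp",
          sprintf("%s\t%s\t%.2f\t(%.2f, %.2f)\t%.3g",
                  assoc_cont$outcome, assoc_cont$cg, assoc_cont$diff,
                  assoc_cont$ci_lo, assoc_cont$ci_hi, assoc_cont$p))
  if (!is.null(stab)) {
    offdiag <- stab$similarity[upper.tri(stab$similarity)]
    md <- c(md, "", "## Stability", "",
            sprintf("- subsets: %d of size %d", stab$n_subsets, stab$subset_size),
            sprintf("- mean pairwise co-assignment (defined pairs): %.3f",
                    mean(offdiag, na.rm = TRUE)))
  }
  json <- list(seed = seed,
               counts = as.list(stats::setNames(as.integer(counts), names(counts))),
               combinations = as.list(stats::setNames(
                 as.integer(combos$by_count), names(combos$by_count))),
               associations_binary = assoc,
               associations_continuous = assoc_cont)
  list(markdown = md, json = json)
}
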