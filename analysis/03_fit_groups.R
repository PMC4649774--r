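#!/usr/bin/env Rscript
# Fit the latent component-group model by variational Bayes, assign
# components to CGs at the 0.7 membership threshold, score every child's
# posterior sensitization to each CG and call sensitization at >= 0.5, and
# derive the sorted-heatmap ordering.

library(igegroup)

b_df <- read.delim("results/binary_filtered.tsv", check.names = FALSE)
b <- as.matrix(b_df[, -1]); rownames(b) <- b_df[[1]]
isu <- read_isu_matrix("results/cohort/isu.tsv")

ps <- fit_approximate(b, model_config(), seed = 1L)
cat(sprintf("variational fit: objective %.1f after %d iterations (converged: %s)\n",
            ps$elbo, ps$n_iter, ps$converged))

asg <- assign_components(ps, membership_threshold = 0.7)
cnt <- attr(asg, "counts")
cat(sprintf("components per group: %s\n",
            paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", ")))
cat(sprintf("memberships above 0.9 among assigned components: %d of %d\n",
            sum(asg$max_membership > 0.9 & asg$cg != "non-CG"),
            sum(asg$cg != "non-CG")))

scores <- score_children(ps, asg, sensitization_threshold = 0.5,
                         all_subjects = rownames(isu))
cc <- combination_counts(scores)
cat(sprintf("children sensitized to 0/1/2/3 CGs: %s\n",
            paste(as.integer(cc$by_count), collapse = "/")))

ord <- heatmap_order(binarize(discretize_isu(isu)),
                     asg, scores)

write_posterior_summary(ps, "results")
write.table(asg, "results/assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_matrix_tsv(scores$scores, "results/child_scores.tsv")
write_matrix_tsv(scores$calls, "results/child_calls.tsv")
writeLines(ord$component_order, "results/heatmap_component_order.txt")
writeLines(ord$subject_order, "results/heatmap_subject_order.txt")
cat("wrote membership/sensitization posteriors, assignments, scores, orderings\n")
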