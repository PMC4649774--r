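#!/usr/bin/env Rscript
# Robustness of the grouping under subject resampling: repeat the whole
# analysis (fresh component filter, fit, 0.7-threshold assignment) on 20
# random subsets of 200 children and summarize pairwise co-assignment.

library(igegroup)

b_df <- read.delim("results/binary_filtered.tsv", check.names = FALSE)
b <- as.matrix(b_df[, -1]); rownames(b) <- b_df[[1]]
b <- binarize(b)

st <- stability_analysis(b, model_config(), n_subsets = 20L,
                         subset_size = 200L, seed = 2L)

truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
lab <- truth$component_class[match(colnames(b), truth$component)]
sim <- st$similarity
same_cluster <- outer(lab, lab, `==`) & grepl("^cluster", lab)
off <- upper.tri(sim)
within <- mean(sim[off & same_cluster], na.rm = TRUE)
between <- mean(sim[off & !same_cluster & outer(grepl("^cluster", lab),
                                               grepl("^cluster", lab), `&`)],
                na.rm = TRUE)
cat(sprintf("20 subsets of %d children:\n", st$subset_size))
cat(sprintf("mean co-assignment within true clusters:  %.3f\n", within))
cat(sprintf("mean co-assignment between true clusters: %.3f\n", between))

write_matrix_tsv(st$similarity, "results/similarity.tsv", "component")
cat("wrote results/similarity.tsv\n")
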