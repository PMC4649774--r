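#!/usr/bin/env Rscript
# Prepare the modelling matrix: read raw ISU values, discretize on the
# manufacturer's 0.3/1/15 ISU scale, binarize at 0.3 ISU, then keep
# components recognized by >= 3 children and children with >= 1 positive.

library(igegroup)

isu <- read_isu_matrix("results/cohort/isu.tsv")
cat(sprintf("read %d x %d ISU matrix\n", nrow(isu), ncol(isu)))

b <- binarize(discretize_isu(isu))
fc <- filter_components(b, min_positive = 3L)
fs <- filter_subjects(fc$matrix)

cat(sprintf("components with >= 3 positive children: %d of %d (excluded: %s)\n",
            ncol(fc$matrix), ncol(b), paste(fc$excluded, collapse = ", ")))
cat(sprintf("children with any positive result: %d of %d\n",
            nrow(fs$matrix), nrow(b)))

write_matrix_tsv(fs$matrix, "results/binary_filtered.tsv")
writeLines(fc$excluded, "results/excluded_components.txt")
writeLines(fs$excluded, "results/excluded_subjects.txt")
cat("wrote results/binary_filtered.tsv and exclusion lists\n")
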