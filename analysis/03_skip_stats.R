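#!/usr/bin/env Rscript
# Compare per-junction exon-skipping fractions between the native human RPE
# and 4-month ARPE-19 libraries (transcribed junction counts shipped with the
# package) with the two-sided Fisher exact test, and render the
# publication-style table.

suppressMessages(library(sisplice))

human <- rpe65_skip_counts("Human RPE")
arpe <- rpe65_skip_counts("ARPE-19 (4 months)")

cmp <- compare_libraries(human, arpe)
write.table(cmp, "results/skip_comparison.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

tab <- render_skip_table(cmp, labels = c("Human RPE", "ARPE-19 (4 months)"))
write.table(tab, "results/skip_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sig <- cmp$upstream_exon[cmp$p_two_sided < 0.05]
cat("Junctions with significantly different skipping (p < 0.05): exons",
    paste(sig + 1, collapse = ", "), "are skipped more in culture.\n")
print(tab, row.names = FALSE)
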