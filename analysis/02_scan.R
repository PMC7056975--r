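#!/usr/bin/env Rscript
# Stage 2: divergence-interval scan.
#
# Thresholds follow the published procedure: qualifying variants have
# |delta p| > 0.8, and interruptions of fewer than three variants, each
# with |delta p| > 0.5, are merged into their flanking intervals.

library(pleioscan)

variants <- read_variants("results/data/variants.tsv")
annotations <- read_annotations("results/data/annotations.tsv")

intervals <- scan_intervals(variants, scan_params())
intervals <- assign_genes(intervals, annotations,
                          known_arms = unique(variants$arm))
write.table(intervals, "results/intervals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_intervals_bed(intervals, "results/intervals.bed")

per_arm <- aggregate(cbind(n = rep(1, nrow(intervals)),
                           bp = intervals$span_bp) ~ intervals$arm, FUN = sum)
names(per_arm) <- c("arm", "n_intervals", "bp_covered")
print(per_arm)
message(sprintf("%d intervals covering %.2f Mb; %d genes fall inside them",
                nrow(intervals), sum(intervals$span_bp) / 1e6,
                length(interval_gene_ids(intervals))))

rec <- sweep_recovery(variants, intervals)
message(sprintf("planted-sweep recovery: %d/%d within 2 variants of the true boundaries",
                sum(rec$recovered), nrow(rec)))
write.csv(rec, "results/sweep_recovery.csv", row.names = FALSE)
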