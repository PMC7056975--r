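#!/usr/bin/env Rscript
# Stage 3: candidate-gene selection.
#
# A gene is carried into the screen when (a) it lies in a divergence
# interval and its best per-variant divergence P-value is < 1e-5, or it
# lies outside the intervals but is nominally significant (P < 1e-3); and
# (b) it is expressed in ovary and accessory gland; and (c) an RNAi stock
# without off-target effects is available. Rejections carry audit flags.

library(pleioscan)

annotations <- read_annotations("results/data/annotations.tsv")
intervals <- read.delim("results/intervals.tsv")

candidates <- select_candidates(annotations, intervals)
write.table(candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d of %d genes selected (%d via the interval route, %d via nominal P)",
                sum(candidates$selected), nrow(candidates),
                sum(candidates$route == "interval", na.rm = TRUE),
                sum(candidates$route == "nominal", na.rm = TRUE)))
print(table(rejected_because = candidates$audit[!candidates$selected]))
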