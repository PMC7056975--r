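#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the design: 5 selected (O) vs 5 control (B) replicate lines,
# 10,000 variants over five chromosome arms with fifteen planted sweeps
# (target divergence 0.90-0.95), a synthetic gene-annotation table, the
# 12-gene RNAi screen panel (48 lifespan vials/genotype, 13 productivity
# vials, 2x3 qPCR replicates) and the reciprocal O/B productivity assay.

library(pleioscan)

seed <- 1701
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

arms <- data.frame(arm = c("X", "2L", "2R", "3L", "3R"),
                   length_bp = rep(2e7, 5), n_variants = rep(2000, 5))
sweeps <- do.call(rbind, lapply(seq_len(5), function(i) {
  data.frame(arm = arms$arm[i],
             start = c(2e6, 8e6, 14e6), end = c(3e6, 9e6, 15e6),
             divergence = c(0.9, 0.92, 0.95))
}))
cfg <- sim_config(seed = seed, arms = arms, sweeps = sweeps, coverage = 50)
print(cfg)

variants <- simulate_frequencies(cfg)
annotations <- simulate_annotations(cfg, variants)
write_variants(variants, file.path(out, "variants.tsv"))
write_annotations(annotations, file.path(out, "annotations.tsv"))
message(sprintf("wrote %d variants (%d inside planted sweeps), %d genes",
                nrow(variants), sum(!is.na(variants$sweep)),
                nrow(annotations)))

screen <- simulate_screen(cfg)
write_phenotypes(screen$lifespan, file.path(out, "lifespan.csv"), "lifespan")
write_phenotypes(screen$productivity, file.path(out, "productivity.csv"),
                 "productivity")
write_phenotypes(screen$qpcr, file.path(out, "qpcr.csv"), "qpcr")
message(sprintf("screen: %d lifespan flies, %d vial-weeks of productivity, %d qPCR wells",
                nrow(screen$lifespan), nrow(screen$productivity),
                nrow(screen$qpcr)))

ob <- simulate_ob_productivity(cfg)
write_phenotypes(ob, file.path(out, "ob_productivity.csv"), "productivity")
message("wrote the reciprocal O/B cross productivity assay (maternal late-week effect planted)")
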