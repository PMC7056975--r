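#!/usr/bin/env Rscript
# Stage 4: effect calling on the RNAi screen and the O/B assay.
#
# Lifespan: mixed ANOVA with random vials nested in genotype, then per-sex
# reduced models. Productivity: lifetime sums per vial and per-week
# one-way models. qPCR: log2 normalized expression with biological
# replicate as the random stratum. The O/B assay partitions weekly
# productivity into maternal and paternal regime effects with Tukey
# letters per week.

library(pleioscan)

screen <- list(
  lifespan = read_phenotypes("results/data/lifespan.csv", "lifespan"),
  productivity = read_phenotypes("results/data/productivity.csv", "productivity"),
  qpcr = read_phenotypes("results/data/qpcr.csv", "qpcr")
)
calls <- call_screen_effects(screen)
write.csv(calls, "results/effect_calls.csv", row.names = FALSE)
print(summarize_calls(calls))

ob <- read_phenotypes("results/data/ob_productivity.csv", "productivity")
res <- analyze_ob_productivity(ob)
message("O/B full-model ANOVA:")
print(res$full)
for (w in names(res$weekly)) {
  message("week ", w, " Tukey letters over the four crosses:")
  print(res$weekly[[w]]$tukey$letters)
}
sink("results/ob_anova.txt")
print(res$full)
for (w in names(res$weekly)) print(res$weekly[[w]]$tukey)
sink()
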