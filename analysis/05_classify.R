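#!/usr/bin/env Rscript
# Stage 5: antagonistic-pleiotropy classification.
#
# Each gene's lifespan and productivity calls are mapped onto the
# pleiotropy taxonomy: antagonism between the sexes, between early and
# late reproduction, and between lifespan and reproduction.

library(pleioscan)

calls <- read.csv("results/effect_calls.csv")
profiles <- classify_screen(calls)
write.csv(profiles, "results/profiles.csv", row.names = FALSE)

print(profiles[, c("gene", "lifespan_pattern", "productivity_pattern",
                   "category", "antagonism_axes")])
message("category tallies:")
print(tally_categories(profiles))
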