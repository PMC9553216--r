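#!/usr/bin/env Rscript
# Enumerate the experimental design: 6 crop species in 4 phylogenetic
# groups; singles, monocultures, all between-group 2-species mixtures and
# all one-per-group 4-species mixtures, crossed with 2 fertilization levels,
# 3 coexistence-history seed sources and the stated replication.

library(coexhist)

dir.create("results", showWarnings = FALSE)

comps <- enumerate_compositions()
design <- build_design(comps, seed = 1)

cat("Compositions:\n")
print(table(comps$kind, comps$richness))
cat("\nPlots:", nrow(design),
    "| community:", sum(design$kind != "single"),
    "| mixtures:", sum(design$kind == "mixture"),
    "| singles:", sum(design$kind == "single"), "\n")
cat("History classes among community plots:\n")
print(table(design$history_class[design$kind != "single"]))

write.csv(comps, "results/compositions.csv", row.names = FALSE)
write.csv(design, "results/design.csv", row.names = FALSE)
cat("\nWrote results/compositions.csv and results/design.csv\n")
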