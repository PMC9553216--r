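#!/usr/bin/env Rscript
# Trait structure: SLA and LDMC derived from raw leaf measurements,
# species-level means and CVs, community-weighted means (biomass weights),
# community-level CVs, and convex-hull functional richness in standardized
# trait space.

library(coexhist)

bundle <- read_bundle("results/dataset")
trs <- trait_summaries(bundle)

pt <- merge(trs$plot_traits, bundle$design, by = "plot_id")
by_hist <- function(col)
  round(tapply(pt[[col]], pt$history_class, mean, na.rm = TRUE), 4)
cat("Community trait responses to coexistence history (same vs different):\n")
for (col in c("cwm_height_cm", "cwm_ldmc_g_g", "cv_height_cm", "cv_ldmc_g_g",
              "cv_seed_mass_g", "fric")) {
  v <- by_hist(col)
  cat(sprintf("  %-16s same %8.4f  different %8.4f  (%+.1f%%)\n", col,
              v["same"], v["different"],
              100 * (v["same"] - v["different"]) / abs(v["different"])))
}

write.csv(trs$species_traits, "results/species_traits.csv", row.names = FALSE)
write.csv(trs$plot_traits, "results/plot_traits.csv", row.names = FALSE)
cat("\nWrote results/{species_traits,plot_traits}.csv\n")
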