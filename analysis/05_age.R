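#!/usr/bin/env Rscript
# Stage 5: age correlations with oldest-specimen sensitivity.
#
# Pearson correlations of donor age with each mRNA metric, across all
# specimens and by neurotype, re-run after excluding the one and two oldest
# donors to check whether any age association rests on a single old specimen.

library(fishcoloc)

specimens <- read.csv("results/specimen_metrics.csv")
cohort <- read.csv("results/data/cohort.csv")
wide <- merge_specimen_table(specimens, cohort)

sens <- drop_oldest_sensitivity(wide, k_list = c(1L, 2L))
write.csv(sens, "results/age_correlations.csv", row.names = FALSE)

base <- sens[sens$k_excluded == 0 & sens$stratum == "all", ]
cat("age correlations (all specimens, no exclusion):\n")
print(base[, c("metric", "r", "p", "n", "verdict")], row.names = FALSE)

cat("\nverdict transitions under oldest-k exclusion:\n")
tr <- reshape(sens[sens$stratum == "all",
                   c("metric", "k_excluded", "verdict")],
              idvar = "metric", timevar = "k_excluded", direction = "wide")
print(tr, row.names = FALSE)
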