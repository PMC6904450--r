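#!/usr/bin/env Rscript
# Generate the three synthetic survey datasets the workflow analyses:
# an upper-ocean-like survey (many samples, double power-law community,
# ~1e6 total reads), a deep-ocean-like survey (few samples, shifted
# power-law community) and a 20-day mesocosm time series. Ground truth is
# written alongside each table.

suppressPackageStartupMessages(library(sadscaling))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 42

message("upper-ocean-like survey: 50 samples x 20,000 reads, double power law")
upper <- synth_survey(double_power_law(0.36, 1.54, 2313),
                      n_samples = 50, reads_per_sample = 2e4,
                      seed = seed, target_reads = 2e6)
write_otu_table(upper$table, "results/data/upper_survey.tsv")
writeLines(as.character(jsonlite::toJSON(upper$truth[c("model", "S_true", "seed")],
                                         auto_unbox = TRUE)),
           "results/data/upper_survey.truth.json")
message("  ", nrow(upper$table), " OTUs observed of ", upper$truth$S_true,
        " in the latent community")

message("deep-ocean-like survey: 10 samples x 50,000 reads, shifted power law")
deep <- synth_survey(shifted_power_law(0.89, 20.34, 1e6),
                     n_samples = 10, reads_per_sample = 5e4,
                     seed = seed + 1, target_reads = 2e6)
write_otu_table(deep$table, "results/data/deep_survey.tsv")
writeLines(as.character(jsonlite::toJSON(deep$truth[c("model", "S_true", "seed")],
                                         auto_unbox = TRUE)),
           "results/data/deep_survey.truth.json")
message("  ", nrow(deep$table), " OTUs observed of ", deep$truth$S_true)

message("mesocosm: 20 daily samples around 10,000 reads/day, alpha = 0.53")
meso <- synth_mesocosm(days = 20, mean_depth = 1e4, seed = seed + 2)
write_otu_table(meso$table, "results/data/mesocosm.tsv")
writeLines(as.character(jsonlite::toJSON(meso$truth[c("model", "S_true", "seed")],
                                         auto_unbox = TRUE)),
           "results/data/mesocosm.truth.json")
message("  day-1 reads: ", sum(meso$table[, 1]),
        "; 20-day aggregate: ", sum(meso$table))
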