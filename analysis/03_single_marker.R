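#!/usr/bin/env Rscript
# Single-marker LD-decay age estimates on the simulated dataset, with
# the simulation-calibrated growth correction at r = 1.5.
# Writes results/single_marker.tsv.

library(founderage)

loaded <- read_dataset("results/sim_dataset")
dataset <- loaded$dataset
map <- dataset$map
dists <- carrier_distributions_from_phased(dataset$case_haps)
freqs <- allele_frequencies(dataset$control_haps, map, dists)
anc <- infer_ancestral_haplotype(dists, map, freqs)

tab <- single_marker_ages(freqs, anc, map, r = 1.5,
                          correction = "montecarlo",
                          n_sims = 1000, seed = 101)
write.table(tab, "results/single_marker.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- summarize_markers(tab)

cat("Per-marker estimates written for", nrow(tab), "markers;",
    s$n_excluded, "excluded (undefined excess or < 0.1 cM from the",
    "locus).\n")
cat(sprintf("Median raw estimate: %.2f generations; median corrected (r = 1.5): %.2f\n",
            s$median_raw, s$median_corrected))
cat("Truth is 17 generations; single-marker medians on SNP panels are",
    "coarse because markers whose ancestral allele is still fixed among",
    "carriers contribute an estimate of 0.\n")
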