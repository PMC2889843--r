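#!/usr/bin/env Rscript
# Growth-rate arithmetic for the Ashkenazi census history, and the
# generation/year conversions used when interpreting age estimates.
# Writes results/demography.tsv.

library(founderage)
dir.create("results", showWarnings = FALSE)

census <- data.frame(
  label = c("fast_1765_1900", "slow_600_1900", "mid_1100_1900"),
  p0 = c(560000, 11000, 11000),
  p1 = c(5e6, 5e6, 5e6),
  year0 = c(1765, 600, 1100),
  year1 = c(1900, 1900, 1900)
)
census$generations <- NA_real_
census$r <- NA_real_
for (i in seq_len(nrow(census))) {
  gr <- growth_rate(census$p0[i], census$p1[i], census$year0[i],
                    census$year1[i])
  census$generations[i] <- gr$generations
  census$r[i] <- gr$r
}
write.table(census, "results/demography.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Per-generation fold growth rates from census pairs:\n")
print(census[, c("label", "generations", "r")], digits = 4)
cat("\nA 17-generation-old mutation at 25 years/generation arose",
    generations_to_years(17)$years, "years before present, i.e. around",
    generations_to_years(17, reference_year = 2000)$origin_year, "CE.\n")
cat("The fast (post-1765) rate is ~1.5-fold per generation; the rates",
    "assuming growth started in 600 or 1100 CE are ~1.125 and ~1.21.\n")
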