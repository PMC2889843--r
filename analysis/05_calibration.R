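#!/usr/bin/env Rscript
# Calibration studies for the estimators on data with known truth:
#  (a) Galton-Watson sanity: unconditioned mean copy count vs r^g and
#      the extinction frequency vs the analytic fixed point;
#  (b) star-genealogy calibration of the single-marker estimator;
#  (c) branching-genealogy behaviour of the multi-marker likelihood:
#      median estimate and interval coverage.
# Writes results/calibration.tsv.

library(founderage)
dir.create("results", showWarnings = FALSE)
rows <- list()

## (a) Galton-Watson sanity ---------------------------------------------
set.seed(606)
finals <- vapply(seq_len(10000), function(i) {
  tail(simulate_growth_lineages(20, 1.5, condition_on_survival = FALSE,
                                mode = "counts")$trajectory, 1)
}, numeric(1))
rows$gw <- data.frame(study = "galton_watson", quantity = "mean_final_count",
                      observed = mean(finals), expected = 1.5^20, n = 10000)
rows$ext <- data.frame(study = "galton_watson", quantity = "extinction_freq",
                       observed = mean(finals == 0),
                       expected = gw_extinction_prob(1.5), n = 10000)
cat(sprintf("Mean copy count after 20 generations at r = 1.5: %.0f (r^g = %.0f); extinction %.3f (fixed point %.3f)\n",
            mean(finals), 1.5^20, mean(finals == 0),
            gw_extinction_prob(1.5)))

## (b) star-genealogy single-marker calibration -------------------------
map_s <- one_theta <- build_marker_map(
  data.frame(name = "m1", position_bp = 3e6, type = "snp",
             alleles = I(list(c("1", "2"))), mutation_rate = 0),
  disease_locus_bp = 1e6)
map_s$table$theta_locus <- 0.02
map_s$table$theta_interval <- 0.02
est <- numeric(100)
for (k in 1:100) {
  set.seed(700 + k)
  pool <- list(haps = matrix(sample(c(rep("1", 80), rep("2", 120))),
                             ncol = 1, dimnames = list(NULL, "m1")),
               freqs = rep(1 / 200, 200))
  cfg <- sim_config(30, 1.5, 2000, 500, map_s, pool, genealogy = "star",
                    seed = 700 + k)
  sim <- simulate_dataset(cfg)
  dists <- carrier_distributions_from_phased(sim$dataset$case_haps)
  fr <- allele_frequencies(sim$dataset$control_haps, map_s, dists)
  anc <- infer_ancestral_haplotype(dists, map_s, fr)
  est[k] <- single_marker_ages(fr, anc, map_s)$g_raw[1]
}
rows$star <- data.frame(study = "star_single_marker",
                        quantity = "median_age", observed = median(est),
                        expected = 30, n = 100)
cat(sprintf("Star-genealogy single-marker median over 100 replicates: %.2f (truth 30)\n",
            median(est)))

## (c) branching-genealogy likelihood recovery --------------------------
mk <- data.frame(name = sprintf("m%02d", 1:19),
                 position_bp = round(seq(0, 12.3e6, length.out = 19)),
                 type = "snp",
                 alleles = I(replicate(19, c("1", "2"), simplify = FALSE)))
map <- build_marker_map(mk, disease_locus_bp = round(12.3e6 / 2) + 1)
ghat <- numeric(100); cover <- 0L
for (k in 1:100) {
  set.seed(9000 + k)
  pool <- make_background_pool(map, 200)
  cfg <- sim_config(17, 1.5, 16, 109, map, pool, genealogy = "branching",
                    condition = "n_cases", seed = 9000 + k)
  sim <- simulate_dataset(cfg)
  dists <- carrier_distributions_from_phased(sim$dataset$case_haps)
  fr <- allele_frequencies(sim$dataset$control_haps, map, dists)
  anc <- infer_ancestral_haplotype(dists, map, fr)
  mod <- goldgar_model(map, anc, fr)
  fit <- suppressWarnings(mle_age(dists, mod, 0, 100))
  ghat[k] <- fit$g_hat
  if (fit$ci_low <= 17 && 17 <= fit$ci_high) cover <- cover + 1L
}
rows$gg_med <- data.frame(study = "branching_goldgar",
                          quantity = "median_ghat",
                          observed = median(ghat), expected = 17, n = 100)
rows$gg_cov <- data.frame(study = "branching_goldgar",
                          quantity = "ci_coverage",
                          observed = cover / 100, expected = 0.95, n = 100)
cat(sprintf("Branching-genealogy likelihood: median estimate %.1f (truth 17), 95%% CI coverage %d/100\n",
            median(ghat), cover))
cat("Coverage falls short of nominal under the branching genealogy:",
    "carriers share ancestry, which the independent-carrier likelihood",
    "does not model. Under the star genealogy the same intervals are",
    "close to nominal (see the package tests).\n")

out <- do.call(rbind, rows)
rownames(out) <- NULL
write.table(out, "results/calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
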