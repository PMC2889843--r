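# fixtures local to the likelihood tests: model with exactly set
# frequencies and thetas
two_marker_model <- function(theta1 = 0.01, theta12 = 0.01, p1 = 0.7,
                             p2 = 0.7, mu = 0, pi_recurrence = 0) {
  # two markers on the distal side; theta values set directly
  mk <- data.frame(name = c("m1", "m2"), position_bp = c(2e6, 3e6),
                   type = "snp", alleles = I(list(c("1", "2"), c("1", "2"))))
  map <- build_marker_map(mk, disease_locus_bp = 1e6)
  map$table$theta_interval <- c(theta1, theta12)
  map$table$mutation_rate[] <- mu
  fr <- exact_freqs(map, c(p1, p2))
  anc <- as_ancestral(c("1", "1"), map)
  goldgar_model(map, anc, fr, pi_recurrence = pi_recurrence)
}

test_that("age zero: exact match is certain, any mismatch impossible", {
  mod <- two_marker_model()
  expect_equal(haplotype_loglik(c("1", "1"), 0, mod), 0)
  expect_equal(haplotype_loglik(c("1", "2"), 0, mod), -Inf)
  expect_equal(haplotype_loglik(c("2", "2"), 0, mod), -Inf)
  expect_error(haplotype_loglik(c("1", "1"), -1, mod), "non-negative")
})

test_that("two-marker scan equals the hand-derived decomposition", {
  # match at m1, mismatch at m2 whose allele has background frequency 0.3:
  # either the segment survived the locus flank and broke in the
  # m1-m2 interval (emit mismatch at background), or it broke in the
  # flank (both markers at background)
  mod <- two_marker_model(p1 = 0.7, p2 = 0.7)  # mismatch allele "2": 0.3
  g <- 5
  q <- 0.99^g
  manual <- q * (1 - q) * 0.3 + (1 - q) * 0.7 * 0.3 + q * q * 0
  expect_equal(exp(haplotype_loglik(c("1", "2"), g, mod)), manual,
               tolerance = 1e-12)
})

test_that("one-marker closed-form reduction holds to 1e-12", {
  map <- one_marker_map(0.01)
  fr <- exact_freqs(map, 0.1)
  mod <- goldgar_model(map, as_ancestral("1", map), fr)
  p <- exp(haplotype_loglik("1", 10, mod))
  closed <- 0.99^10 + (1 - 0.99^10) * 0.1
  expect_equal(p, closed, tolerance = 1e-12)
  expect_equal(p, 0.91394, tolerance = 1e-5)
  # mismatch: complementary path
  p2 <- exp(haplotype_loglik("2", 10, mod))
  expect_equal(p2, (1 - 0.99^10) * 0.9, tolerance = 1e-12)
  expect_equal(p + p2, 1, tolerance = 1e-12)
})

test_that("intact-state emissions sum to one at every marker and age", {
  mk <- data.frame(
    name = c("s1", "str1", "str2"),
    position_bp = c(2e6, 3e6, 4e6),
    type = c("snp", "dinucleotide_str", "tetranucleotide_str"),
    alleles = I(list(c("1", "2"), c("10", "12", "14", "16"), c("8", "12"))),
    mutation_rate = c(1e-4, 5e-4, 2e-4)
  )
  map <- build_marker_map(mk, disease_locus_bp = 1e6)
  for (g in c(1, 10, 100)) {
    for (j in 1:3) {
      alleles <- map$alleles[[j]]
      for (anc in alleles) {
        tot <- sum(vapply(alleles, function(obs) {
          founderage:::.intact_emission(obs, anc, mk$mutation_rate[j], g,
                                        alleles, mk$type[j])
        }, numeric(1)))
        expect_equal(tot, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("all-ancestral likelihood is non-increasing in age when mu = 0", {
  mod <- two_marker_model()
  ll <- haplotype_loglik(c("1", "1"), 0:60, mod)
  expect_true(all(diff(ll) <= 1e-12))
})

test_that("scan equals exhaustive event-placement enumeration", {
  set.seed(42)
  # three-marker map, mixed sides and types, random frequencies
  mk <- data.frame(
    name = c("a", "b", "c"),
    position_bp = c(5e5, 2.2e6, 3.4e6),
    type = c("snp", "dinucleotide_str", "snp"),
    alleles = I(list(c("1", "2"), c("10", "12", "14"), c("1", "2"))),
    mutation_rate = c(1e-3, 5e-3, 2e-3)   # inflated so mutation paths count
  )
  map <- build_marker_map(mk, disease_locus_bp = 1.5e6)
  p_N <- list(a = c("1" = 0.6, "2" = 0.4),
              b = c("10" = 0.3, "12" = 0.5, "14" = 0.2),
              c = c("1" = 0.25, "2" = 0.75))
  fr <- structure(list(p_N = p_N, p_D = NULL), class = "allele_frequencies")
  anc <- as_ancestral(c("1", "12", "2"), map)
  mod <- goldgar_model(map, anc, fr, pi_recurrence = 0.05)
  haps <- list(c("1", "12", "2"), c("2", "12", "2"), c("1", "10", "1"),
               c("2", "14", "1"), c("1", "14", "2"))
  for (g in c(0, 1, 3, 5)) {
    for (h in haps) {
      s <- haplotype_loglik(h, g, mod)
      o <- goldgar_enumerate_loglik(h, g, mod)
      expect_equal(exp(s), exp(o), tolerance = 1e-10)
    }
  }
})

test_that("dataset likelihood: additivity and haplotype mixtures", {
  mod <- two_marker_model()
  mk_d <- function(haps, probs) {
    d <- data.frame(haplotype = haps, probability = probs)
    class(d) <- c("hap_distribution", "data.frame")
    d
  }
  one <- list(mk_d("1,1", 1))
  expect_equal(dataset_loglik(one, 7, mod),
               haplotype_loglik(c("1", "1"), 7, mod))
  two <- list(mk_d("1,1", 1), mk_d("1,1", 1))
  expect_equal(dataset_loglik(two, 7, mod),
               2 * haplotype_loglik(c("1", "1"), 7, mod))
  mix <- list(mk_d(c("1,1", "1,2"), c(0.5, 0.5)))
  expect_equal(dataset_loglik(mix, 7, mod),
               log(0.5 * exp(haplotype_loglik(c("1", "1"), 7, mod)) +
                     0.5 * exp(haplotype_loglik(c("1", "2"), 7, mod))))
})

test_that("recurrence prior rescues otherwise impossible haplotypes", {
  mod0 <- two_marker_model(pi_recurrence = 0)
  modp <- two_marker_model(pi_recurrence = 0.01)
  expect_equal(haplotype_loglik(c("2", "2"), 0, mod0), -Inf)
  # at g = 0 the descent likelihood is 0; only the recurrence path remains
  expect_equal(exp(haplotype_loglik(c("2", "2"), 0, modp)),
               0.01 * 0.3 * 0.3, tolerance = 1e-12)
})

test_that("unknown alleles are rejected", {
  mod <- two_marker_model()
  expect_error(haplotype_loglik(c("1", "X"), 5, mod), "absent")
})

test_that("grid MLE: degenerate grids, no-decay data, CI definition", {
  mod <- two_marker_model()
  mk_d <- function(haps, probs) {
    d <- data.frame(haplotype = haps, probability = probs)
    class(d) <- c("hap_distribution", "data.frame")
    d
  }
  all_anc <- replicate(10, mk_d("1,1", 1), simplify = FALSE)
  est <- suppressWarnings(mle_age(all_anc, mod, 0, 50))
  expect_equal(est$g_hat, 0)   # no decay observed: youngest age wins

  est1 <- suppressWarnings(mle_age(all_anc, mod, 5, 5))
  expect_equal(est1$g_hat, 5)
  expect_equal(c(est1$ci_low, est1$ci_high), c(5, 5))

  # CI is exactly the grid set within the cutoff of the maximum; data
  # with a few outer-marker recombinants give an interior maximum
  mod2 <- two_marker_model(theta1 = 0.01, theta12 = 0.05)
  some_rec <- c(replicate(9, mk_d("1,1", 1), simplify = FALSE),
                replicate(3, mk_d("1,2", 1), simplify = FALSE))
  est2 <- mle_age(some_rec, mod2, 0, 200)
  expect_false(est2$boundary_high)
  ll <- est2$curve$loglik
  in_ci <- est2$curve$g[max(ll) - ll <= est2$ci_cutoff]
  expect_equal(est2$ci_low, min(in_ci))
  expect_equal(est2$ci_high, max(in_ci))
  expect_true(est2$ci_low <= est2$g_hat && est2$g_hat <= est2$ci_high)
})

test_that("growth correction shifts the estimate and both bounds", {
  mod <- two_marker_model()
  mk_d <- function(h) {
    d <- data.frame(haplotype = h, probability = 1)
    class(d) <- c("hap_distribution", "data.frame")
    d
  }
  dists <- c(replicate(9, mk_d("1,1"), simplify = FALSE),
             replicate(3, mk_d("1,2"), simplify = FALSE))
  est <- mle_age(dists, two_marker_model(theta1 = 0.01, theta12 = 0.05),
                 0, 200)
  corr <- corrected_age(est, 24.31)
  expect_equal(corr$g_corrected, est$g_hat + 24.31)
  expect_equal(corr$ci_low_corrected, est$ci_low + 24.31)
  expect_equal(corr$ci_high_corrected, est$ci_high + 24.31)
  expect_equal(corr$boundary_low, est$boundary_low)
  ident <- corrected_age(est, 0)
  expect_equal(ident$g_corrected, est$g_hat)
  # published convention: 9 + 24.31 = 33.31, 17 + 24.31 = 41.31
  expect_equal(9 + 24.31, 33.31)
  expect_equal(17 + 24.31, 41.31)
})

test_that("MLE recovers the age of a star-genealogy simulation", {
  set.seed(314)
  map <- make_snp_map(9, span_mb = 10)
  pool <- fixed_freq_pool(map, 0.4)
  cfg <- sim_config(20, 1.5, 50, 200, map, pool, genealogy = "star",
                    seed = 271)
  res <- simulate_dataset(cfg)
  dists <- carrier_distributions_from_phased(res$dataset$case_haps)
  fr <- allele_frequencies(res$dataset$control_haps, map, dists)
  anc <- infer_ancestral_haplotype(dists, map, fr)
  mod <- goldgar_model(map, anc, fr)
  est <- mle_age(dists, mod, 0, 150)
  expect_true(est$ci_low <= 20 && 20 <= est$ci_high)
  expect_true(est$ci_low <= est$g_hat && est$g_hat <= est$ci_high)
})
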