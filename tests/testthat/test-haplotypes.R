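test_that("fully homozygous individuals phase trivially", {
  g <- matrix(c("A/A", "B/B"), 1, 2)
  em <- em_haplotype_frequencies(g)
  expect_equal(nrow(em$phase[[1]]), 1)
  expect_equal(em$phase[[1]]$probability, 1)
  expect_equal(em$phase[[1]]$hap1, "A,B")
})

test_that("a lone double heterozygote is phased 50/50 by symmetry", {
  g <- matrix(c("A/a", "B/b"), 1, 2)
  em <- em_haplotype_frequencies(g)
  expect_equal(sort(em$phase[[1]]$probability), c(0.5, 0.5))
})

test_that("EM phasing matches a direct likelihood maximisation", {
  # one double heterozygote plus two A,B homozygotes: the A,B|a,b phasing
  # should win, and the EM solution should attain the same maximum
  # likelihood as a direct search over the haplotype-frequency simplex
  g <- matrix(c("A/a", "A/A", "A/A",
                "B/b", "B/B", "B/B"), 3, 2)
  em <- em_haplotype_frequencies(g, tol = 1e-12)
  ph <- em$phase[[1]]
  p_cis <- ph$probability[ph$hap1 == "A,B" | ph$hap2 == "A,B"]
  expect_gt(p_cis, 0.5)

  # independent oracle: the likelihood (2 f_AB f_ab + 2 f_Ab f_aB) f_AB^4
  # is maximised on the boundary f_Ab = f_aB = 0 (moving trans mass to the
  # cis pair never lowers any factor), so it reduces to 2 f_AB^5 f_ab with
  # f_AB + f_ab = 1, maximised at f_AB = 5/6. A grid scan over the simplex
  # confirms this is the global maximum.
  loglik_of <- function(f) log(2 * f[1] * f[4] + 2 * f[2] * f[3]) +
    4 * log(f[1])
  grid <- seq(0.002, 0.998, by = 0.018)
  best <- -Inf
  for (f1 in grid) for (f2 in grid) for (f4 in grid) {
    if (f1 + f2 + f4 < 1) {
      v <- loglik_of(c(f1, f2, 1 - f1 - f2 - f4, f4))
      if (v > best) best <- v
    }
  }
  analytic <- log(2 * (5 / 6)^5 * (1 / 6))
  expect_lte(best, analytic + 1e-9)
  expect_equal(tail(em$loglik, 1), analytic, tolerance = 1e-6)
  expect_gt(p_cis, 0.99)
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(19)
  map <- make_snp_map(6, span_mb = 5)
  pool <- fixed_freq_pool(map, c(0.3, 0.5, 0.2, 0.7, 0.4, 0.6))
  cfg <- sim_config(8, 1.5, 10, 40, map, pool, genealogy = "star",
                    emit_genotypes = TRUE, seed = 3)
  res <- simulate_dataset(cfg)
  em <- em_haplotype_frequencies(res$dataset$case_genotypes)
  expect_true(all(diff(em$loglik) >= -1e-9))
  expect_error(em_haplotype_frequencies(matrix("A/A", 1, 13)),
               "<= 12 markers")
})

test_that("carrier haplotype distributions pass through, merge, renormalise", {
  ph <- data.frame(hap1 = c("A,B", "A,b"), hap2 = c("a,b", "a,B"),
                   probability = c(0.7, 0.3))
  d <- carrier_haplotype_distribution(ph, carrier = c(1L, 1L))
  expect_equal(d$probability[d$haplotype == "A,B"], 0.7)
  expect_equal(sum(d$probability), 1)

  # both configurations give the same carrier haplotype: merged to one
  ph2 <- data.frame(hap1 = c("A,B", "A,B"), hap2 = c("a,b", "a,B"),
                    probability = c(0.6, 0.4))
  d2 <- carrier_haplotype_distribution(ph2, carrier = c(1L, 1L))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$probability, 1)

  expect_error(carrier_haplotype_distribution(ph, carrier = NULL),
               "carrier")

  # tiny entries are pruned and the rest renormalised
  ph3 <- data.frame(hap1 = c("A,B", "A,b"), hap2 = c("a,b", "a,B"),
                    probability = c(1 - 1e-9, 1e-9))
  d3 <- carrier_haplotype_distribution(ph3, carrier = c(1L, 1L))
  expect_equal(nrow(d3), 1)
  expect_equal(sum(d3$probability), 1)
})

test_that("phased carrier chromosomes become unit-mass distributions", {
  haps <- matrix(c("A", "B", "a", "b"), 2, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), NULL))
  ds <- carrier_distributions_from_phased(haps)
  expect_equal(ds$s1$haplotype, "A,B")
  expect_equal(ds$s1$probability, 1)
  expect_equal(vapply(ds, function(d) sum(d$probability), 1),
               c(s1 = 1, s2 = 1))
})

test_that("anchor phasing recovers carrier haplotypes from genotypes", {
  # carriers homozygous at every marker phase exactly; the anchor selects
  # the mutation-bearing chromosome unambiguously
  map <- make_snp_map(3, span_mb = 2)
  cg <- matrix(c("1/1", "2/2", "1/1"), 1, 3,
               dimnames = list("c1", map$table$name))
  d <- phase_carriers(cg, map)
  expect_equal(d$c1$haplotype, "1,2,1")
  expect_equal(d$c1$probability, 1)

  # a heterozygous carrier against many homozygous "1,1,1" controls:
  # joint phasing should favour assigning the common background
  # haplotype to the non-carrier chromosome
  cg2 <- matrix(c("1/2", "1/2", "1/2"), 1, 3,
                dimnames = list("c1", map$table$name))
  ctl <- matrix("1/1", 8, 3)
  d2 <- phase_carriers(cg2, map, control_genotypes = ctl)
  top <- d2$c1$haplotype[which.max(d2$c1$probability)]
  expect_equal(top, "2,2,2")
})

test_that("allele counting in controls and weighted counting in carriers", {
  map <- make_snp_map(1, span_mb = 2)
  ctl <- matrix(c(rep("1", 9), "2"), 10, 1,
                dimnames = list(NULL, map$table$name))
  fr <- allele_frequencies(ctl, map)
  expect_equal(unname(fr$p_N[[1]]["1"]), 0.9)
  expect_error(allele_frequencies(ctl[0, , drop = FALSE], map),
               "at least one control")

  # two carriers, one split 0.5/0.5 across alleles at the marker:
  # weighted count = (1 + 0.5) / 2
  mk_d <- function(haps, probs) {
    d <- data.frame(haplotype = haps, probability = probs)
    class(d) <- c("hap_distribution", "data.frame")
    d
  }
  dist <- list(mk_d("1", 1), mk_d(c("1", "2"), c(0.5, 0.5)))
  fr2 <- allele_frequencies(ctl, map, dist)
  expect_equal(unname(fr2$p_D[[1]]["1"]), 0.75)
  expect_equal(unname(fr2$p_D[[1]]["2"]), 0.25)
})

test_that("ancestral haplotype is the weighted allele mode with sensible
           tie-breaks", {
  map <- make_snp_map(1, span_mb = 2)
  mk_d <- function(haps, probs) {
    d <- data.frame(haplotype = haps, probability = probs)
    class(d) <- c("hap_distribution", "data.frame")
    d
  }
  # carriers split 0.6/0.4
  dist <- list(mk_d(c("1", "2"), c(0.6, 0.4)))
  anc <- infer_ancestral_haplotype(dist, map)
  expect_equal(unname(anc$alleles[1]), "1")
  expect_equal(unname(anc$support[1]), 0.6)

  # exact tie: prefer the allele enriched relative to controls
  dist2 <- list(mk_d(c("1", "2"), c(0.5, 0.5)))
  ctl <- matrix(c(rep("1", 9), "2"), 10, 1,
                dimnames = list(NULL, map$table$name))
  fr <- allele_frequencies(ctl, map)
  anc2 <- infer_ancestral_haplotype(dist2, map, fr)
  expect_equal(unname(anc2$alleles[1]), "2")   # p_D/p_N = .5/.1 beats .5/.9
  # tie with no frequencies: lexicographically smallest label
  anc3 <- infer_ancestral_haplotype(dist2, map)
  expect_equal(unname(anc3$alleles[1]), "1")
})

test_that("ancestral inference recovers the simulated founder at close
           markers", {
  # moderate age, no marker mutation: markers with theta < 0.01 should
  # almost always keep the founder allele as the carrier majority
  set.seed(2024)
  map <- make_snp_map(5, span_mb = 5)   # thetas up to ~0.025
  close_mk <- map$table$name[map$table$theta_locus < 0.01]
  map$table$mutation_rate[] <- 0
  hits <- 0L
  n_rep <- 200
  for (k in seq_len(n_rep)) {
    pool <- fixed_freq_pool(map, 0.5, n_haps = 100)
    cfg <- sim_config(10, 1.5, 20, 50, map, pool, genealogy = "star",
                      seed = 5000 + k)
    res <- simulate_dataset(cfg)
    dists <- carrier_distributions_from_phased(res$dataset$case_haps)
    anc <- infer_ancestral_haplotype(dists, map)
    if (all(anc$alleles[close_mk] ==
              res$truth$ancestral_haplotype[close_mk])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("phase distribution readers parse both dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thap1\thap2\tprobability",
               "s1\tA,B\ta,b\t0.7",
               "s1\tA,b\ta,B\t0.3",
               "s2\tA,B\tA,B\t1.0"), tsv)
  ph <- read_phase_tsv(tsv)
  expect_equal(names(ph), c("s1", "s2"))
  expect_equal(ph$s1$probability, c(0.7, 0.3))

  pairs <- tempfile(fileext = ".out")
  writeLines(c("BEGIN BESTPAIRS1",
               "IND: s1",
               "A B , a b , 0.7",
               "A b , a B , 0.3",
               "IND: s2",
               "A B , A B , 1.0",
               "END BESTPAIRS1"), pairs)
  ph2 <- read_phase_pairs(pairs)
  expect_equal(ph2$s1$hap1, c("A,B", "A,b"))
  expect_equal(ph2$s1$probability, c(0.7, 0.3))
  expect_equal(ph2$s2$hap2, "A,B")

  writeLines(c("IND: s1", "A B , a b"), pairs)
  expect_error(read_phase_pairs(pairs), "line 2")
})
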