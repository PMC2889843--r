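test_that("growth process basics: zero generations, trajectory shape", {
  out <- simulate_growth_lineages(0, 1.5)
  expect_equal(out$trajectory, 1L)
  expect_length(out$parents, 0)

  set.seed(3)
  out <- simulate_growth_lineages(10, 1.4)
  expect_length(out$trajectory, 11)
  expect_equal(out$trajectory[1], 1)
  expect_gt(tail(out$trajectory, 1), 0)   # conditioned on survival
  # parent pointers are consistent with the trajectory
  for (t in seq_len(10)) {
    expect_length(out$parents[[t]], out$trajectory[t + 1])
    if (out$trajectory[t + 1] > 0) {
      expect_true(all(out$parents[[t]] >= 1 &
                        out$parents[[t]] <= out$trajectory[t]))
    }
  }
})

test_that("unconditioned mean copy count is r^g and extinction matches the
           fixed point of s = exp(r(s-1))", {
  set.seed(101)
  n_reps <- 4000
  r <- 1.5; g <- 12
  finals <- vapply(seq_len(n_reps), function(i) {
    tail(simulate_growth_lineages(g, r, condition_on_survival = FALSE,
                                  mode = "counts")$trajectory, 1)
  }, numeric(1))
  expect_equal(mean(finals), r^g, tolerance = 0.1)
  expect_equal(mean(finals == 0), gw_extinction_prob(r), tolerance = 0.03)
  expect_equal(gw_extinction_prob(1.5), 0.417, tolerance = 1e-3)
  expect_equal(gw_extinction_prob(0.9), 1)
})

test_that("growth conditioning fails loudly for a shrinking population", {
  expect_error(
    simulate_growth_lineages(60, 0.2, max_attempts = 25, mode = "counts"),
    "max_attempts")
})

test_that("no recombination and no mutation transmit the founder exactly", {
  map <- make_snp_map(5, span_mb = 4)
  map$table$theta_interval[] <- 0
  map$table$mutation_rate[] <- 0
  set.seed(7)
  pool <- fixed_freq_pool(map, 0.3)
  cfg <- sim_config(12, 1.3, 8, 20, map, pool, genealogy = "branching",
                    condition = "n_cases", seed = 21)
  res <- simulate_dataset(cfg)
  anc <- res$truth$ancestral_haplotype
  for (i in seq_len(nrow(res$dataset$case_haps))) {
    expect_equal(unname(res$dataset$case_haps[i, ]), unname(anc))
  }
})

test_that("at age zero the single case is the founder draw", {
  map <- make_snp_map(4, span_mb = 3)
  set.seed(9)
  pool <- fixed_freq_pool(map, c(0.2, 0.5, 0.7, 0.4))
  cfg <- sim_config(0, 1.5, 1, 5, map, pool, seed = 4)
  res <- simulate_dataset(cfg)
  expect_equal(unname(res$dataset$case_haps[1, ]),
               unname(res$truth$ancestral_haplotype))
})

test_that("star-mode decay at one marker matches the closed form", {
  theta <- 0.01; g <- 10; n <- 5000
  map <- one_marker_map(theta, mu = 0)
  set.seed(15)
  pool <- fixed_freq_pool(map, 0.4, n_haps = 1000)
  cfg <- sim_config(g, 1.5, n, 0, map, pool, genealogy = "star", seed = 33)
  res <- simulate_dataset(cfg)
  anc <- res$truth$ancestral_haplotype[1]
  p_pool <- mean(pool$haps[, 1] == anc)
  phi <- (1 - theta)^g
  expected <- phi + (1 - phi) * p_pool
  observed <- mean(res$dataset$case_haps[, 1] == anc)
  expect_equal(observed, expected, tolerance = 0.02)
})

test_that("case haplotypes are ancestral-core mosaics when mu = 0", {
  map <- make_snp_map(7, span_mb = 12)
  map$table$mutation_rate[] <- 0
  set.seed(5)
  pool <- fixed_freq_pool(map, 0.5)
  cfg <- sim_config(25, 1.4, 12, 10, map, pool, genealogy = "branching",
                    condition = "n_cases", seed = 12)
  res <- simulate_dataset(cfg)
  anc <- res$truth$ancestral_haplotype
  cov <- res$truth$case_coverage
  for (s in c("proximal", "distal")) {
    idx <- side_indices(map, s)
    cc <- if (s == "proximal") cov$cov_proximal else cov$cov_distal
    for (i in seq_len(nrow(cov))) {
      keep <- idx[seq_len(cc[i])]
      expect_equal(unname(res$dataset$case_haps[i, keep]),
                   unname(anc[keep]))
    }
  }
})

test_that("decay of the intact fraction is monotone in age and in theta", {
  set.seed(77)
  mean_pd <- function(g, theta) {
    mean(simulate_marker_decay(g, 1.5, theta, p_anc = 0.2, n_cases = 500,
                               n_reps = 400, genealogy = "star"))
  }
  by_g <- vapply(c(5, 20, 60), mean_pd, numeric(1), theta = 0.02)
  expect_true(all(diff(by_g) < 0))
  by_theta <- vapply(c(0.005, 0.02, 0.08), function(th) mean_pd(20, th),
                     numeric(1))
  expect_true(all(diff(by_theta) < 0))
})

test_that("seeded simulations are bit-reproducible", {
  map <- make_snp_map(6, span_mb = 8)
  set.seed(2)
  pool <- fixed_freq_pool(map, 0.35)
  cfg <- sim_config(15, 1.5, 10, 30, map, pool, genealogy = "branching",
                    condition = "n_cases", emit_genotypes = TRUE, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$case_haps, b$dataset$case_haps)
  expect_identical(a$dataset$control_haps, b$dataset$control_haps)
  expect_identical(a$dataset$case_genotypes, b$dataset$case_genotypes)
  expect_identical(a$truth$trajectory, b$truth$trajectory)
})

test_that("conditioning on bare survival refuses an oversized sample", {
  map <- one_marker_map(0.01)
  set.seed(1)
  pool <- fixed_freq_pool(map, 0.5)
  cfg <- sim_config(3, 1.1, 500, 0, map, pool, genealogy = "branching",
                    condition = "survival", seed = 8)
  expect_error(simulate_dataset(cfg), "surviving copies")
})

test_that("dataset round trip through TSV/JSON is lossless", {
  map <- make_snp_map(5, span_mb = 6)
  set.seed(10)
  pool <- fixed_freq_pool(map, 0.4)
  cfg <- sim_config(10, 1.5, 6, 15, map, pool, genealogy = "star",
                    emit_genotypes = TRUE, seed = 55)
  res <- simulate_dataset(cfg)
  dir <- tempfile("ds")
  write_dataset(res$dataset, dir, truth = res$truth)
  back <- read_dataset(dir)
  expect_equal(back$dataset$case_haps, res$dataset$case_haps)
  expect_equal(back$dataset$control_haps, res$dataset$control_haps)
  expect_equal(back$dataset$case_genotypes, res$dataset$case_genotypes)
  expect_equal(back$dataset$map$table, map$table)
  expect_equal(back$truth$g_true, res$truth$g_true)
  expect_equal(back$truth$ancestral_haplotype, res$truth$ancestral_haplotype)
  expect_equal(back$truth$trajectory, as.numeric(res$truth$trajectory))

  # truth sidecar is optional
  dir2 <- tempfile("ds")
  write_dataset(res$dataset, dir2)
  expect_null(read_dataset(dir2)$truth)

  # corrupted allele labels are a parse error with a line number
  tab <- readLines(file.path(dir, "haplotypes.tsv"))
  tab[2] <- sub("\t[12]$", "\tZ", tab[2])
  writeLines(tab, file.path(dir, "haplotypes.tsv"))
  expect_error(read_dataset(dir), "line 2")
})
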