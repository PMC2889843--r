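# Shared fixtures: small marker maps and background pools built in code.

# evenly spaced SNP map with the locus at the centre
make_snp_map <- function(n_markers = 5, span_mb = 5, locus_frac = 0.5,
                         cm_per_mb = 1) {
  pos <- round(seq(0, span_mb * 1e6, length.out = n_markers))
  mk <- data.frame(
    name = sprintf("m%02d", seq_len(n_markers)),
    position_bp = pos,
    type = "snp",
    alleles = I(replicate(n_markers, c("1", "2"), simplify = FALSE)),
    stringsAsFactors = FALSE
  )
  locus <- round(span_mb * 1e6 * locus_frac) + 1L  # off-grid of the markers
  build_marker_map(mk, disease_locus_bp = locus, cm_per_mb = cm_per_mb)
}


# one-marker map with an exactly chosen recombination fraction
one_marker_map <- function(theta, alleles = c("1", "2"), type = "snp",
                           mu = 0) {
  mk <- data.frame(name = "m1", position_bp = 1e6, type = type,
                   alleles = I(list(alleles)), mutation_rate = mu,
                   stringsAsFactors = FALSE)
  map <- build_marker_map(mk, disease_locus_bp = 0)
  map$table$theta_locus <- theta
  map$table$theta_interval <- theta
  map
}

# pool with independent per-marker allele frequencies fixed by the caller:
# p1[j] is the frequency of allele "1" at marker j (SNP maps only)
fixed_freq_pool <- function(map, p1, n_haps = 400) {
  m <- nrow(map$table)
  p1 <- rep_len(p1, m)
  haps <- matrix("", n_haps, m)
  colnames(haps) <- map$table$name
  for (j in seq_len(m)) {
    n1 <- round(n_haps * p1[j])
    haps[, j] <- sample(c(rep("1", n1), rep("2", n_haps - n1)))
  }
  list(haps = haps, freqs = rep(1 / n_haps, n_haps))
}

# allele_frequencies object with exact, hand-set control frequencies
exact_freqs <- function(map, p1) {
  m <- nrow(map$table)
  p1 <- rep_len(p1, m)
  p_N <- lapply(seq_len(m), function(j) {
    stats::setNames(c(p1[j], 1 - p1[j]), map$alleles[[map$table$name[j]]])
  })
  names(p_N) <- map$table$name
  structure(list(p_N = p_N, p_D = NULL, n_controls = NA, n_carriers = NA),
            class = "allele_frequencies")
}

as_ancestral <- function(alleles, map) {
  structure(list(alleles = stats::setNames(alleles, map$table$name),
                 support = stats::setNames(rep(1, length(alleles)),
                                           map$table$name)),
            class = "ancestral_haplotype")
}
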