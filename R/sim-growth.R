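#' Simulate the growth of mutation copies as a Galton-Watson process
#'
#' Forward-simulates the number of copies of a founder mutation over `g`
#' generations, starting from a single copy, with each copy leaving
#' Poisson(`r`) offspring per generation (so the expected copy count after
#' g generations is r^g). By default the process is conditioned on at
#' least one copy surviving to the present, by full resampling of extinct
#' runs.
#'
#' Two modes are offered. `"genealogy"` keeps parent pointers for every
#' generation (needed to propagate haplotypes down the tree);
#' `"counts"` tracks only the per-generation copy count, using the
#' equivalent aggregated recursion N' ~ Poisson(r N), which is cheap even
#' for large populations.
#'
#' @param g Number of generations (integer >= 0).
#' @param r Growth rate: mean offspring per copy per generation (> 0).
#' @param condition_on_survival If TRUE (default), resample runs that go
#'   extinct before generation g.
#' @param mode "genealogy" or "counts".
#' @param max_attempts Resampling cap when conditioning on survival.
#' @param max_pop Population cap in genealogy mode (guards runaway
#'   memory when r is large).
#' @return A list with `trajectory` (copy counts, length g+1, starting at
#'   1) and, in genealogy mode, `parents`: a list of g integer vectors,
#'   `parents[[t]][k]` giving the index (in generation t-1) of the parent
#'   of copy k in generation t.
#' @export
simulate_growth_lineages <- function(g, r, condition_on_survival = TRUE,
                                     mode = c("genealogy", "counts"),
                                     max_attempts = 10000, max_pop = 1e6) {
  stopifnot(g >= 0, r > 0)
  mode <- match.arg(mode)
  g <- as.integer(g)
  if (g == 0) {
    return(list(trajectory = 1L,
                parents = if (mode == "genealogy") list() else NULL))
  }
  for (attempt in seq_len(max_attempts)) {
    traj <- numeric(g + 1)
    traj[1] <- 1
    parents <- if (mode == "genealogy") vector("list", g) else NULL
    n <- 1
    extinct <- FALSE
    for (t in seq_len(g)) {
      if (mode == "genealogy") {
        off <- stats::rpois(n, r)
        n_new <- sum(off)
        if (n_new > max_pop) {
          stop("population exceeded max_pop = ", max_pop,
               " at generation ", t, "; reduce g or r, or use mode='counts'")
        }
        if (n_new > 0) parents[[t]] <- rep.int(seq_len(n), off)
        n <- n_new
      } else {
        n <- stats::rpois(1, r * n)
      }
      traj[t + 1] <- n
      if (n == 0) { extinct <- TRUE; break }
    }
    if (!extinct || !condition_on_survival) {
      return(list(trajectory = traj, parents = parents))
    }
  }
  stop("no surviving lineage after max_attempts = ", max_attempts,
       " resampling attempts (r = ", r, ", g = ", g, ")")
}

#' Ultimate extinction probability of the Poisson Galton-Watson process
#'
#' The extinction probability is the smallest fixed point of
#' s = exp(r (s - 1)); for r <= 1 it is 1.
#'
#' @param r Mean offspring per generation.
#' @return Extinction probability in [0, 1].
#' @export
gw_extinction_prob <- function(r) {
  stopifnot(r > 0)
  if (r <= 1) return(1)
  f <- function(s) exp(r * (s - 1)) - s
  stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-12)$root
}

# Single-marker decay under the intra-allelic genealogy, tracked at the
# population level. Only two numbers are needed per replicate and
# generation: the total copy count N and the count N_I of copies whose
# ancestral segment still covers the marker ("intact"). Offspring of an
# intact copy are intact with probability (1 - theta); Poisson offspring
# and binomial thinning give the exact joint recursion
#   O_I ~ Poisson(r N_I), O_rest ~ Poisson(r (N - N_I)),
#   N'  = O_I + O_rest,   N_I' ~ Binomial(O_I, 1 - theta).
# This captures the shared-ancestry correlation of the branching genealogy
# without storing the tree. Once counts are very large the stochastic
# recursion is replaced by its deterministic limit (fractions evolve as
# phi' = phi (1 - theta)), which also keeps very fast-growing populations
# (r >> 1) tractable.
#
# Sampled chromosomes match the ancestral allele if intact, or with
# probability p_anc (the allele's background pool frequency) if not.

#' Simulate the carrier-sample ancestral-allele fraction at one marker
#'
#' Runs `n_reps` replicates of the founder process at a single marker a
#' recombination fraction `theta` from the disease locus, and returns for
#' each replicate the fraction of `n_cases` sampled carrier chromosomes
#' that carry the ancestral allele. Under the star genealogy the carriers
#' are independent; under the branching (Galton-Watson) genealogy early
#' shared recombination events make replicates much more variable, which
#' is the source of the downward bias of the median single-marker age
#' estimate that the growth correction removes.
#'
#' @param g True age in generations.
#' @param r Growth rate per generation (used in branching mode).
#' @param theta Recombination fraction marker-locus.
#' @param p_anc Background pool frequency of the ancestral allele.
#' @param n_cases Carrier chromosomes sampled per replicate (in branching
#'   mode, when fewer copies survive, all surviving copies are sampled).
#' @param n_reps Number of replicates.
#' @param genealogy "branching" (Galton-Watson, conditioned on survival)
#'   or "star" (independent lineages of depth g).
#' @return Numeric vector of length `n_reps`: per-replicate fraction of
#'   sampled carriers matching the ancestral allele.
#' @export
simulate_marker_decay <- function(g, r, theta, p_anc, n_cases, n_reps,
                                  genealogy = c("branching", "star")) {
  genealogy <- match.arg(genealogy)
  stopifnot(g >= 0, theta >= 0, theta < 1, p_anc >= 0, p_anc <= 1,
            n_cases >= 1, n_reps >= 1)
  g <- as.integer(g)

  if (genealogy == "star") {
    phi <- (1 - theta)^g
    p_match <- phi + (1 - phi) * p_anc
    return(stats::rbinom(n_reps, n_cases, p_match) / n_cases)
  }

  det_threshold <- 1e7
  out <- numeric(n_reps)
  need <- rep(TRUE, n_reps)   # replicates still to be filled
  attempt <- 0
  repeat {
    attempt <- attempt + 1
    if (attempt > 10000) {
      stop("no surviving lineage after 10000 resampling rounds (r = ", r,
           ", g = ", g, ")")
    }
    idx <- which(need)
    N <- rep(1, length(idx)); NI <- rep(1, length(idx))
    for (t in seq_len(g)) {
      big <- N > det_threshold
      if (any(!big)) {
        oi <- stats::rpois(sum(!big), r * NI[!big])
        oo <- stats::rpois(sum(!big), r * (N[!big] - NI[!big]))
        NI[!big] <- stats::rbinom(sum(!big), oi, 1 - theta)
        N[!big] <- oi + oo
      }
      if (any(big)) {
        # deterministic limit for huge populations
        NI[big] <- NI[big] * r * (1 - theta)
        N[big] <- N[big] * r
      }
      if (all(N == 0)) break
    }
    ok <- N >= 1
    if (any(ok)) {
      k <- idx[ok]
      Nk <- N[ok]; NIk <- NI[ok]
      # sample without replacement (all copies when fewer survive than
      # requested): the intact count is hypergeometric; non-intact
      # chromosomes match the ancestral allele at its pool frequency
      draw <- pmin(n_cases, Nk)
      intact <- integer(length(k))
      big <- Nk > det_threshold
      if (any(big)) {
        intact[big] <- stats::rbinom(sum(big), draw[big], NIk[big] / Nk[big])
      }
      if (any(!big)) {
        intact[!big] <- stats::rhyper(sum(!big), round(NIk[!big]),
                                      round(Nk[!big] - NIk[!big]),
                                      draw[!big])
      }
      matches <- intact + stats::rbinom(length(k), draw - intact, p_anc)
      out[k] <- matches / draw
      need[k] <- FALSE
    }
    if (!any(need)) break
  }
  out
}
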