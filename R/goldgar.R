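# Modified Goldgar multi-marker likelihood.
#
# The likelihood of one carrier haplotype given an age g proceeds outward
# from the disease locus on each side independently. The ancestral segment
# survives each inter-marker interval (including the locus flank) over g
# meioses with probability (1 - theta_interval)^g; recombination is
# absorbing -- once the segment is lost, all outer markers emit at the
# background (control) allele frequency. While the segment is intact, a
# marker emits the ancestral allele with probability (1 - mu)^g and a
# mutant allele with the complementary mass (SNPs and generic markers:
# spread over the other alleles; STRs: split equally over the one-step
# neighbours, so distant repeat lengths are explained by recombination,
# not mutation). The two side-likelihoods multiply. With a recurrence
# prior pi > 0 the total is (1 - pi) * L_descent + pi * L_background,
# where L_background emits every marker at its background frequency.
# Carrier haplotype uncertainty enters as a weighted sum over each
# carrier's possible mutation-bearing haplotypes.

#' Build a Goldgar model object
#'
#' Precomputes the per-side interval recombination fractions, the
#' mutation rates and ancestral alleles in outward order, so the
#' likelihood can be evaluated cheaply on a grid of ages.
#'
#' @param map A `marker_map`.
#' @param ancestral An [infer_ancestral_haplotype()] result (or a named
#'   allele vector in map order).
#' @param freqs An [allele_frequencies()] object (p_N is used).
#' @param mu Optional per-marker mutation-rate override (named, or single
#'   value recycled); defaults to the map's per-marker rates.
#' @param pi_recurrence Prior probability that a carrier chromosome is an
#'   independent recurrence of the mutation rather than a descent copy
#'   (default 0).
#' @return A classed `goldgar_model` list.
#' @export
goldgar_model <- function(map, ancestral, freqs, mu = NULL,
                          pi_recurrence = 0) {
  anc <- if (inherits(ancestral, "ancestral_haplotype")) ancestral$alleles
         else ancestral
  stopifnot(length(anc) == nrow(map$table))
  if (pi_recurrence < 0 || pi_recurrence >= 1) {
    stop("pi_recurrence must lie in [0, 1)")
  }
  mu_vec <- map$table$mutation_rate
  names(mu_vec) <- map$table$name
  if (!is.null(mu)) {
    if (is.null(names(mu))) mu_vec[] <- mu else mu_vec[names(mu)] <- mu
  }
  if (any(mu_vec < 0 | mu_vec > 0.1)) {
    stop("per-generation mutation rates must lie in [0, 0.1]")
  }
  sides <- lapply(c(proximal = "proximal", distal = "distal"), function(s) {
    idx <- side_indices(map, s)
    list(idx = idx,
         theta = map$table$theta_interval[idx],
         mu = mu_vec[idx],
         anc = unname(anc[map$table$name[idx]]),
         names = map$table$name[idx])
  })
  structure(list(map = map, ancestral = anc, freqs = freqs,
                 mu = mu_vec, pi_recurrence = pi_recurrence,
                 sides = sides),
            class = "goldgar_model")
}

# intact-state emission probability of observed allele `obs` at a marker
# with ancestral allele `anc`, for a vector of ages g. `alleles` is the
# marker's ordered allele list, `type` its marker type.
.intact_emission <- function(obs, anc, mu, g, alleles, type) {
  keep <- (1 - mu)^g
  if (obs == anc) return(keep)
  if (type %in% c("dinucleotide_str", "tetranucleotide_str")) {
    ia <- match(anc, alleles); io <- match(obs, alleles)
    nb <- sum(c(ia - 1, ia + 1) >= 1 & c(ia - 1, ia + 1) <= length(alleles))
    if (abs(io - ia) == 1) (1 - keep) / nb else rep(0, length(g))
  } else {
    (1 - keep) / (length(alleles) - 1)
  }
}

# likelihood of one side's observed alleles for a vector of ages g
.side_lik <- function(obs, side, model, g) {
  k <- length(side$idx)
  G <- length(g)
  if (k == 0) return(rep(1, G))
  map <- model$map
  pN <- vapply(seq_len(k), function(j) {
    p <- model$freqs$p_N[[side$names[j]]][obs[j]]
    if (is.na(p)) {
      stop("allele '", obs[j], "' absent from the frequency table of ",
           side$names[j])
    }
    p
  }, numeric(1))
  # survival per interval and cumulative ancestral-segment reach
  q <- vapply(seq_len(k), function(j) (1 - side$theta[j])^g, numeric(G))
  if (G == 1) q <- matrix(q, 1, k)
  A <- t(apply(q, 1, cumprod))            # G x k, A[, b] = reach >= b
  if (k == 1) A <- matrix(A, G, 1)
  # intact emissions and their cumulative products
  E <- vapply(seq_len(k), function(j) {
    .intact_emission(obs[j], side$anc[j], side$mu[j], g,
                     map$alleles[[side$names[j]]],
                     map$table$type[side$idx[j]])
  }, numeric(G))
  if (G == 1) E <- matrix(E, 1, k)
  Cm <- t(apply(E, 1, cumprod))
  if (k == 1) Cm <- matrix(Cm, G, 1)
  # background suffix products D[b+1] = prod_{j>b} pN_j, b = 0..k
  D <- rev(cumprod(c(1, rev(pN))))
  L <- (1 - q[, 1]) * D[1]                # segment lost in the locus flank
  for (b in seq_len(k)) {
    w <- if (b < k) A[, b] * (1 - q[, b + 1]) else A[, k]
    L <- L + w * Cm[, b] * D[b + 1]
  }
  L
}

#' Log-likelihood of one haplotype under the Goldgar model
#'
#' @param hap Haplotype: comma-joined string or character vector of
#'   allele labels in map order.
#' @param g Age(s) in generations (vectorised).
#' @param model A [goldgar_model()].
#' @return Log-probability (vector over `g`); -Inf when the haplotype is
#'   impossible at that age.
#' @export
haplotype_loglik <- function(hap, g, model) {
  if (any(g < 0)) stop("g must be non-negative")
  m <- nrow(model$map$table)
  a <- if (length(hap) == 1 && m > 1) hap_alleles(hap) else as.character(hap)
  if (length(a) != m) {
    stop("haplotype length ", length(a), " does not match the map (",
         m, " markers)")
  }
  names(a) <- model$map$table$name
  L <- rep(1, length(g))
  for (s in model$sides) {
    L <- L * .side_lik(unname(a[s$names]), s, model, g)
  }
  pi <- model$pi_recurrence
  if (pi > 0) {
    pbg <- prod(vapply(seq_along(a), function(j) {
      model$freqs$p_N[[names(a)[j]]][a[j]]
    }, numeric(1)))
    L <- (1 - pi) * L + pi * pbg
  }
  log(L)
}

#' Total log-likelihood of a carrier dataset
#'
#' Sums over carriers the log of the probability-weighted likelihood over
#' each carrier's possible mutation-bearing haplotypes.
#'
#' @param distributions List of `hap_distribution`s.
#' @param g Age(s) in generations (vectorised).
#' @param model A [goldgar_model()].
#' @return Log-likelihood vector over `g`.
#' @export
dataset_loglik <- function(distributions, g, model) {
  stopifnot(length(distributions) >= 1)
  total <- rep(0, length(g))
  for (nm in seq_along(distributions)) {
    d <- distributions[[nm]]
    Lsum <- rep(0, length(g))
    for (k in seq_len(nrow(d))) {
      Lsum <- Lsum + d$probability[k] *
        exp(haplotype_loglik(d$haplotype[k], g, model))
    }
    if (all(Lsum == 0)) {
      id <- names(distributions)[nm]
      stop("carrier ", if (is.null(id) || id == "") nm else id,
           " has zero likelihood at every requested age")
    }
    total <- total + log(Lsum)
  }
  total
}

#' Maximum-likelihood age by integer grid search
#'
#' Maximises the dataset log-likelihood over an integer grid of ages and
#' reports a likelihood-ratio confidence interval: all grid ages whose
#' log-likelihood is within `ci_cutoff` of the maximum (1.92, the
#' chi-square 1-df 95% cutoff, by default; 2.30 gives the 1-LOD
#' convention). Interval bounds that touch the grid boundary are flagged,
#' as is a tie at the maximum (resolved to the smallest age).
#'
#' @param distributions List of `hap_distribution`s.
#' @param model A [goldgar_model()].
#' @param g_min,g_max Grid bounds in generations (default 0-500).
#' @param ci_cutoff Log-likelihood drop defining the interval.
#' @return An `age_estimate`: list with `method`, `g_hat`, `ci_low`,
#'   `ci_high`, `loglik_at_max`, boundary/tie flags, the per-age
#'   log-likelihood `curve`, and (initially zero) growth-correction
#'   fields.
#' @export
mle_age <- function(distributions, model, g_min = 0, g_max = 500,
                    ci_cutoff = 1.92) {
  stopifnot(g_min >= 0, g_max >= g_min)
  grid <- seq.int(g_min, g_max)
  ll <- dataset_loglik(distributions, grid, model)
  finite <- is.finite(ll)
  if (!any(finite)) stop("log-likelihood is -Inf over the whole grid")
  mx <- max(ll[finite])
  at_max <- which(ll == mx)
  tie <- length(at_max) > 1
  g_hat <- grid[at_max[1]]
  in_ci <- which(finite & (mx - ll) <= ci_cutoff)
  ci_low <- grid[min(in_ci)]; ci_high <- grid[max(in_ci)]
  boundary_low <- ci_low == g_min
  boundary_high <- ci_high == g_max
  if (g_hat %in% c(g_min, g_max) && (ll[1] == mx || ll[length(ll)] == mx)) {
    warning("likelihood is maximised at the grid boundary (g = ", g_hat,
            "); widen the grid")
  }
  structure(list(method = "goldgar", g_hat = g_hat,
                 ci_low = ci_low, ci_high = ci_high,
                 loglik_at_max = mx, ci_cutoff = ci_cutoff,
                 boundary_low = boundary_low, boundary_high = boundary_high,
                 tie_at_max = tie,
                 delta = 0, g_corrected = g_hat,
                 ci_low_corrected = ci_low, ci_high_corrected = ci_high,
                 curve = data.frame(g = grid, loglik = ll)),
            class = "age_estimate")
}

#' Apply an additive growth correction to an age estimate
#'
#' The same correction is added to the point estimate and to both
#' confidence bounds; boundary flags are preserved (a corrected
#' lower bound that was at the grid boundary is still reported as an
#' at-boundary bound, "<= low").
#'
#' @param estimate An `age_estimate`.
#' @param delta Additive correction in generations (>= 0).
#' @return The corrected `age_estimate`.
#' @export
corrected_age <- function(estimate, delta) {
  stopifnot(inherits(estimate, "age_estimate"), delta >= 0)
  estimate$delta <- delta
  estimate$g_corrected <- estimate$g_hat + delta
  estimate$ci_low_corrected <- estimate$ci_low + delta
  estimate$ci_high_corrected <- estimate$ci_high + delta
  estimate
}

#' @export
print.age_estimate <- function(x, ...) {
  fmt_b <- function(v, flag) if (flag) paste0("<= ", v) else v
  cat(x$method, "age estimate:", x$g_hat, "generations, 95% CI [",
      fmt_b(x$ci_low, x$boundary_low), ",",
      fmt_b(x$ci_high, x$boundary_high), "]\n")
  if (x$delta > 0) {
    cat("  growth-corrected:", x$g_corrected, "generations, CI [",
        fmt_b(x$ci_low_corrected, x$boundary_low), ",",
        fmt_b(x$ci_high_corrected, x$boundary_high), "]\n")
  }
  invisible(x)
}

#' Exhaustive reference likelihood by event-placement enumeration
#'
#' Computes the same haplotype probability as [haplotype_loglik()] by
#' brute force, enumerating on each side every placement of recombination
#' events on the per-meiosis lattice (g meioses x k intervals) and every
#' pattern of marker-mutation indicators, summing the probability of each
#' configuration consistent with the observed alleles. Exponential in
#' g and the map size; intended only for validating the scan on tiny
#' maps.
#'
#' @param hap Haplotype (string or allele vector in map order).
#' @param g Age in generations (single value).
#' @param model A [goldgar_model()].
#' @param max_configs Guard on the enumeration size (default 2^20).
#' @return Log-probability.
#' @export
goldgar_enumerate_loglik <- function(hap, g, model, max_configs = 2^20) {
  stopifnot(length(g) == 1, g >= 0)
  m <- nrow(model$map$table)
  a <- if (length(hap) == 1 && m > 1) hap_alleles(hap) else as.character(hap)
  names(a) <- model$map$table$name
  map <- model$map
  side_prob <- function(side) {
    k <- length(side$idx)
    if (k == 0) return(1)
    obs <- unname(a[side$names])
    pN <- vapply(seq_len(k), function(j) {
      model$freqs$p_N[[side$names[j]]][obs[j]]
    }, numeric(1))
    n_rec_bits <- g * k
    if (2^n_rec_bits * 2^k > max_configs) {
      stop("enumeration too large (", n_rec_bits + k, " bits); shrink g or the map")
    }
    total <- 0
    mut_p <- 1 - (1 - side$mu)^g     # P(>= 1 mutation over g generations)
    for (cfg in seq_len(max(2^n_rec_bits, 1)) - 1L) {
      rec <- if (n_rec_bits > 0) {
        matrix(as.integer(intToBits(cfg))[seq_len(n_rec_bits)], g, k) == 1L
      } else matrix(FALSE, 0, k)
      p_rec <- prod(ifelse(rec, rep(side$theta, each = g),
                           rep(1 - side$theta, each = g)))
      # marker j stays on the ancestral segment iff no event ever occurred
      # in intervals 1..j (the segment only erodes outward-in)
      ever <- if (g > 0) apply(rec, 2, any) else rep(FALSE, k)
      intact <- !cumsum(ever) > 0
      # enumerate mutation indicators on the intact markers
      for (mcfg in seq_len(2^k) - 1L) {
        mut <- as.integer(intToBits(mcfg))[seq_len(k)] == 1L
        p_mut <- prod(ifelse(mut, mut_p, 1 - mut_p))
        p_obs <- 1
        for (j in seq_len(k)) {
          p_obs <- p_obs * if (!intact[j]) {
            pN[j]
          } else if (!mut[j]) {
            as.numeric(obs[j] == side$anc[j])
          } else {
            alleles <- map$alleles[[side$names[j]]]
            type <- map$table$type[side$idx[j]]
            if (type %in% c("dinucleotide_str", "tetranucleotide_str")) {
              ia <- match(side$anc[j], alleles); io <- match(obs[j], alleles)
              nb <- sum(c(ia - 1, ia + 1) >= 1 &
                          c(ia - 1, ia + 1) <= length(alleles))
              if (abs(io - ia) == 1) 1 / nb else 0
            } else {
              if (obs[j] != side$anc[j]) 1 / (length(alleles) - 1) else 0
            }
          }
          if (p_obs == 0) break
        }
        total <- total + p_rec * p_mut * p_obs
      }
    }
    total
  }
  L <- prod(vapply(model$sides, side_prob, numeric(1)))
  pi <- model$pi_recurrence
  if (pi > 0) {
    pbg <- prod(vapply(seq_along(a), function(j) {
      model$freqs$p_N[[names(a)[j]]][a[j]]
    }, numeric(1)))
    L <- (1 - pi) * L + pi * pbg
  }
  log(L)
}
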