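# Single-marker age estimation from the decay of linkage disequilibrium.
#
# If p_D is the frequency of the ancestral (mutation-associated) allele on
# carrier chromosomes and p_N its frequency on control chromosomes, the
# excess association is delta = (p_D - p_N)/(1 - p_N). Under a star
# genealogy delta decays as (1 - theta)^g, so the age estimate is
# g = log(delta)/log(1 - theta). Estimates are undefined when the control
# frequency exceeds the carrier frequency (delta <= 0) and unstable for
# markers very close to the locus, where theta cannot be well estimated
# and log(1 - theta) is tiny.

#' Excess association of the ancestral allele on carrier chromosomes
#'
#' @param p_D Carrier-chromosome frequency of the ancestral allele.
#' @param p_N Control-chromosome frequency of the same allele (< 1).
#' @return delta = (p_D - p_N)/(1 - p_N); may be <= 0, in which case no
#'   age estimate exists downstream.
#' @export
p_excess <- function(p_D, p_N) {
  if (any(p_D < 0 | p_D > 1) || any(p_N < 0 | p_N > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (any(p_N >= 1)) stop("p_N must be < 1")
  (p_D - p_N) / (1 - p_N)
}

#' Single-marker age estimate from LD decay
#'
#' @param delta Excess association in (0, 1].
#' @param theta Recombination fraction marker-locus, in (0, 0.5).
#' @return Age in generations, log(delta)/log(1 - theta).
#' @export
age_single_marker <- function(delta, theta) {
  if (any(delta <= 0)) stop("delta must be positive (undefined excess)")
  if (any(delta > 1)) stop("delta must be <= 1")
  if (any(theta <= 0 | theta >= 0.5)) stop("theta must lie in (0, 0.5)")
  log(delta) / log(1 - theta)
}

#' Per-marker single-marker age estimates for a dataset
#'
#' Computes, for every marker in the map, the carrier and control
#' frequencies of the ancestral allele, the excess delta, the raw age
#' estimate, and (when a growth rate is supplied) the growth-corrected
#' estimate. Markers where the control frequency is not exceeded get
#' status `undefined_excess`; markers closer than `min_cm` to the locus
#' are estimated but flagged `unstable_close_marker` (their recombination
#' fraction is too small to be trusted) and are excluded from summaries.
#'
#' @param freqs An [allele_frequencies()] object with both p_N and p_D.
#' @param ancestral An [infer_ancestral_haplotype()] result.
#' @param map The `marker_map`.
#' @param r Optional growth rate (> 1) to apply the growth correction.
#' @param correction "montecarlo" or "table"; see [labuda_correction()].
#' @param delta_table Named per-marker corrections for table mode (a
#'   single unnamed value is recycled to all markers).
#' @param min_cm Markers closer than this (cM) are flagged unstable
#'   (default 0.1).
#' @param seed,n_sims,n_cases Passed to [labuda_correction()] in
#'   montecarlo mode.
#' @return A data.frame, one row per marker: name, dist_cm, theta, p_D,
#'   p_N, delta, g_raw, delta_correction, g_corrected, status.
#' @export
single_marker_ages <- function(freqs, ancestral, map, r = NULL,
                               correction = c("montecarlo", "table"),
                               delta_table = NULL, min_cm = 0.1,
                               seed = 1, n_sims = 1000, n_cases = 100) {
  correction <- match.arg(correction)
  if (is.null(freqs$p_D)) stop("freqs must include carrier frequencies p_D")
  tab <- map$table
  n <- nrow(tab)
  out <- data.frame(
    marker = tab$name, dist_cm = tab$dist_cm, theta = tab$theta_locus,
    p_D = NA_real_, p_N = NA_real_, delta = NA_real_, g_raw = NA_real_,
    delta_correction = NA_real_, g_corrected = NA_real_,
    status = "ok", stringsAsFactors = FALSE
  )
  for (j in seq_len(n)) {
    anc <- ancestral$alleles[tab$name[j]]
    pD <- freqs$p_D[[tab$name[j]]][anc]
    pN <- freqs$p_N[[tab$name[j]]][anc]
    out$p_D[j] <- pD; out$p_N[j] <- pN
    if (pN >= 1) { out$status[j] <- "undefined_excess"; next }
    d <- p_excess(pD, pN)
    out$delta[j] <- d
    if (d <= 0) { out$status[j] <- "undefined_excess"; next }
    if (out$theta[j] <= 0) { out$status[j] <- "unstable_close_marker"; next }
    out$g_raw[j] <- age_single_marker(d, out$theta[j])
    if (out$dist_cm[j] < min_cm) out$status[j] <- "unstable_close_marker"
    if (!is.null(r) && out$g_raw[j] == 0) {
      # delta = 1: no decay observed, so no genealogy-shape bias to remove
      out$delta_correction[j] <- 0
      out$g_corrected[j] <- 0
    } else if (!is.null(r) && out$g_raw[j] > 0) {
      if (correction == "table") {
        dv <- if (is.null(names(delta_table))) delta_table[1] else
          delta_table[tab$name[j]]
        if (is.null(dv) || is.na(dv)) {
          stop("no table correction for marker ", tab$name[j])
        }
        corr <- labuda_correction(out$g_raw[j], out$theta[j], r,
                                  mode = "table", delta = dv)
      } else {
        corr <- labuda_correction(out$g_raw[j], out$theta[j], r,
                                  mode = "montecarlo", p_anc = pN,
                                  n_cases = n_cases, n_sims = n_sims,
                                  seed = seed)
      }
      out$delta_correction[j] <- corr$delta
      out$g_corrected[j] <- corr$g_corrected
    }
  }
  out
}

#' Median summary of single-marker estimates
#'
#' The single-marker results are summarised by the median across the
#' markers with a defined, stable estimate; undefined and unstable
#' markers are excluded and counted.
#'
#' @param estimates Result of [single_marker_ages()], or a numeric vector
#'   of raw estimates.
#' @return A list: `median_raw`, `median_corrected` (NA when no corrected
#'   values), `n_used`, `n_excluded`.
#' @export
summarize_markers <- function(estimates) {
  if (is.numeric(estimates)) {
    estimates <- data.frame(g_raw = estimates,
                            g_corrected = NA_real_,
                            status = ifelse(is.na(estimates),
                                            "undefined_excess", "ok"))
  }
  ok <- estimates$status == "ok" & !is.na(estimates$g_raw)
  if (!any(ok)) stop("no marker yields a usable single-marker estimate")
  corr <- estimates$g_corrected[ok]
  list(median_raw = stats::median(estimates$g_raw[ok]),
       median_corrected = if (all(is.na(corr))) NA_real_ else
         stats::median(corr, na.rm = TRUE),
       n_used = sum(ok), n_excluded = sum(!ok))
}
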