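# Haplotype handling: an enumeration-based EM phaser (a stand-in for
# full coalescent-informed phasing such as PHASE), per-carrier
# distributions over possible mutation-bearing haplotypes, ancestral
# haplotype inference, and allele-frequency estimation.
#
# Haplotypes are represented throughout as comma-joined allele labels in
# map order ("A,12,G"), so multi-character STR labels are unambiguous.

#' Join / split haplotype allele vectors
#' @param alleles Character vector of allele labels in map order.
#' @return `hap_string`: a single string; `hap_alleles`: the vector.
#' @export
hap_string <- function(alleles) paste(alleles, collapse = ",")

#' @rdname hap_string
#' @param hap A haplotype string.
#' @export
hap_alleles <- function(hap) strsplit(hap, ",", fixed = TRUE)[[1]]

.parse_geno <- function(entry) strsplit(entry, "/", fixed = TRUE)

# Enumerate the compatible (unordered) haplotype pairs of one unphased
# genotype row. With h heterozygous markers there are 2^(h-1) pairs.
.enumerate_pairs <- function(a, b) {
  het <- which(a != b)
  h <- length(het)
  if (h == 0) {
    return(list(h1 = hap_string(a), h2 = hap_string(b)))
  }
  n_cfg <- 2L^(h - 1L)
  h1 <- character(n_cfg); h2 <- character(n_cfg)
  for (k in seq_len(n_cfg)) {
    # bits of k-1 choose the parental origin at each het marker after the
    # first (the first is pinned to remove the mirror-image duplicate)
    bits <- as.integer(intToBits(k - 1L))[seq_len(max(h - 1L, 1L))]
    swap <- c(FALSE, as.logical(bits[seq_len(h - 1L)]))
    x <- a; y <- b
    x[het[swap]] <- b[het[swap]]
    y[het[swap]] <- a[het[swap]]
    h1[k] <- hap_string(x); h2[k] <- hap_string(y)
  }
  list(h1 = h1, h2 = h2)
}

#' Estimate haplotype frequencies and per-individual phasings by EM
#'
#' Standard expectation-maximisation over the compatible haplotype pairs
#' of each unphased genotype (gene-counting); per-individual pair
#' probabilities are proportional to the products of the haplotype
#' frequencies (times 2 for heterozygous pairs). Enumeration-based, so
#' the marker window must be small.
#'
#' @param genotypes Character matrix, one row per individual, one column
#'   per marker, entries "a/b" (unordered).
#' @param max_iter Iteration cap (default 500).
#' @param tol Convergence: maximum absolute frequency change (default 1e-8).
#' @return A list: `frequencies` (named haplotype frequency vector),
#'   `phase` (per individual, a data.frame with `hap1`, `hap2`,
#'   `probability`), `loglik` (trace; non-decreasing), `converged`.
#' @export
em_haplotype_frequencies <- function(genotypes, max_iter = 500, tol = 1e-8) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 1)
  if (ncol(genotypes) > 12) {
    stop("window of ", ncol(genotypes), " markers is too large for ",
         "enumeration-based phasing; phase in windows of <= 12 markers")
  }
  n <- nrow(genotypes)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ab <- .parse_geno(genotypes[i, ])
    bad <- which(lengths(ab) != 2)
    if (length(bad)) {
      stop("malformed genotype for individual ", i, " at marker column ",
           bad[1], ": '", genotypes[i, bad[1]], "'")
    }
    a <- vapply(ab, `[`, "", 1)
    b <- vapply(ab, `[`, "", 2)
    pairs[[i]] <- .enumerate_pairs(a, b)
  }
  haps <- unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2))))
  H <- length(haps)
  i1 <- lapply(pairs, function(p) match(p$h1, haps))
  i2 <- lapply(pairs, function(p) match(p$h2, haps))
  cc <- lapply(pairs, function(p) ifelse(p$h1 == p$h2, 1, 2))

  f <- rep(1 / H, H)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      w <- cc[[i]] * f[i1[[i]]] * f[i2[[i]]]
      s <- sum(w)
      if (s <= 0) stop("individual ", i, " has zero likelihood under EM")
      ll <- ll + log(s)
      w <- w / s
      # expected chromosome counts
      tab1 <- tapply(w, i1[[i]], sum)
      tab2 <- tapply(w, i2[[i]], sum)
      counts[as.integer(names(tab1))] <- counts[as.integer(names(tab1))] + tab1
      counts[as.integer(names(tab2))] <- counts[as.integer(names(tab2))] + tab2
    }
    loglik <- c(loglik, ll)
    if (iter > 1 && loglik[iter] < loglik[iter - 1] - 1e-9) {
      stop("EM log-likelihood decreased; this is a bug")
    }
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }

  phase <- vector("list", n)
  names(phase) <- rownames(genotypes)
  for (i in seq_len(n)) {
    w <- cc[[i]] * f[i1[[i]]] * f[i2[[i]]]
    w <- w / sum(w)
    phase[[i]] <- data.frame(hap1 = pairs[[i]]$h1, hap2 = pairs[[i]]$h2,
                             probability = w, stringsAsFactors = FALSE)
  }
  list(frequencies = stats::setNames(f, haps), phase = phase,
       loglik = loglik, converged = converged)
}

#' Distribution over a carrier's possible mutation-bearing haplotypes
#'
#' Given an individual's phase distribution and, per configuration, which
#' of the two haplotypes bears the disease mutation, collects the
#' mutation-bearing haplotype of each configuration with the
#' configuration's probability; duplicates are merged, entries below the
#' pruning threshold dropped, and the result renormalised.
#'
#' @param phase A data.frame with `hap1`, `hap2`, `probability`.
#' @param carrier Integer vector (1 or 2) per row: which haplotype of the
#'   pair carries the mutation. Required.
#' @param prune Drop entries below this probability after merging
#'   (default 1e-6).
#' @return A `hap_distribution`: data.frame with `haplotype`,
#'   `probability` (summing to 1).
#' @export
carrier_haplotype_distribution <- function(phase, carrier, prune = 1e-6) {
  if (missing(carrier) || is.null(carrier)) {
    stop("carrier designation is required: which haplotype of each pair ",
         "bears the mutation")
  }
  stopifnot(all(carrier %in% c(1L, 2L)), length(carrier) == nrow(phase))
  hap <- ifelse(carrier == 1L, phase$hap1, phase$hap2)
  p <- tapply(phase$probability, hap, sum)
  out <- data.frame(haplotype = names(p), probability = as.numeric(p),
                    stringsAsFactors = FALSE)
  out <- out[out$probability >= prune, , drop = FALSE]
  out$probability <- out$probability / sum(out$probability)
  out <- out[order(-out$probability), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hap_distribution", "data.frame")
  out
}

#' Degenerate distributions from fully phased carrier chromosomes
#'
#' @param case_haps Character matrix of phased carrier haplotypes (rows:
#'   chromosomes, columns: markers in map order).
#' @return A named list of single-entry `hap_distribution`s.
#' @export
carrier_distributions_from_phased <- function(case_haps) {
  out <- lapply(seq_len(nrow(case_haps)), function(i) {
    d <- data.frame(haplotype = hap_string(case_haps[i, ]), probability = 1,
                    stringsAsFactors = FALSE)
    class(d) <- c("hap_distribution", "data.frame")
    d
  })
  names(out) <- rownames(case_haps)
  out
}

#' Phase carrier genotypes with the mutation site as an anchor
#'
#' Phases cases (and, by default, controls jointly) by EM over the marker
#' window plus one pseudo-marker at the disease locus at which carriers
#' are heterozygous M/+ and controls homozygous +/+. Each phased pair
#' then has exactly one M-bearing haplotype, which identifies the
#' mutation-carrying chromosome; the anchor column is stripped from the
#' returned haplotypes. Joint phasing of cases and controls assumes both
#' draw from a common haplotype pool; this is the default and is flagged
#' here because it is an assumption, not a fact of the data.
#'
#' @param case_genotypes Character matrix of carrier genotypes ("a/b").
#' @param map The `marker_map` (provides the anchor position).
#' @param control_genotypes Optional control genotypes phased jointly.
#' @param prune Pruning threshold for [carrier_haplotype_distribution()].
#' @param ... Passed to [em_haplotype_frequencies()].
#' @return Named list of `hap_distribution`s, one per carrier.
#' @export
phase_carriers <- function(case_genotypes, map, control_genotypes = NULL,
                           prune = 1e-6, ...) {
  n_prox <- sum(map$table$side == "proximal")
  add_anchor <- function(g, geno) {
    cbind(g[, seq_len(n_prox), drop = FALSE],
          anchor__ = rep(geno, nrow(g)),
          g[, -seq_len(n_prox), drop = FALSE])
  }
  cases <- add_anchor(case_genotypes, "M/+")
  all_g <- if (is.null(control_genotypes)) cases else {
    rbind(cases, add_anchor(control_genotypes, "+/+"))
  }
  em <- em_haplotype_frequencies(all_g, ...)
  anchor_col <- n_prox + 1L
  out <- vector("list", nrow(case_genotypes))
  names(out) <- rownames(case_genotypes)
  for (i in seq_len(nrow(case_genotypes))) {
    ph <- em$phase[[i]]
    has_m1 <- vapply(ph$hap1,
                     function(h) hap_alleles(h)[anchor_col] == "M", TRUE)
    carrier <- ifelse(has_m1, 1L, 2L)
    strip <- function(h) {
      a <- hap_alleles(h)
      hap_string(a[-anchor_col])
    }
    ph$hap1 <- vapply(ph$hap1, strip, "")
    ph$hap2 <- vapply(ph$hap2, strip, "")
    out[[i]] <- carrier_haplotype_distribution(ph, carrier, prune)
  }
  out
}

#' Estimate allele frequencies in controls and (weighted) in carriers
#'
#' Control frequencies p_N are estimated by direct allele counting in the
#' control chromosomes; carrier frequencies p_D by probability-weighted
#' counting over each carrier's haplotype distribution.
#'
#' @param control_haps Character matrix of control chromosomes.
#' @param map The `marker_map`.
#' @param distributions Optional list of `hap_distribution`s (for p_D).
#' @param pseudocount Added per allele to the control counts (default 0;
#'   a small value guards zero frequencies for alleles seen only in
#'   carriers).
#' @return An `allele_frequencies` object: lists `p_N` and `p_D`, each a
#'   per-marker named vector over the map's alleles.
#' @export
allele_frequencies <- function(control_haps, map, distributions = NULL,
                               pseudocount = 0) {
  if (is.null(control_haps) || nrow(control_haps) == 0) {
    stop("allele frequencies need at least one control chromosome")
  }
  mnames <- map$table$name
  p_N <- vector("list", length(mnames)); names(p_N) <- mnames
  for (j in seq_along(mnames)) {
    a <- map$alleles[[mnames[j]]]
    cnt <- table(factor(control_haps[, j], levels = a)) + pseudocount
    p_N[[j]] <- stats::setNames(as.numeric(cnt / sum(cnt)), a)
  }
  p_D <- NULL
  if (!is.null(distributions)) {
    p_D <- lapply(seq_along(mnames), function(j) {
      a <- map$alleles[[mnames[j]]]
      stats::setNames(numeric(length(a)), a)
    })
    names(p_D) <- mnames
    for (d in distributions) {
      for (k in seq_len(nrow(d))) {
        al <- hap_alleles(d$haplotype[k])
        for (j in seq_along(mnames)) {
          p_D[[j]][al[j]] <- p_D[[j]][al[j]] + d$probability[k]
        }
      }
    }
    nd <- length(distributions)
    p_D <- lapply(p_D, function(v) v / nd)
  }
  structure(list(p_N = p_N, p_D = p_D,
                 n_controls = nrow(control_haps),
                 n_carriers = length(distributions)),
            class = "allele_frequencies")
}

#' Infer the ancestral (mutation-associated) haplotype
#'
#' Per marker, the allele with the highest probability-weighted count
#' across the carriers' haplotype distributions; its weighted share is
#' reported as the support. Ties prefer the allele most enriched in
#' carriers relative to controls (largest p_D/p_N), then the
#' lexicographically smallest label.
#'
#' @param distributions List of `hap_distribution`s (>= 1 carrier).
#' @param map The `marker_map`.
#' @param freqs Optional `allele_frequencies` for the enrichment
#'   tie-break.
#' @return An `ancestral_haplotype`: list with `alleles` and `support`,
#'   both named by marker.
#' @export
infer_ancestral_haplotype <- function(distributions, map, freqs = NULL) {
  stopifnot(length(distributions) >= 1)
  mnames <- map$table$name
  counts <- lapply(seq_along(mnames), function(j) {
    a <- map$alleles[[mnames[j]]]
    stats::setNames(numeric(length(a)), a)
  })
  names(counts) <- mnames
  for (d in distributions) {
    for (k in seq_len(nrow(d))) {
      al <- hap_alleles(d$haplotype[k])
      for (j in seq_along(mnames)) {
        counts[[j]][al[j]] <- counts[[j]][al[j]] + d$probability[k]
      }
    }
  }
  nd <- length(distributions)
  alleles <- character(length(mnames)); support <- numeric(length(mnames))
  for (j in seq_along(mnames)) {
    v <- counts[[j]]
    top <- names(v)[v == max(v)]
    if (length(top) > 1 && !is.null(freqs)) {
      pn <- freqs$p_N[[mnames[j]]][top]
      ratio <- (v[top] / nd) / pmax(pn, .Machine$double.eps)
      top <- top[ratio == max(ratio)]
    }
    alleles[j] <- sort(top)[1]
    support[j] <- v[alleles[j]] / nd
  }
  structure(list(alleles = stats::setNames(alleles, mnames),
                 support = stats::setNames(support, mnames)),
            class = "ancestral_haplotype")
}

#' Read per-individual phase distributions from the native TSV format
#'
#' Columns: `sample_id`, `hap1`, `hap2`, `probability`; haplotypes are
#' comma-joined allele labels in map order. Rows with the same sample_id
#' form that individual's distribution.
#'
#' @param path Path to the TSV file.
#' @return Named list of phase data.frames (`hap1`, `hap2`,
#'   `probability`), probabilities renormalised per individual.
#' @export
read_phase_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("sample_id", "hap1", "hap2", "probability")
  if (!all(req %in% names(df))) {
    stop("phase TSV must have columns: ", paste(req, collapse = ", "))
  }
  df$probability <- as.numeric(df$probability)
  out <- split(df[c("hap1", "hap2", "probability")], df$sample_id)
  lapply(out, function(d) {
    d$probability <- d$probability / sum(d$probability)
    rownames(d) <- NULL
    d
  })
}

#' Read a PHASE v2 style pairs listing
#'
#' Parses the pairs-output dialect: blocks introduced by `IND: <id>`
#' followed by lines `<hap1> , <hap2> , <probability>`, haplotype alleles
#' separated by whitespace. `BEGIN BESTPAIRS`/`END BESTPAIRS` wrappers
#' are tolerated and ignored.
#'
#' @param path Path to the pairs file.
#' @return Named list of phase data.frames as in [read_phase_tsv()].
#' @export
read_phase_pairs <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  rows <- NULL
  flush <- function(out, cur, rows) {
    if (!is.null(cur)) {
      if (is.null(rows)) stop("no haplotype pairs for individual ", cur)
      rows$probability <- rows$probability / sum(rows$probability)
      out[[cur]] <- rows
    }
    out
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^(BEGIN|END)", ln)) next
    if (grepl("^IND:", ln)) {
      out <- flush(out, cur, rows)
      cur <- trimws(sub("^IND:", "", ln))
      rows <- NULL
      next
    }
    parts <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    if (length(parts) != 3) {
      stop("parse error in phase pairs file line ", k, ": '", lines[k], "'")
    }
    tok <- function(s) hap_string(strsplit(s, "[[:space:]]+")[[1]])
    rows <- rbind(rows, data.frame(hap1 = tok(parts[1]), hap2 = tok(parts[2]),
                                   probability = as.numeric(parts[3]),
                                   stringsAsFactors = FALSE))
  }
  flush(out, cur, rows)
}
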