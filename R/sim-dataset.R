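# Forward-in-time generator of founder-mutation case haplotypes with known
# truth. A founder chromosome is drawn from a background pool; each meiosis
# applies, per marker interval (including the locus flank), recombination
# with probability theta_interval, switching the remainder of the
# chromosome (outward) to a fresh pool draw, and per-marker mutation (SNP:
# switch allele; STR: +/-1 repeat step, reflecting at the allele-range
# bounds). Recombination therefore erodes the ancestral segment from the
# outside in, leaving a contiguous ancestral core containing the locus --
# the mosaic structure the LD-decay estimators assume.

#' Construct a simulation configuration
#'
#' @param g_true True mutation age in generations (integer >= 0).
#' @param r Growth rate per generation (> 0); mean offspring per copy in
#'   branching mode.
#' @param n_cases Carrier chromosomes to sample.
#' @param n_controls Control chromosomes to draw from the pool.
#' @param marker_map A [build_marker_map()] object.
#' @param pool A background pool: list with `haps` (character matrix, one
#'   row per haplotype, columns in map order) and `freqs` (summing to 1).
#' @param genealogy "star" (n_cases independent lineages of depth g_true;
#'   the estimators' null model) or "branching" (Galton-Watson).
#' @param condition "survival" (>= 1 copy at present; sampling then fails
#'   if fewer than n_cases copies survive) or "n_cases" (resample until at
#'   least n_cases copies survive).
#' @param emit_genotypes If TRUE, also emit unphased case genotypes by
#'   pairing each carrier chromosome with a fresh pool draw.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return A classed `sim_config` list.
#' @export
sim_config <- function(g_true, r, n_cases, n_controls, marker_map, pool,
                       genealogy = c("star", "branching"),
                       condition = c("survival", "n_cases"),
                       emit_genotypes = FALSE, seed = 1) {
  genealogy <- match.arg(genealogy)
  condition <- match.arg(condition)
  stopifnot(inherits(marker_map, "marker_map"),
            g_true >= 0, r > 0, n_cases >= 1, n_controls >= 0)
  if (!is.matrix(pool$haps) || is.null(pool$freqs)) {
    stop("pool must be a list with a haplotype matrix `haps` and `freqs`")
  }
  if (abs(sum(pool$freqs) - 1) > 1e-9) stop("pool frequencies must sum to 1")
  if (ncol(pool$haps) != nrow(marker_map$table)) {
    stop("pool haplotypes must have one column per map marker")
  }
  structure(list(g_true = as.integer(g_true), r = r,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 marker_map = marker_map, pool = pool,
                 genealogy = genealogy, condition = condition,
                 emit_genotypes = emit_genotypes, seed = as.integer(seed)),
            class = "sim_config")
}

# map allele labels <-> integer indices, column-wise
.haps_to_idx <- function(haps, map) {
  idx <- matrix(0L, nrow(haps), ncol(haps))
  for (j in seq_len(ncol(haps))) {
    a <- map$alleles[[map$table$name[j]]]
    v <- match(haps[, j], a)
    if (anyNA(v)) {
      stop("allele label not in map for marker ", map$table$name[j], ": ",
           paste(unique(haps[is.na(v), j]), collapse = ", "))
    }
    idx[, j] <- v
  }
  idx
}

.idx_to_haps <- function(idx, map) {
  out <- matrix("", nrow(idx), ncol(idx))
  colnames(out) <- map$table$name
  for (j in seq_len(ncol(idx))) {
    out[, j] <- map$alleles[[map$table$name[j]]][idx[, j]]
  }
  out
}

# One generation of meiosis applied to every row of H (allele-index
# matrix). Returns updated H, per-side ancestral coverage counts, and
# per-chromosome mutation-event counts.
.meiose <- function(H, covL, covR, mutc, map, pool_idx, pool_freqs) {
  nc <- nrow(H)
  if (nc == 0) return(list(H = H, covL = covL, covR = covR, mutc = mutc))
  n_pool <- nrow(pool_idx)
  draw_pool <- function(n) sample.int(n_pool, n, replace = TRUE,
                                      prob = pool_freqs)
  for (s in c("proximal", "distal")) {
    sidx <- side_indices(map, s)
    ks <- length(sidx)
    if (ks == 0) next
    th <- map$table$theta_interval[sidx]
    E <- matrix(stats::runif(nc * ks), nc, ks) < rep(th, each = nc)
    # ancestral coverage truncates at the innermost recombined interval
    fe <- rep.int(ks + 1L, nc)
    for (j in rev(seq_len(ks))) fe[E[, j]] <- j
    if (s == "proximal") covL <- pmin(covL, fe - 1L) else covR <- pmin(covR, fe - 1L)
    # each event switches the chromosome outward of it to a fresh pool draw;
    # applying events inward-to-outward makes outer events overwrite inner
    for (j in seq_len(ks)) {
      w <- which(E[, j])
      if (!length(w)) next
      d <- draw_pool(length(w))
      H[w, sidx[j:ks]] <- pool_idx[d, sidx[j:ks], drop = FALSE]
    }
  }
  # per-marker mutation
  mu <- map$table$mutation_rate
  m <- ncol(H)
  U <- matrix(stats::runif(nc * m), nc, m) < rep(mu, each = nc)
  for (j in which(colSums(U) > 0)) {
    w <- which(U[, j])
    K <- length(map$alleles[[map$table$name[j]]])
    cur <- H[w, j]
    if (map$table$type[j] %in% c("dinucleotide_str", "tetranucleotide_str")) {
      step <- sample(c(-1L, 1L), length(w), replace = TRUE)
      nv <- cur + step
      nv[nv < 1L] <- 2L       # reflect at the allele-range bounds
      nv[nv > K] <- K - 1L
    } else {
      nv <- ((cur - 1L + sample.int(K - 1L, length(w), replace = TRUE)) %% K) + 1L
    }
    H[w, j] <- nv
  }
  mutc <- mutc + rowSums(U)
  list(H = H, covL = covL, covR = covR, mutc = mutc)
}

#' Simulate a case-control founder-mutation dataset with known truth
#'
#' Runs the forward process described in the package overview: founder
#' draw, `g_true` generations of meiosis with recombination against the
#' background pool and per-marker mutation, sampling of carrier
#' chromosomes (star or Galton-Watson genealogy) and of an independent
#' control pool.
#'
#' @param config A [sim_config()].
#' @param max_pop Population cap for branching mode.
#' @param max_attempts Resampling cap when conditioning.
#' @return A list with `dataset` (class `cc_dataset`: `case_haps`,
#'   `control_haps`, optional `case_genotypes`, `map`) and `truth`
#'   (class `sim_truth`: true age, growth rate, ancestral haplotype,
#'   copy-count trajectory, per-case ancestral coverage and mutation
#'   counts).
#' @export
simulate_dataset <- function(config, max_pop = 1e6, max_attempts = 10000) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- config$marker_map
  m <- nrow(map$table)
  pool_idx <- .haps_to_idx(config$pool$haps, map)
  pool_freqs <- config$pool$freqs
  g <- config$g_true

  founder <- sample.int(nrow(pool_idx), 1, prob = pool_freqs)
  anc <- pool_idx[founder, ]
  kL <- sum(map$table$side == "proximal")
  kR <- sum(map$table$side == "distal")

  if (config$genealogy == "star") {
    n <- config$n_cases
    H <- matrix(anc, n, m, byrow = TRUE)
    covL <- rep.int(kL, n); covR <- rep.int(kR, n); mutc <- numeric(n)
    for (t in seq_len(g)) {
      st <- .meiose(H, covL, covR, mutc, map, pool_idx, pool_freqs)
      H <- st$H; covL <- st$covL; covR <- st$covR; mutc <- st$mutc
    }
    traj <- c(1L, rep.int(n, g))[seq_len(g + 1)]
    case_idx <- seq_len(n)
  } else {
    min_copies <- if (config$condition == "n_cases") config$n_cases else 1L
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      H <- matrix(anc, 1, m)
      covL <- kL; covR <- kR; mutc <- 0
      traj <- integer(g + 1); traj[1] <- 1L
      n <- 1L
      for (t in seq_len(g)) {
        off <- stats::rpois(n, config$r)
        n_new <- sum(off)
        if (n_new > max_pop) {
          stop("population exceeded max_pop = ", max_pop,
               " at generation ", t)
        }
        if (n_new == 0L) { n <- 0L; traj[t + 1] <- 0L; break }
        parent <- rep.int(seq_len(n), off)
        H <- H[parent, , drop = FALSE]
        covL <- covL[parent]; covR <- covR[parent]; mutc <- mutc[parent]
        st <- .meiose(H, covL, covR, mutc, map, pool_idx, pool_freqs)
        H <- st$H; covL <- st$covL; covR <- st$covR; mutc <- st$mutc
        n <- n_new
        traj[t + 1] <- n
      }
      if (n >= min_copies) { done <- TRUE; break }
    }
    if (!done) {
      stop("simulation failed: no run reached ", min_copies,
           " surviving copies within max_attempts = ", max_attempts)
    }
    if (n < config$n_cases) {
      stop("simulation failure: only ", n, " surviving copies but n_cases = ",
           config$n_cases, " requested (condition = 'survival')")
    }
    case_idx <- sample.int(n, config$n_cases)
  }

  case_haps <- .idx_to_haps(H[case_idx, , drop = FALSE], map)
  rownames(case_haps) <- sprintf("case_%03d", seq_len(nrow(case_haps)))
  ctrl_idx <- sample.int(nrow(pool_idx), config$n_controls, replace = TRUE,
                         prob = pool_freqs)
  control_haps <- .idx_to_haps(pool_idx[ctrl_idx, , drop = FALSE], map)
  if (nrow(control_haps)) {
    rownames(control_haps) <- sprintf("ctrl_%03d", seq_len(nrow(control_haps)))
  }

  dataset <- structure(list(case_haps = case_haps,
                            control_haps = control_haps,
                            case_genotypes = NULL,
                            map = map), class = "cc_dataset")
  if (config$emit_genotypes) {
    mate_idx <- sample.int(nrow(pool_idx), nrow(case_haps), replace = TRUE,
                           prob = pool_freqs)
    mates <- .idx_to_haps(pool_idx[mate_idx, , drop = FALSE], map)
    genos <- matrix("", nrow(case_haps), m, dimnames = dimnames(case_haps))
    flip <- stats::runif(nrow(case_haps)) < 0.5
    for (j in seq_len(m)) {
      a <- ifelse(flip, mates[, j], case_haps[, j])
      b <- ifelse(flip, case_haps[, j], mates[, j])
      genos[, j] <- paste(a, b, sep = "/")
    }
    dataset$case_genotypes <- genos
  }

  truth <- structure(list(
    g_true = g, r = config$r, genealogy = config$genealogy,
    seed = config$seed,
    ancestral_haplotype = stats::setNames(
      .idx_to_haps(matrix(anc, 1), map)[1, ], map$table$name),
    trajectory = traj,
    case_coverage = data.frame(
      sample_id = rownames(case_haps),
      cov_proximal = covL[case_idx], cov_distal = covR[case_idx],
      n_mutations = mutc[case_idx], stringsAsFactors = FALSE),
    n_surviving = utils::tail(traj, 1)
  ), class = "sim_truth")

  list(dataset = dataset, truth = truth)
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat("cc_dataset:", nrow(x$case_haps), "carrier chromosomes,",
      nrow(x$control_haps), "control chromosomes,",
      nrow(x$map$table), "markers\n")
  invisible(x)
}

#' Write a simulated dataset (and optionally its truth) to plain text
#'
#' Haplotypes go to `haplotypes.tsv` (columns sample_id, chrom_index,
#' carrier_flag, then one column per marker), the map to `map.tsv`,
#' map-level configuration to `dataset.json`, genotypes (if present) to
#' `genotypes.tsv` with unphased "a/b" pairs, and the truth record to
#' `truth.json`.
#'
#' @param dataset A `cc_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `sim_truth` sidecar.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- dataset$map
  hap_tab <- function(haps, flag) {
    data.frame(sample_id = rownames(haps),
               chrom_index = 1L, carrier_flag = flag,
               as.data.frame(haps, stringsAsFactors = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  tab <- rbind(hap_tab(dataset$case_haps, 1L),
               if (nrow(dataset$control_haps)) hap_tab(dataset$control_haps, 0L))
  utils::write.table(tab, file.path(dir, "haplotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_marker_map(map, file.path(dir, "map.tsv"))
  jsonlite::write_json(list(disease_locus_bp = map$disease_locus_bp,
                            cm_per_mb = map$cm_per_mb,
                            map_function = map$map_function),
                       file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$case_genotypes)) {
    gt <- data.frame(sample_id = rownames(dataset$case_genotypes),
                     as.data.frame(dataset$case_genotypes,
                                   stringsAsFactors = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `haplotypes.tsv`, `map.tsv` and
#'   `dataset.json`; `genotypes.tsv` and `truth.json` are optional.
#' @return A list with `dataset` (class `cc_dataset`) and `truth` (a
#'   `sim_truth`, or NULL when no truth file is present).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  map <- read_marker_map(file.path(dir, "map.tsv"), meta$disease_locus_bp,
                         meta$cm_per_mb, meta$map_function)
  tab <- utils::read.delim(file.path(dir, "haplotypes.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  marker_cols <- map$table$name
  missing_cols <- setdiff(marker_cols, names(tab))
  if (length(missing_cols)) {
    stop("haplotypes.tsv is missing marker column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  hm <- as.matrix(tab[, marker_cols, drop = FALSE])
  # validate allele labels against the map (reported with the data row,
  # +1 for the header line)
  for (j in seq_along(marker_cols)) {
    ok <- hm[, j] %in% map$alleles[[marker_cols[j]]]
    if (!all(ok)) {
      stop("parse error in haplotypes.tsv line ", which(!ok)[1] + 1L,
           ": allele '", hm[!ok, j][1], "' not in map for marker ",
           marker_cols[j])
    }
  }
  carrier <- as.integer(tab$carrier_flag) == 1L
  case_haps <- hm[carrier, , drop = FALSE]
  rownames(case_haps) <- tab$sample_id[carrier]
  control_haps <- hm[!carrier, , drop = FALSE]
  rownames(control_haps) <- tab$sample_id[!carrier]
  dataset <- structure(list(case_haps = case_haps,
                            control_haps = control_haps,
                            case_genotypes = NULL, map = map),
                       class = "cc_dataset")
  gt_path <- file.path(dir, "genotypes.tsv")
  if (file.exists(gt_path)) {
    gt <- utils::read.delim(gt_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    gm <- as.matrix(gt[, marker_cols, drop = FALSE])
    rownames(gm) <- gt$sample_id
    dataset$case_genotypes <- gm
  }
  truth <- NULL
  tr_path <- file.path(dir, "truth.json")
  if (file.exists(tr_path)) {
    truth <- jsonlite::read_json(tr_path, simplifyVector = TRUE)
    truth$ancestral_haplotype <- stats::setNames(
      as.character(truth$ancestral_haplotype), map$table$name)
    class(truth) <- "sim_truth"
  }
  list(dataset = dataset, truth = truth)
}
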