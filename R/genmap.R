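#' Convert physical distance to genetic distance
#'
#' Converts a physical distance in base pairs to a genetic distance in
#' centiMorgans under a constant recombination rate, by default 1 cM/Mb
#' (the usual genome-wide average used when no empirical map is available).
#'
#' @param distance_bp Physical distance in base pairs (non-negative).
#' @param cm_per_mb Recombination rate in cM per Mb (positive).
#' @return Genetic distance in centiMorgans.
#' @export
#' @examples
#' cm_from_physical(1e6)        # 1 cM
#' cm_from_physical(12.3e6)     # 12.3 cM across a 12.3 Mb region
cm_from_physical <- function(distance_bp, cm_per_mb = 1) {
  if (any(distance_bp < 0)) stop("distance_bp must be non-negative")
  if (any(cm_per_mb <= 0)) stop("cm_per_mb must be positive")
  distance_bp * cm_per_mb / 1e6
}

#' Convert genetic distance to a recombination fraction
#'
#' Maps genetic distance (cM) to a per-meiosis recombination fraction
#' theta. The default is the Haldane map function
#' theta = (1 - exp(-2 d)) / 2 with d in Morgans, which assumes no
#' crossover interference; a linear no-map approximation
#' theta = d (capped at 0.5) is also available. At the sub-Morgan
#' distances typical of founder-mutation maps the two nearly coincide.
#'
#' @param d_cm Genetic distance in centiMorgans (non-negative).
#' @param map_function "haldane" (default) or "linear".
#' @return Recombination fraction in [0, 0.5].
#' @export
#' @examples
#' theta_from_cm(1)   # 0.009901
theta_from_cm <- function(d_cm, map_function = c("haldane", "linear")) {
  if (any(d_cm < 0)) stop("genetic distance must be non-negative")
  map_function <- match.arg(map_function)
  d_m <- d_cm / 100
  switch(map_function,
    haldane = 0.5 * (1 - exp(-2 * d_m)),
    linear = pmin(d_m, 0.5)
  )
}

# Default per-generation marker mutation rates by marker type. The method
# allows type-specific rates (dinucleotide STRs mutate faster than
# tetranucleotide STRs, SNPs essentially never remutate on these time
# scales); these are standard order-of-magnitude defaults, overridable
# per marker.
.default_mutation_rates <- c(
  snp = 1e-8,
  dinucleotide_str = 5e-4,
  tetranucleotide_str = 2e-4,
  other = 1e-8
)

#' Build a marker map around a disease locus
#'
#' Constructs the map object used by all estimators: markers ordered by
#' position, partitioned into the proximal (left) and distal (right) side
#' of the disease locus, with per-marker recombination fractions to the
#' locus (`theta_locus`) and per-adjacent-interval fractions
#' (`theta_interval`, the innermost interval on each side running from the
#' locus to the nearest marker). The single-marker estimator uses
#' `theta_locus`; the outward-scanning multi-marker likelihood uses
#' `theta_interval`.
#'
#' @param markers A data.frame with columns `name`, `position_bp`, `type`
#'   (one of "snp", "dinucleotide_str", "tetranucleotide_str", "other"),
#'   `alleles` (list column of character vectors, or comma-joined strings),
#'   and optionally `mutation_rate` (per generation; NA means use the
#'   type default).
#' @param disease_locus_bp Position of the disease mutation in bp.
#' @param cm_per_mb Recombination rate, default 1 cM/Mb.
#' @param map_function Map function for [theta_from_cm()].
#' @return An object of class `marker_map`: a list with `table` (one row
#'   per marker, position-ordered), `alleles` (named list), and the map
#'   parameters.
#' @export
build_marker_map <- function(markers, disease_locus_bp, cm_per_mb = 1,
                             map_function = c("haldane", "linear")) {
  map_function <- match.arg(map_function)
  stopifnot(is.data.frame(markers), nrow(markers) >= 1)
  req <- c("name", "position_bp", "type", "alleles")
  if (!all(req %in% names(markers))) {
    stop("markers must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(markers$position_bp)) {
    stop("duplicate marker positions in map")
  }
  if (anyDuplicated(markers$name)) stop("duplicate marker names in map")
  bad <- setdiff(unique(markers$type), names(.default_mutation_rates))
  if (length(bad)) stop("unknown marker type(s): ", paste(bad, collapse = ", "))

  ord <- order(markers$position_bp)
  markers <- markers[ord, , drop = FALSE]

  alleles <- markers$alleles
  if (!is.list(alleles)) alleles <- strsplit(as.character(alleles), ",")
  alleles <- lapply(alleles, function(a) as.character(trimws(a)))
  names(alleles) <- markers$name
  n_all <- vapply(alleles, length, integer(1))
  if (any(n_all < 2)) {
    stop("every marker needs >= 2 alleles; offending: ",
         paste(markers$name[n_all < 2], collapse = ", "))
  }

  mu <- if ("mutation_rate" %in% names(markers)) {
    as.numeric(markers$mutation_rate)
  } else {
    rep(NA_real_, nrow(markers))
  }
  mu[is.na(mu)] <- .default_mutation_rates[markers$type[is.na(mu)]]

  dist_bp <- abs(markers$position_bp - disease_locus_bp)
  d_cm <- cm_from_physical(dist_bp, cm_per_mb)
  theta_locus <- theta_from_cm(d_cm, map_function)
  side <- ifelse(markers$position_bp < disease_locus_bp, "proximal", "distal")

  tab <- data.frame(
    name = as.character(markers$name),
    position_bp = as.integer(markers$position_bp),
    type = as.character(markers$type),
    mutation_rate = mu,
    side = side,
    dist_bp = dist_bp,
    dist_cm = d_cm,
    theta_locus = theta_locus,
    stringsAsFactors = FALSE
  )

  # interval theta: per side, outward from the locus
  tab$theta_interval <- NA_real_
  for (s in c("proximal", "distal")) {
    idx <- which(tab$side == s)
    if (!length(idx)) next
    idx <- idx[order(tab$dist_bp[idx])]  # outward order
    gaps_bp <- diff(c(0, tab$dist_bp[idx]))
    tab$theta_interval[idx] <- theta_from_cm(
      cm_from_physical(gaps_bp, cm_per_mb), map_function)
  }

  structure(
    list(
      table = tab,
      alleles = alleles,
      disease_locus_bp = as.integer(disease_locus_bp),
      cm_per_mb = cm_per_mb,
      map_function = map_function
    ),
    class = "marker_map"
  )
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", nrow(x$table), "markers around locus at",
      x$disease_locus_bp, "bp;", x$cm_per_mb, "cM/Mb,",
      x$map_function, "map function\n")
  cat("  proximal:", sum(x$table$side == "proximal"),
      " distal:", sum(x$table$side == "distal"), "\n")
  invisible(x)
}

#' Markers of a map in outward order on one side of the locus
#'
#' @param map A `marker_map`.
#' @param side "proximal" or "distal".
#' @return Integer row indices into `map$table`, ordered by increasing
#'   distance from the locus.
#' @export
side_indices <- function(map, side) {
  idx <- which(map$table$side == side)
  idx[order(map$table$dist_bp[idx])]
}

#' Read a marker map from a TSV file
#'
#' Expects a header row and columns `name`, `chrom`, `position_bp`, `type`,
#' `alleles` (comma-joined labels) and optionally `mutation_rate`. The
#' disease locus position is supplied separately (it is configuration, not
#' a marker).
#'
#' @inheritParams build_marker_map
#' @param path Path to the TSV file.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path, disease_locus_bp, cm_per_mb = 1,
                            map_function = c("haldane", "linear")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(alleles = "character"))
  req <- c("name", "chrom", "position_bp", "type", "alleles")
  if (!all(req %in% names(df))) {
    stop("marker map TSV must have columns: ", paste(req, collapse = ", "))
  }
  build_marker_map(df, disease_locus_bp, cm_per_mb, match.arg(map_function))
}

#' Write a marker map to TSV
#'
#' @param map A `marker_map`.
#' @param path Output path.
#' @param chrom Chromosome label to write (maps are single-region).
#' @export
write_marker_map <- function(map, path, chrom = "chr") {
  tab <- map$table
  out <- data.frame(
    name = tab$name, chrom = chrom, position_bp = tab$position_bp,
    type = tab$type,
    alleles = vapply(map$alleles[tab$name], paste, "", collapse = ","),
    mutation_rate = tab$mutation_rate,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
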