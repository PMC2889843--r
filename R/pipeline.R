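# Configuration-driven end-to-end runs: simulate (or load) -> phase (or
# pass through phased haplotypes) -> estimate by the enabled methods ->
# report, with a single seed making reruns bit-identical.

#' Generate a linkage-equilibrium background pool for simulations
#'
#' Draws `n_haps` equally weighted background haplotypes with independent
#' per-marker allele frequencies (symmetric Dirichlet). The pool carries
#' no background LD, matching the assumption of the estimators that
#' post-recombination alleles are independent draws at the population
#' frequency.
#'
#' @param map A `marker_map`.
#' @param n_haps Number of pool haplotypes (default 200).
#' @param concentration Dirichlet concentration for the per-marker allele
#'   frequencies (default 2, mildly regular frequencies).
#' @return A pool list (`haps`, `freqs`) for [sim_config()].
#' @export
make_background_pool <- function(map, n_haps = 200, concentration = 2) {
  m <- nrow(map$table)
  haps <- matrix("", n_haps, m)
  colnames(haps) <- map$table$name
  for (j in seq_len(m)) {
    a <- map$alleles[[map$table$name[j]]]
    w <- stats::rgamma(length(a), concentration)
    haps[, j] <- sample(a, n_haps, replace = TRUE, prob = w / sum(w))
  }
  list(haps = haps, freqs = rep(1 / n_haps, n_haps))
}

#' Width of a confidence or credible interval
#'
#' @param low,high Interval bounds, `high >= low`.
#' @return `high - low`, rounded to one decimal (the convention used for
#'   reporting interval widths).
#' @export
interval_width <- function(low, high) {
  if (any(high < low)) stop("high must be >= low")
  round(high - low, 1)
}

#' Run the full estimation pipeline
#'
#' Executes the enabled stages in order: obtain a dataset (simulate with
#' known truth, or load from disk), obtain per-carrier haplotype
#' distributions (phased chromosomes pass through; unphased genotypes are
#' phased by the anchor EM), estimate allele frequencies and the
#' ancestral haplotype, run the enabled estimators, and apply the growth
#' correction at each requested growth rate. One report row per enabled
#' method and growth rate.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{simulate}{a [sim_config()] (alternative to `input`)}
#'     \item{input}{a directory for [read_dataset()]}
#'     \item{methods}{subset of c("single_marker", "goldgar")}
#'     \item{growth_rates}{numeric vector (possibly empty) of r values}
#'     \item{correction}{list(mode = "montecarlo"/"table", delta =,
#'       n_sims =, n_cases =)}
#'     \item{grid}{c(g_min, g_max) for the likelihood search (default
#'       c(0, 500))}
#'     \item{use_genotypes}{force the phasing path when genotypes are
#'       present (default: phased haplotypes are used when available)}
#'     \item{seed}{integer master seed}
#'   }
#' @param out_dir Optional output directory; when given, the report
#'   (TSV + JSON), the per-marker single-marker table, the per-age
#'   log-likelihood curve and the run settings are written there.
#' @return A list: `report` (data.frame), `single_marker` (per-marker
#'   table), `goldgar` (raw `age_estimate` or NULL), `dataset`, `truth`,
#'   `ancestral`, `freqs`, `log` (character vector of stage notes).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  methods <- config$methods
  if (is.null(methods)) methods <- c("single_marker", "goldgar")
  if (!length(methods)) stop("at least one method must be enabled")
  stopifnot(all(methods %in% c("single_marker", "goldgar")))
  growth_rates <- config$growth_rates
  if (is.null(growth_rates)) growth_rates <- numeric(0)
  if (length(growth_rates) && any(growth_rates <= 1)) {
    stop("growth rates must exceed 1 when a correction is requested")
  }
  grid <- if (is.null(config$grid)) c(0, 500) else config$grid
  corr_cfg <- config$correction
  if (is.null(corr_cfg)) corr_cfg <- list(mode = "montecarlo")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  # --- data stage -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    dataset <- sim$dataset; truth <- sim$truth
    note("simulated dataset: g_true = ", truth$g_true, ", genealogy = ",
         truth$genealogy, ", seed = ", config$simulate$seed)
  } else if (!is.null(config$input)) {
    loaded <- read_dataset(config$input)
    dataset <- loaded$dataset; truth <- loaded$truth
    note("loaded dataset from ", config$input)
  } else {
    stop("config needs either a `simulate` block or an `input` directory")
  }
  map <- dataset$map

  # --- phasing stage --------------------------------------------------
  use_geno <- isTRUE(config$use_genotypes)
  if (!is.null(dataset$case_haps) && nrow(dataset$case_haps) && !use_geno) {
    distributions <- carrier_distributions_from_phased(dataset$case_haps)
    note("phased carrier chromosomes supplied; phasing stage skipped")
  } else if (!is.null(dataset$case_genotypes)) {
    distributions <- phase_carriers(dataset$case_genotypes, map)
    note("carrier genotypes phased by anchor EM (cases only)")
  } else {
    stop("dataset has neither phased carrier haplotypes nor genotypes")
  }

  # --- frequencies and ancestral haplotype ----------------------------
  freqs <- allele_frequencies(dataset$control_haps, map, distributions,
                              pseudocount = config$pseudocount %||% 0)
  ancestral <- infer_ancestral_haplotype(distributions, map, freqs)

  # --- estimators -----------------------------------------------------
  sm_tables <- list()
  goldgar_est <- NULL
  report <- NULL
  rates <- if (length(growth_rates)) growth_rates else NA_real_
  rate_key <- function(r) if (is.na(r)) "uncorrected" else as.character(r)

  if ("single_marker" %in% methods || "goldgar" %in% methods) {
    for (r in rates) {
      sm <- single_marker_ages(
        freqs, ancestral, map,
        r = if (is.na(r)) NULL else r,
        correction = corr_cfg$mode %||% "montecarlo",
        delta_table = corr_cfg$delta,
        seed = seed,
        n_sims = corr_cfg$n_sims %||% 1000,
        n_cases = corr_cfg$n_cases %||% 100)
      sm_tables[[rate_key(r)]] <- sm
    }
    n_excl <- sum(sm_tables[[1]]$status != "ok")
    note("single-marker estimates: ", nrow(sm_tables[[1]]), " markers, ",
         n_excl, " excluded (undefined or unstable)")
  }

  if ("single_marker" %in% methods) {
    for (r in rates) {
      sm <- sm_tables[[rate_key(r)]]
      s <- summarize_markers(sm)
      report <- rbind(report, data.frame(
        method = "single_marker", n_markers = s$n_used, growth_rate = r,
        estimate_raw = s$median_raw, delta = NA_real_,
        estimate_corrected = s$median_corrected,
        ci_low = NA_real_, ci_high = NA_real_, ci_width = NA_real_,
        flags = if (s$n_excluded) paste0(s$n_excluded, "_markers_excluded")
                else "", stringsAsFactors = FALSE))
    }
  }

  if ("goldgar" %in% methods) {
    model <- goldgar_model(map, ancestral, freqs,
                           pi_recurrence = config$pi_recurrence %||% 0)
    goldgar_est <- mle_age(distributions, model, grid[1], grid[2],
                           ci_cutoff = config$ci_cutoff %||% 1.92)
    note("goldgar MLE: g_hat = ", goldgar_est$g_hat, ", CI [",
         goldgar_est$ci_low, ", ", goldgar_est$ci_high, "]",
         if (goldgar_est$boundary_low || goldgar_est$boundary_high)
           " (CI touches the grid boundary)" else "")
    for (r in rates) {
      if (is.na(r)) {
        est <- goldgar_est
      } else {
        # growth correction for the multi-marker estimate: the median of
        # the per-marker single-marker corrections at this growth rate
        sm <- sm_tables[[rate_key(r)]]
        ok <- sm$status == "ok" & !is.na(sm$delta_correction)
        if (!any(ok)) {
          stop("no usable single-marker correction for growth rate ", r)
        }
        dmed <- stats::median(sm$delta_correction[ok])
        est <- corrected_age(goldgar_est, dmed)
      }
      report <- rbind(report, data.frame(
        method = "goldgar", n_markers = nrow(map$table), growth_rate = r,
        estimate_raw = est$g_hat, delta = est$delta,
        estimate_corrected = est$g_corrected,
        ci_low = est$ci_low_corrected, ci_high = est$ci_high_corrected,
        ci_width = interval_width(est$ci_low_corrected,
                                  est$ci_high_corrected),
        flags = paste0(c(if (est$boundary_low) "ci_low_at_boundary",
                         if (est$boundary_high) "ci_high_at_boundary",
                         if (est$tie_at_max) "tie_at_max"),
                       collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(report) <- NULL

  out <- list(report = report, single_marker = sm_tables[[1]],
              goldgar = goldgar_est, dataset = dataset, truth = truth,
              ancestral = ancestral, freqs = freqs, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = FALSE, digits = NA, na = "null",
                         dataframe = "rows")
    utils::write.table(out$single_marker,
                       file.path(out_dir, "single_marker.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(goldgar_est)) {
      utils::write.table(goldgar_est$curve,
                         file.path(out_dir, "goldgar_loglik.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed, methods = methods, growth_rates = growth_rates,
           grid = grid, correction = corr_cfg, log = log),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  out
}

#' Load a pipeline report back from its JSON artifact
#'
#' @param path Path to a `report.json` written by [run_pipeline()].
#' @return The report data.frame.
#' @export
read_report_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$flags[is.na(df$flags)] <- ""
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
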