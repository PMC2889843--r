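# Demographic arithmetic: per-generation growth rates from census pairs
# under p1 = p0 * r^g, and generation/year conversions.

#' Per-generation growth rate from a census pair
#'
#' Under exponential growth p1 = p0 * r^g with g generations between the
#' two censuses, the per-generation fold growth is r = (p1/p0)^(1/g).
#' Fractional generation counts are kept exact (no rounding before
#' exponentiation).
#'
#' @param p0,p1 Population sizes at `year0` and `year1` (positive).
#' @param year0,year1 Calendar years, `year1 > year0`.
#' @param years_per_generation Default 25.
#' @return A list with `r` (fold growth per generation) and `generations`.
#' @export
#' @examples
#' growth_rate(560000, 5e6, 1765, 1900)$r    # about 1.5
#' growth_rate(11000, 5e6, 600, 1900)$r      # about 1.125
growth_rate <- function(p0, p1, year0, year1, years_per_generation = 25) {
  if (p0 <= 0 || p1 <= 0) stop("population sizes must be positive")
  if (year1 <= year0) stop("year1 must be after year0")
  if (years_per_generation <= 0) stop("years_per_generation must be positive")
  g <- (year1 - year0) / years_per_generation
  list(r = (p1 / p0)^(1 / g), generations = g)
}

#' Convert generations to years and to a calendar year of origin
#'
#' @param g Age in generations (>= 0).
#' @param years_per_generation Default 25.
#' @param reference_year Present-day calendar year the age counts back
#'   from (optional).
#' @return A list with `years` and, when a reference year is given,
#'   `origin_year = reference_year - years`.
#' @export
#' @examples
#' generations_to_years(17)                        # 425 years
#' generations_to_years(17, reference_year = 2000) # origin about 1575
generations_to_years <- function(g, years_per_generation = 25,
                                 reference_year = NULL) {
  if (any(g < 0)) stop("g must be non-negative")
  years <- g * years_per_generation
  out <- list(years = years)
  if (!is.null(reference_year)) out$origin_year <- reference_year - years
  out
}
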