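#' Phenotype table of herbicide-assay survival counts
#'
#' One row per population and replication: plants treated and plants
#' surviving, plus population metadata (region and a county-level covariate
#' such as the groundwater-protection-area size in km^2).
#'
#' @param population population ID per row.
#' @param replication replication index per row.
#' @param n_treated,n_survived integer counts, \code{0 <= survived <= treated}.
#' @param region optional region label per row.
#' @param covariate optional county covariate per row (e.g. GWPA km^2).
#' @return A data.frame of class \code{phenotype_table}.
#' @export
phenotype_table <- function(population, replication, n_treated, n_survived,
                            region = NA, covariate = NA) {
  n_treated <- as.integer(n_treated); n_survived <- as.integer(n_survived)
  if (any(n_treated <= 0)) stop("every replication needs n_treated > 0")
  if (any(n_survived < 0 | n_survived > n_treated))
    stop("need 0 <= n_survived <= n_treated")
  out <- data.frame(population = as.character(population),
                    replication = as.integer(replication),
                    n_treated = n_treated, n_survived = n_survived,
                    region = region, covariate = covariate,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Population-level resistance from assay survival
#'
#' R is the mean over replications of the per-replication survivor
#' proportion; SE is the standard deviation of per-replication proportions
#' over sqrt(number of replications), 0 for a single replication.  Note the
#' replication mean differs from the pooled ratio when replication sizes
#' differ.
#'
#' @param tbl a \code{\link{phenotype_table}}.
#' @return A data.frame: population, n_reps, R, SE.
#' @export
population_resistance <- function(tbl) {
  if (any(tbl$n_treated <= 0)) stop("replication with n_treated = 0")
  sp <- split(tbl, tbl$population)
  out <- lapply(sp, function(d) {
    pr <- d$n_survived / d$n_treated
    data.frame(population = d$population[1], n_reps = nrow(d),
               R = mean(pr),
               SE = if (nrow(d) > 1) stats::sd(pr) / sqrt(nrow(d)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[match(unique(tbl$population), out$population), , drop = FALSE]
}

#' Regional mean resistance frequencies
#'
#' Unweighted mean of population-level R within each region, rounded to two
#' decimals for reporting.
#'
#' @param R named vector of population resistance frequencies.
#' @param region_map named vector mapping population -> region.
#' @param digits rounding for the reported means.
#' @return Named numeric vector of regional means (NA for empty regions).
#' @export
regional_means <- function(R, region_map, digits = 2) {
  if (!all(names(R) %in% names(region_map)))
    stop("every population must be mapped to a region")
  reg <- region_map[names(R)]
  means <- tapply(R, reg, function(x) mean(x, na.rm = TRUE))
  round(means, digits)
}

#' Correlation between resistance and a county covariate
#'
#' Pearson product-moment correlation of population resistance frequencies
#' with a county-level covariate (GWPA area), with the two-sided t-test
#' p-value, via \code{stats::cor.test}.
#'
#' @param R named vector of population resistance frequencies.
#' @param covariate named vector of covariate values per population.
#' @return A list: \code{r}, \code{p}, \code{df}, \code{n}.
#' @export
gwpa_correlation <- function(R, covariate) {
  common <- intersect(names(R), names(covariate))
  x <- R[common]; y <- covariate[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 populations with both values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}

#' Bundled field survey of glyphosate resistance
#'
#' The bundled survey of 42 California \emph{Conyza canadensis} field
#' populations plus a resistant and a susceptible control line: glyphosate
#' assay totals (plants treated and surviving at 840 g a.e./ha), the
#' published population-level resistance frequency R (mean over 2-3
#' replications, which the pooled totals cannot always reconstruct), region,
#' county and county groundwater-protection-area size.
#'
#' @return A data.frame, one row per population.
#' @export
conyza_survey <- function() {
  utils::read.csv(system.file("extdata", "conyza_survey.csv",
                              package = "ssrabc", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Bundled per-population diversity and selfing-rate table
#'
#' Published per-population microsatellite summaries for the same survey:
#' sample size, rarefied allelic richness, expected/observed heterozygosity,
#' multilocus F_IS and the selfing rate derived from it.
#'
#' @return A data.frame, one row per population.
#' @export
conyza_diversity <- function() {
  utils::read.csv(system.file("extdata", "conyza_diversity.csv",
                              package = "ssrabc", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
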