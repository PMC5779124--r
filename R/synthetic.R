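#' Configuration for the synthetic study-like data generator
#'
#' The defaults emulate the study conditions: 42 populations of 30 diploid
#' individuals genotyped at 12 microsatellite loci; extreme self-fertilization
#' (s = 0.96) so each population holds few multilocus genotypes, founded from
#' a shared regional pool of selfing lineages (hence MLGs shared across
#' populations) drawn from two diverged gene pools; a fraction of populations
#' "resistant"; and a county covariate positively linked to the resistance
#' frequency through a logistic model.
#'
#' @param n_populations,n_individuals,n_loci data dimensions.
#' @param selfing selfing probability s* in [0, 1] of the forward mating
#'   model.
#' @param n_founders founder lineages drawn per population.
#' @param n_lineage_pool size of the shared regional lineage pool.
#' @param mu forward per-gene-copy, per-generation single-step mutation rate.
#' @param n_generations forward generations (enough to approach inbreeding
#'   equilibrium at high s).
#' @param resistant_fraction fraction of populations labelled resistant.
#' @param covariate_link logistic slope tying the (standardized) covariate to
#'   the resistance frequency; 0 gives no association.
#' @param pool_split_time,pool_ne coalescent settings of the two founder gene
#'   pools.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_populations = 42L, n_individuals = 30L,
                         n_loci = 12L, selfing = 0.96, n_founders = 3L,
                         n_lineage_pool = 60L, mu = 1e-4,
                         n_generations = 20L, resistant_fraction = 0.4,
                         covariate_link = 2.0, pool_split_time = 2000,
                         pool_ne = 1000) {
  stopifnot(n_populations >= 1, n_individuals >= 2, n_loci >= 1,
            selfing >= 0, selfing <= 1, n_founders >= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic genotype dataset with known ground truth
#'
#' A shared pool of homozygous founder lineages is drawn from a two-gene-pool
#' coalescent (each lineage is one gene copy doubled, reflecting a fully
#' selfed ancestor).  Each population draws founders from its pool half and
#' is propagated forward for \code{n_generations}: an offspring is produced
#' by selfing with probability s* (copying one parent) or by outcrossing two
#' random parents (one allele from each per locus), with single-step
#' mutation at rate \code{mu} per gene copy.  The truth record carries the
#' founder-lineage pool, each individual's founding lineage, and all
#' outcross events.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return A list: \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{truth} (founder assignments, outcross pedigree events, per-pop
#'   lineage counts, covariate and resistance labels).
#' @export
generate_genotypes <- function(cfg) {
  # founder lineage pool from two diverged panmictic demes
  ev <- matrix(c(cfg$pool_split_time, 1, 2, 1, 0), 1, 5)
  half <- ceiling(cfg$n_lineage_pool / 2)
  copies <- .sim_loci_cpp(c(half, cfg$n_lineage_pool - half),
                          c(cfg$pool_ne, cfg$pool_ne), ev,
                          cfg$n_loci, 5e-4, 0.3)
  lineage_pool <- copies  # one gene copy per lineage; founders homozygous
  pool_of_lineage <- rep(1:2, c(half, cfg$n_lineage_pool - half))
  npop <- cfg$n_populations
  pool_of_pop <- rep(1:2, length.out = npop)
  resistant <- seq_len(npop) <= round(cfg$resistant_fraction * npop)
  covariate <- exp(stats::rnorm(npop, mean = ifelse(resistant, 1, 0), sd = 0.7))
  n <- cfg$n_individuals
  a1 <- a2 <- matrix(NA_integer_, npop * n, cfg$n_loci)
  pop <- rep(paste0("SP", seq_len(npop)), each = n)
  founder_of <- integer(npop * n)
  outcross <- list()
  step_mut <- function(g) {
    hit <- stats::runif(length(g)) < cfg$mu
    if (any(hit))
      g[hit] <- pmax(1L, pmin(40L, g[hit] +
        sample(c(-1L, 1L), sum(hit), replace = TRUE)))
    g
  }
  for (p in seq_len(npop)) {
    cand <- which(pool_of_lineage == pool_of_pop[p])
    fl <- sample(cand, min(cfg$n_founders, length(cand)))
    lin <- sample(fl, n, replace = TRUE)
    g1 <- lineage_pool[lin, , drop = FALSE]
    g2 <- g1
    lineage_id <- lin
    for (gen in seq_len(cfg$n_generations)) {
      h1 <- h2 <- matrix(NA_integer_, n, cfg$n_loci)
      new_lin <- integer(n)
      for (i in seq_len(n)) {
        if (stats::runif(1) < cfg$selfing) {
          m <- sample.int(n, 1)
          pick <- stats::runif(cfg$n_loci) < 0.5
          # selfed offspring: one of the parent's two alleles per locus, twice drawn
          h1[i, ] <- ifelse(pick, g1[m, ], g2[m, ])
          pick2 <- stats::runif(cfg$n_loci) < 0.5
          h2[i, ] <- ifelse(pick2, g1[m, ], g2[m, ])
          new_lin[i] <- lineage_id[m]
        } else {
          m <- sample.int(n, 2)
          pick <- stats::runif(cfg$n_loci) < 0.5
          h1[i, ] <- ifelse(pick, g1[m[1], ], g2[m[1], ])
          pick2 <- stats::runif(cfg$n_loci) < 0.5
          h2[i, ] <- ifelse(pick2, g1[m[2], ], g2[m[2], ])
          new_lin[i] <- lineage_id[m[1]]
          outcross[[length(outcross) + 1L]] <-
            data.frame(population = paste0("SP", p), generation = gen,
                       offspring = i, parent1 = lineage_id[m[1]],
                       parent2 = lineage_id[m[2]])
        }
        h1[i, ] <- step_mut(h1[i, ]); h2[i, ] <- step_mut(h2[i, ])
      }
      g1 <- h1; g2 <- h2; lineage_id <- new_lin
    }
    rows <- (p - 1) * n + seq_len(n)
    a1[rows, ] <- g1; a2[rows, ] <- g2
    founder_of[rows] <- lineage_id
  }
  G <- genotype_matrix(a1, a2, pop = factor(pop, levels = unique(pop)))
  truth <- list(
    founder_of = founder_of,
    outcross_events = if (length(outcross)) do.call(rbind, outcross) else NULL,
    lineages_per_pop = tapply(founder_of, pop, function(x) length(unique(x))),
    resistant = setNames(resistant, unique(pop)),
    covariate = setNames(covariate, unique(pop)),
    pool_of_pop = setNames(pool_of_pop, unique(pop)))
  list(genotypes = G, truth = truth)
}

#' Generate a synthetic phenotype (survival-assay) table
#'
#' Each population gets a true resistance frequency from a logistic function
#' of its standardized covariate (plus binomial sampling noise), and 2-3
#' assay replications of 20-30 treated plants with binomial survivor counts.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param truth the truth record from \code{\link{generate_genotypes}} (for
#'   the covariate); omit to draw a fresh covariate.
#' @return A list: \code{table} (a \code{\link{phenotype_table}}),
#'   \code{true_R} (per-population true resistance frequency),
#'   \code{covariate}.
#' @export
generate_phenotypes <- function(cfg, truth = NULL) {
  npop <- cfg$n_populations
  pops <- paste0("SP", seq_len(npop))
  covariate <- if (!is.null(truth)) truth$covariate[pops] else
    setNames(exp(stats::rnorm(npop, 0, 1)), pops)
  z <- as.numeric(scale(log(covariate)))
  true_R <- stats::plogis(-1 + cfg$covariate_link * z)
  rows <- list()
  for (p in seq_len(npop)) {
    for (rep_i in seq_len(sample(2:3, 1))) {
      nt <- sample(20:30, 1)
      ns <- stats::rbinom(1, nt, true_R[p])
      rows[[length(rows) + 1L]] <- data.frame(
        population = pops[p], replication = rep_i,
        n_treated = nt, n_survived = ns)
    }
  }
  d <- do.call(rbind, rows)
  tbl <- phenotype_table(d$population, d$replication, d$n_treated,
                         d$n_survived, covariate = covariate[d$population])
  list(table = tbl, true_R = setNames(true_R, pops), covariate = covariate)
}
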