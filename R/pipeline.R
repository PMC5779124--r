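#' Run configuration for the analysis pipelines
#'
#' Collects the knobs of \code{\link{run_descriptive}} and
#' \code{\link{run_abc}} with the study defaults: 1000 permutations and
#' bootstraps, automatic rarefaction size, and desk-scale ABC settings.  The
#' seed is recorded in every output bundle.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every randomized stage derives from it.
#' @param qc_policy \code{"drop"} or \code{"keep_flagged"}.
#' @param n_perm,n_boot permutation and bootstrap counts.
#' @param rarefaction_n rarefaction size or \code{"auto"}.
#' @param n_per_scenario,n_closest_frac,n_pods,n_check_sims ABC scale.
#' @param n_loci simulated loci.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(out_dir = "ssrabc-out", seed = 1L,
                       qc_policy = "drop", n_perm = 1000L, n_boot = 1000L,
                       rarefaction_n = "auto", n_per_scenario = 10000L,
                       n_closest_frac = 0.10, n_pods = 100L,
                       n_check_sims = 1000L, n_loci = 12L) {
  stopifnot(n_perm >= 0, n_boot >= 0, n_per_scenario >= 1,
            n_closest_frac > 0, n_closest_frac <= 1)
  structure(as.list(environment()), class = "run_config")
}

.write_header <- function(config, path, extra = list()) {
  info <- c(list(seed = config$seed, date = format(Sys.time())), extra)
  writeLines(paste(names(info), vapply(info, function(x)
    paste(format(x), collapse = " "), ""), sep = ": "), path)
}

#' Descriptive population-genetic report bundle
#'
#' Runs the full descriptive chain on a genotype dataset (and optional
#' phenotype table): per-locus and per-population diversity summaries,
#' pairwise F_ST with permutation significance, Nei distances with a PHYLIP
#' export, the MLG sharing/classification report, and resistance summaries
#' with the covariate correlation.  All files are written under
#' \code{config$out_dir} together with a manifest recording the seed.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param config a \code{\link{run_config}}.
#' @param phenotypes optional \code{\link{phenotype_table}}.
#' @return Invisibly, the list of written file paths.
#' @export
run_descriptive <- function(G, config = run_config(), phenotypes = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  paths <- character()
  wr <- function(x, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(locus_summaries(G, n_perm = config$n_perm), "locus_summaries.csv")
  ps <- population_summaries(G, rarefaction_n = config$rarefaction_n)
  wr(ps, "population_summaries.csv")
  if (nlevels(G$pop) >= 2) {
    pf <- pairwise_fst(G, n_perm = config$n_perm)
    wr(as.data.frame(pf$fst), "pairwise_fst.csv")
    wr(as.data.frame(pf$p), "pairwise_fst_p.csv")
    nd <- nei_distance_matrix(G, n_boot = config$n_boot)
    wr(as.data.frame(nd$D), "nei_distance.csv")
    pp <- file.path(config$out_dir, "nei_distance.phy")
    write_phylip(nd$D, pp); paths <- c(paths, pp)
  }
  mlg <- identify_mlgs(G)
  wr(mlg$mlgs, "mlg_table.csv")
  wr(as.data.frame(mlg$counts), "mlg_counts.csv")
  if (!is.null(phenotypes)) {
    rs <- population_resistance(phenotypes)
    wr(rs, "resistance_summaries.csv")
    cov <- tapply(phenotypes$covariate, phenotypes$population, `[`, 1)
    if (!all(is.na(cov))) {
      ct <- gwpa_correlation(setNames(rs$R, rs$population), cov)
      wr(data.frame(r = ct$r, p = ct$p, df = ct$df, n = ct$n),
         "covariate_correlation.csv")
    }
    rep <- mlg_report(mlg, G, setNames(rs$R, rs$population))
    wr(rep, "mlg_lineage_report.csv")
  }
  .write_header(config, file.path(config$out_dir, "MANIFEST.txt"),
                list(stage = "descriptive", n_perm = config$n_perm,
                     n_boot = config$n_boot))
  invisible(c(paths, file.path(config$out_dir, "MANIFEST.txt")))
}

#' ABC report bundle for one scenario family
#'
#' Builds the reference table for a scenario set (A: 7 scenarios, B/C: 5
#' scenarios), computes the scenario posterior for the observed data, the
#' confidence-in-choice confusion matrix with recent- vs no-recent-admixture
#' grouping, parameter posteriors for the selected scenario, and the
#' posterior predictive model check, writing each as CSV.
#'
#' @param observed_G observed \code{\link{genotype_matrix}} whose populations
#'   match the scenario layout (P1, P2, ... in level order).
#' @param scenario_set \code{"A"}, \code{"B"} or \code{"C"}, or a named list
#'   of \code{\link{build_scenario}} objects.
#' @param config a \code{\link{run_config}}.
#' @param confidence run the (expensive) confidence-in-choice stage.
#' @return Invisibly, a list with the in-memory results
#'   (\code{reference}, \code{posterior}, \code{confusion},
#'   \code{parameters}, \code{check}).
#' @export
run_abc <- function(observed_G, scenario_set, config = run_config(),
                    confidence = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  scenarios <- if (is.list(scenario_set)) scenario_set else {
    ids <- paste0(scenario_set, seq_len(if (scenario_set == "A") 7L else 5L))
    setNames(lapply(ids, build_scenario), ids)
  }
  ref <- build_reference_table(scenarios, config$n_per_scenario,
                               n_loci = config$n_loci)
  n_closest <- max(2L, round(config$n_closest_frac * nrow(ref$stats)))
  obs_stats <- abc_summary_stats(observed_G)
  post <- scenario_posterior(ref, obs_stats, n_closest)
  utils::write.csv(post$table,
                   file.path(config$out_dir, "scenario_posterior.csv"),
                   row.names = FALSE)
  conf <- NULL
  if (confidence) {
    recent <- names(scenarios)[vapply(scenarios, function(s)
      any(vapply(s$admixture, `[[`, "", "when") == "recent"), TRUE)]
    conf <- confidence_in_choice(
      ref, n_pods = config$n_pods, n_closest = n_closest,
      groups = list(no_recent_admixture = setdiff(names(scenarios), recent),
                    recent_admixture = recent))
    utils::write.csv(as.data.frame(conf$freq),
                     file.path(config$out_dir, "confusion_matrix.csv"))
    utils::write.csv(data.frame(scenario = names(conf$type1),
                                type1 = conf$type1,
                                type2 = conf$type2[names(conf$type1)]),
                     file.path(config$out_dir, "error_rates.csv"),
                     row.names = FALSE)
    if (!is.null(conf$group_rates))
      utils::write.csv(conf$group_rates,
                       file.path(config$out_dir, "group_error_rates.csv"),
                       row.names = FALSE)
  }
  best <- select_scenario(post)
  est <- estimate_parameters(ref, best, obs_stats,
                             n_closest = max(2L, round(config$n_closest_frac *
                                                         config$n_per_scenario)))
  utils::write.csv(est$summary,
                   file.path(config$out_dir, "parameter_posteriors.csv"),
                   row.names = FALSE)
  chk <- model_check(ref, est, observed_G, n_sims = config$n_check_sims)
  utils::write.csv(chk, file.path(config$out_dir, "model_check.csv"),
                   row.names = FALSE)
  .write_header(config, file.path(config$out_dir, "MANIFEST-abc.txt"),
                list(stage = "abc",
                     scenarios = paste(names(scenarios), collapse = ","),
                     n_per_scenario = config$n_per_scenario,
                     n_closest = n_closest, selected = best))
  invisible(list(reference = ref, posterior = post, confusion = conf,
                 parameters = est, check = chk))
}
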