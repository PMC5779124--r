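#' ABC summary-statistic vector of a genotype dataset
#'
#' The selection/estimation statistics: per-population mean allele number and
#' mean Garza-Williamson M; pairwise multilocus Weir-Cockerham F_ST for all
#' unordered population pairs; and mean individual assignment log-likelihoods
#' for all ordered population pairs.  Ordering is deterministic given the
#' population levels.  Undefined pairwise F_ST (monomorphic pair) is imputed
#' as 0 to keep the vector finite.  The posterior predictive test statistics
#' (genic diversity, allele-size variance, shared allele distance) are
#' deliberately not part of this vector.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return A named numeric vector.
#' @export
abc_summary_stats <- function(G) {
  pi <- pop_index(G)
  am <- .allele_number_m_cpp(G$a1, G$a2, pi$idx, pi$k)
  out <- c(setNames(am[, 1], paste0("NAL_", pi$labels)),
           setNames(am[, 2], paste0("M_", pi$labels)))
  if (pi$k >= 2) {
    fst <- .pairwise_fst_cpp(G$a1, G$a2, pi$idx, pi$k)
    al <- .assign_loglik_cpp(G$a1, G$a2, pi$idx, pi$k)
    for (i in seq_len(pi$k - 1)) for (j in (i + 1):pi$k) {
      v <- fst[i, j]
      out[paste0("FST_", pi$labels[i], ".", pi$labels[j])] <-
        if (is.na(v)) 0 else v
    }
    for (i in seq_len(pi$k)) for (j in seq_len(pi$k)) {
      if (i == j) next
      out[paste0("AL_", pi$labels[i], ".", pi$labels[j])] <- al[i, j]
    }
  }
  out
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors, simulates a dataset, and records its
#' summary-statistic vector, for each of \code{n_per_scenario} rows per
#' scenario.  Seed the R RNG beforehand for bit-for-bit reproducibility.
#'
#' @param scenarios named list of \code{\link{build_scenario}} objects with
#'   identical sampled-population layouts.
#' @param n_per_scenario simulations per scenario (>= 1).
#' @param n_loci loci per simulated dataset.
#' @param progress print a progress line per scenario.
#' @return An object of class \code{abc_reference}: \code{stats} (row x
#'   statistic matrix), \code{scenario} (factor), \code{params} (list of
#'   per-scenario parameter matrices), \code{n_loci}.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, n_loci = 12L,
                                  progress = FALSE) {
  if (n_per_scenario < 1) stop("n_per_scenario must be >= 1")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "id")
  stats_rows <- list(); scen <- character(); params <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    pm <- NULL
    for (b in seq_len(n_per_scenario)) {
      par <- draw_params(sc)
      G <- tryCatch(simulate_dataset(sc, par, n_loci),
                    error = function(e) stop("scenario ", nm, ": ",
                                             conditionMessage(e)))
      s <- abc_summary_stats(G)
      stats_rows[[length(stats_rows) + 1L]] <- s
      flat <- unlist(par)
      if (is.null(pm)) pm <- matrix(NA_real_, n_per_scenario, length(flat),
                                    dimnames = list(NULL, names(flat)))
      pm[b, names(flat)] <- flat
    }
    params[[nm]] <- pm
    scen <- c(scen, rep(nm, n_per_scenario))
    if (progress) message("scenario ", nm, ": ", n_per_scenario, " rows")
  }
  stats <- do.call(rbind, stats_rows)
  structure(list(stats = stats, scenario = factor(scen, levels = names(scenarios)),
                 params = params, n_loci = as.integer(n_loci),
                 scenarios = scenarios),
            class = "abc_reference")
}

#' @export
print.abc_reference <- function(x, ...) {
  cat("abc_reference:", nrow(x$stats), "rows (",
      paste(levels(x$scenario), collapse = ", "), "),",
      ncol(x$stats), "summary statistics\n")
  invisible(x)
}

# z-score the reference stats; returns scaled matrix, centers/scales and the
# retained columns (zero-variance statistics are dropped)
.normalize_stats <- function(stats) {
  mu <- colMeans(stats)
  sdv <- apply(stats, 2, stats::sd)
  keep <- which(sdv > 0)
  list(z = sweep(sweep(stats[, keep, drop = FALSE], 2, mu[keep]), 2,
                 sdv[keep], "/"),
       center = mu[keep], scale = sdv[keep], keep = keep)
}

.epanechnikov <- function(d, dmax) {
  if (dmax <= 0) return(rep(1, length(d)))
  pmax(0, 1 - (d / dmax)^2)
}

#' Scenario posterior probabilities by local logistic regression
#'
#' Ranks reference rows by Euclidean distance on z-scored statistics, keeps
#' the \code{n_closest} best, and fits a multinomial logistic regression of
#' scenario on the (centered) statistics with Epanechnikov distance weights;
#' the posterior is the fit evaluated at the observed vector, with 95%
#' confidence intervals by the delta method on the fitted intercepts.
#' Scenarios absent from the retained set get probability 0 with a
#' degenerate interval (with a warning).
#'
#' @param ref an \code{\link{build_reference_table}} object.
#' @param observed a summary-statistic vector from
#'   \code{\link{abc_summary_stats}}.
#' @param n_closest retained simulations (<= rows of \code{ref}).
#' @param ridge ridge penalty on the (z-scored) statistic slopes of the local
#'   logistic fit; intercepts are never penalized, so the class odds at the
#'   observed point stay unbiased.  The default tempers quasi-separation when
#'   the retained set is small relative to the statistic dimension.
#' @return An object of class \code{scenario_posterior}: data.frame with
#'   scenario, posterior probability, CI bounds; plus the retained index.
#' @export
scenario_posterior <- function(ref, observed, n_closest, ridge = 2) {
  if (n_closest > nrow(ref$stats)) stop("n_closest exceeds reference rows")
  nz <- .normalize_stats(ref$stats)
  obs <- (observed[colnames(nz$z)] - nz$center) / nz$scale
  d <- sqrt(rowSums(sweep(nz$z, 2, obs)^2))
  ord <- order(d)  # ties broken by row index
  sel <- ord[seq_len(n_closest)]
  w <- .epanechnikov(d[sel], max(d[sel]))
  if (all(w == 0)) w <- rep(1, length(sel))
  lev <- levels(ref$scenario)
  ysel <- factor(ref$scenario[sel], levels = lev)
  present <- lev[table(ysel) > 0]
  if (length(present) < length(lev))
    warning("scenario(s) absent from retained set: ",
            paste(setdiff(lev, present), collapse = ", "))
  probs <- setNames(rep(0, length(lev)), lev)
  lo <- hi <- probs
  if (length(present) == 1L) {
    probs[present] <- 1; lo[present] <- hi[present] <- 1
  } else {
    X <- cbind(1, sweep(nz$z[sel, , drop = FALSE], 2, obs))
    yi <- as.integer(factor(as.character(ysel), levels = present))
    K <- length(present)
    fit <- .multinom_irls_cpp(X, yi, w / mean(w), K, ridge = ridge)
    eta <- c(fit$coef[1, ], 0)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    probs[present] <- p
    # delta method on the K-1 intercepts
    pidx <- ncol(X) * (seq_len(K - 1) - 1) + 1  # vcov index of each intercept
    V <- fit$vcov[pidx, pidx, drop = FALSE]
    if (!anyNA(V)) {
      Jac <- matrix(0, K, K - 1)
      for (i in seq_len(K)) for (j in seq_len(K - 1))
        Jac[i, j] <- p[i] * ((i == j) - p[j])
      se <- sqrt(pmax(0, diag(Jac %*% V %*% t(Jac))))
      lo[present] <- pmax(0, p - 1.96 * se)
      hi[present] <- pmin(1, p + 1.96 * se)
    } else {
      lo[present] <- NA_real_; hi[present] <- NA_real_
    }
  }
  structure(list(
    table = data.frame(scenario = lev, posterior = unname(probs),
                       ci_lo = unname(lo), ci_hi = unname(hi),
                       stringsAsFactors = FALSE),
    retained = sel, n_closest = n_closest),
    class = "scenario_posterior")
}

#' @export
print.scenario_posterior <- function(x, digits = 4, ...) {
  cat("scenario posterior (local logistic on", x$n_closest, "closest rows):\n")
  tb <- x$table
  tb$posterior <- round(tb$posterior, digits)
  tb$ci_lo <- round(tb$ci_lo, digits); tb$ci_hi <- round(tb$ci_hi, digits)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Most probable scenario
#' @param post a \code{\link{scenario_posterior}}.
#' @return The scenario label with the highest posterior probability.
#' @export
select_scenario <- function(post) {
  post$table$scenario[which.max(post$table$posterior)]
}

#' Confidence in scenario choice (Type I / Type II error rates)
#'
#' For each true scenario, simulates pseudo-observed datasets (PODs) from the
#' prior, selects the max-posterior scenario for each with the same local
#' logistic machinery, and tabulates selection frequencies.  Type I for
#' scenario i is 1 minus its self-selection frequency; Type II for i is the
#' mean frequency with which i is selected when another scenario is true.
#' Optional scenario groups (e.g., no-recent-admixture vs recent-admixture)
#' get grouped rates: a grouped selection counts as correct when the selected
#' scenario lies in the true scenario's group.
#'
#' @param ref an \code{\link{build_reference_table}} object.
#' @param n_pods PODs per true scenario.
#' @param n_closest retained rows for each POD's posterior.
#' @param true_scenarios subset of scenario labels to simulate under
#'   (default all).
#' @param groups optional named list of character vectors of scenario labels.
#' @return An object of class \code{abc_confusion}: \code{freq} (true x
#'   selected selection-frequency matrix), \code{type1}, \code{type2},
#'   \code{group_rates}.
#' @export
confidence_in_choice <- function(ref, n_pods = 100L, n_closest,
                                 true_scenarios = levels(ref$scenario),
                                 groups = NULL) {
  if (n_pods < 1) stop("n_pods must be >= 1")
  lev <- levels(ref$scenario)
  freq <- matrix(0, length(true_scenarios), length(lev),
                 dimnames = list(true_scenarios, lev))
  for (tr in true_scenarios) {
    sc <- ref$scenarios[[tr]]
    for (b in seq_len(n_pods)) {
      par <- draw_params(sc)
      G <- simulate_dataset(sc, par, ref$n_loci)
      post <- suppressWarnings(
        scenario_posterior(ref, abc_summary_stats(G), n_closest))
      sel <- select_scenario(post)
      freq[tr, sel] <- freq[tr, sel] + 1
    }
  }
  freq <- freq / n_pods
  diagv <- vapply(true_scenarios, function(tr) freq[tr, tr], 0)
  type1 <- 1 - diagv
  type2 <- vapply(lev, function(s) {
    others <- setdiff(true_scenarios, s)
    if (!length(others)) return(NA_real_)
    mean(freq[others, s])
  }, 0)
  group_rates <- NULL
  if (!is.null(groups)) {
    group_rates <- lapply(names(groups), function(g) {
      members <- intersect(groups[[g]], true_scenarios)
      if (!length(members)) return(NULL)
      insel <- lev %in% groups[[g]]
      t1 <- mean(vapply(members, function(tr) 1 - sum(freq[tr, insel]), 0))
      others <- setdiff(true_scenarios, groups[[g]])
      t2 <- if (length(others))
        mean(vapply(others, function(tr) sum(freq[tr, insel]), 0)) else NA_real_
      data.frame(group = g, type1 = t1, type2 = t2, stringsAsFactors = FALSE)
    })
    group_rates <- do.call(rbind, group_rates)
  }
  structure(list(freq = freq, type1 = type1, type2 = type2,
                 group_rates = group_rates, n_pods = n_pods),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, digits = 2, ...) {
  cat("confidence in scenario choice (", x$n_pods, "PODs per scenario):\n")
  cat("selection frequencies (rows = true scenario):\n")
  print(round(x$freq, digits))
  cat("Type I:\n"); print(round(x$type1, digits))
  cat("Type II:\n"); print(round(x$type2, digits))
  if (!is.null(x$group_rates)) { cat("grouped rates:\n"); print(x$group_rates) }
  invisible(x)
}

# parameter transforms for regression adjustment: rates and the GSM
# coefficient are logit-transformed within their prior bounds, everything
# else (sizes, times, mu) log-transformed
.param_transform <- function(name, x, priors, inverse = FALSE) {
  logit_bounds <- if (grepl("^radm_", name)) c(priors$r_adm$lo, priors$r_adm$hi)
    else if (name == "gsm_p") c(priors$gsm_p$lo, priors$gsm_p$hi)
    else NULL
  if (!is.null(logit_bounds)) {
    lo <- logit_bounds[1]; hi <- logit_bounds[2]
    if (!inverse) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-9), 1 - 1e-9))
    else lo + (hi - lo) * stats::plogis(x)
  } else {
    if (!inverse) log(pmax(x, 1e-12)) else exp(x)
  }
}

#' ABC parameter estimation with local linear regression adjustment
#'
#' Retains the \code{n_closest} reference rows of one scenario by distance to
#' the observed statistics, transforms each parameter (log for sizes, times
#' and mutation rates; logit within prior bounds for admixture rates and the
#' GSM coefficient), regresses the transformed draws on the centered
#' statistics with Epanechnikov weights, shifts each draw by its regression
#' prediction (Beaumont adjustment), back-transforms, and summarizes the
#' weighted posterior sample.  A singular regression falls back to the
#' unadjusted rejection sample with a warning.
#'
#' @param ref an \code{\link{build_reference_table}} object.
#' @param scenario scenario label whose rows (and parameters) to use.
#' @param observed a summary-statistic vector.
#' @param n_closest retained rows (<= rows of that scenario).
#' @param level credible level for the reported intervals (default 0.95).
#' @param ridge ridge penalty on the (z-scored) statistic slopes of the local
#'   regression, intercept unpenalized.  The default tempers the adjustment
#'   when the retained set is small relative to the statistic dimension,
#'   keeping credible-interval coverage near nominal; 0 recovers ordinary
#'   weighted least squares.
#' @return An object of class \code{abc_posterior}: \code{sample}
#'   (adjusted draws), \code{weights}, and \code{summary} (mean, median,
#'   mode, interval bounds per parameter).
#' @export
estimate_parameters <- function(ref, scenario, observed, n_closest,
                                level = 0.95, ridge = 25) {
  rows <- which(ref$scenario == scenario)
  if (!length(rows)) stop("no reference rows for scenario ", scenario)
  if (n_closest > length(rows)) stop("n_closest exceeds the scenario's rows")
  nz <- .normalize_stats(ref$stats[rows, , drop = FALSE])
  obs <- (observed[colnames(nz$z)] - nz$center) / nz$scale
  d <- sqrt(rowSums(sweep(nz$z, 2, obs)^2))
  ord <- order(d)
  sel <- ord[seq_len(n_closest)]
  w <- .epanechnikov(d[sel], max(d[sel]))
  if (all(w == 0)) w <- rep(1, length(sel))
  pm <- ref$params[[scenario]][sel, , drop = FALSE]
  priors <- ref$scenarios[[scenario]]$priors
  X <- cbind(1, sweep(nz$z[sel, , drop = FALSE], 2, obs))
  A <- crossprod(X, X * w)
  if (ridge > 0) A[-1, -1] <- A[-1, -1] + ridge * diag(ncol(X) - 1L)
  adj <- pm
  for (j in colnames(pm)) {
    th <- .param_transform(j, pm[, j], priors)
    bhat <- tryCatch(solve(A, crossprod(X, th * w)), error = function(e) NULL)
    if (is.null(bhat) || anyNA(bhat)) {
      # singular design: keep the rejection sample for this parameter
      adj[, j] <- pm[, j]
      warning("singular regression for ", j, "; rejection sample kept")
    } else {
      # Beaumont shift: prediction at the observed point plus residuals
      th_adj <- bhat[1] + th - drop(X %*% bhat)
      adj[, j] <- .param_transform(j, th_adj, priors, inverse = TRUE)
    }
  }
  a <- (1 - level) / 2
  summ <- lapply(colnames(adj), function(j) {
    x <- adj[, j]
    data.frame(parameter = j,
               mean = stats::weighted.mean(x, w),
               median = .wquantile(x, w, 0.5),
               mode = .wmode(x, w),
               lo = .wquantile(x, w, a),
               hi = .wquantile(x, w, 1 - a),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  structure(list(sample = adj, weights = w, summary = summ, level = level,
                 scenario = scenario),
            class = "abc_posterior")
}

.wquantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

.wmode <- function(x, w) {
  if (length(unique(x)) < 2) return(x[1])
  # bandwidth from the unweighted sample; weights only shape the density
  dd <- stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  dd$x[which.max(dd$y)]
}

#' @export
print.abc_posterior <- function(x, digits = 4, ...) {
  cat("ABC posterior for scenario", x$scenario, "(",
      nrow(x$sample), "weighted draws):\n")
  s <- x$summary
  for (j in setdiff(names(s), "parameter")) s[[j]] <- signif(s[[j]], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Posterior predictive model check
#'
#' Simulates datasets with parameter vectors drawn from the weighted
#' posterior sample and compares held-out test statistics of the observed
#' data (per-population genic diversity and allele-size variance, pairwise
#' shared allele distance) to their posterior predictive distributions.
#' Reports two-tail rank probabilities with Benjamini-Hochberg adjustment
#' across statistics.
#'
#' @param ref an \code{\link{build_reference_table}} object (provides the
#'   scenario objects and locus count).
#' @param posterior an \code{\link{estimate_parameters}} result.
#' @param observed_G the observed \code{\link{genotype_matrix}}.
#' @param n_sims posterior predictive simulations.
#' @return A data.frame: statistic, observed, p (two-tail), p_adj (BH).
#' @export
model_check <- function(ref, posterior, observed_G, n_sims = 1000L) {
  if (!nrow(posterior$sample)) stop("empty posterior sample")
  sc <- ref$scenarios[[posterior$scenario]]
  obs <- .check_stats(observed_G)
  sims <- matrix(NA_real_, n_sims, length(obs),
                 dimnames = list(NULL, names(obs)))
  w <- posterior$weights / sum(posterior$weights)
  for (b in seq_len(n_sims)) {
    # regression-adjusted draws can land outside the scenario's admissible
    # region; redraw on a failed simulation
    for (tr in 1:50) {
      i <- sample.int(nrow(posterior$sample), 1, prob = w)
      par <- as.list(posterior$sample[i, ])
      class(par) <- "scenario_params"
      G <- tryCatch(simulate_dataset(sc, par, ref$n_loci),
                    error = function(e) NULL)
      if (!is.null(G)) break
    }
    if (is.null(G)) stop("posterior sample does not yield simulable parameters")
    sims[b, ] <- .check_stats(G)[names(obs)]
  }
  p <- vapply(seq_along(obs), function(j) {
    lo <- (1 + sum(sims[, j] <= obs[j])) / (1 + n_sims)
    hi <- (1 + sum(sims[, j] >= obs[j])) / (1 + n_sims)
    min(1, 2 * min(lo, hi))
  }, 0)
  data.frame(statistic = names(obs), observed = unname(obs),
             p = p, p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

# held-out test statistics (never in the selection vector)
.check_stats <- function(G) {
  pi <- pop_index(G)
  gv <- .gendiv_sizevar_cpp(G$a1, G$a2, pi$idx, pi$k)
  out <- c(setNames(gv[, 1], paste0("GD_", pi$labels)),
           setNames(gv[, 2], paste0("VAR_", pi$labels)))
  if (pi$k >= 2) {
    das <- .das_cpp(G$a1, G$a2, pi$idx, pi$k)
    for (i in seq_len(pi$k - 1)) for (j in (i + 1):pi$k)
      out[paste0("DAS_", pi$labels[i], ".", pi$labels[j])] <- das[i, j]
  }
  out
}

#' Persist and reload ABC reference tables
#'
#' Writes the statistics matrix, per-scenario parameter draws and a manifest
#' (scenario ids, locus count, row counts) as delimited text files so large
#' tables can be built in batches and reused across analyses.
#'
#' @param ref an \code{\link{build_reference_table}} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_reference_table <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(scenario = ref$scenario, ref$stats,
                              check.names = FALSE),
                   file.path(dir, "stats.csv"), row.names = FALSE)
  for (nm in names(ref$params))
    utils::write.csv(as.data.frame(ref$params[[nm]]),
                     file.path(dir, paste0("params_", nm, ".csv")),
                     row.names = FALSE)
  writeLines(c(paste("scenarios:", paste(levels(ref$scenario), collapse = ",")),
               paste("n_loci:", ref$n_loci),
               paste("rows:", nrow(ref$stats))),
             file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}

#' @param dir directory written by \code{write_reference_table}.
#' @param scenarios the scenario objects the table was built from (their
#'   graphs are not serialized).
#' @rdname write_reference_table
#' @export
read_reference_table <- function(dir, scenarios) {
  man <- readLines(file.path(dir, "MANIFEST.txt"))
  n_loci <- as.integer(sub("n_loci: *", "", man[grepl("^n_loci:", man)]))
  lev <- strsplit(sub("scenarios: *", "", man[grepl("^scenarios:", man)]),
                  ",")[[1]]
  d <- utils::read.csv(file.path(dir, "stats.csv"), check.names = FALSE)
  params <- lapply(stats::setNames(lev, lev), function(nm)
    as.matrix(utils::read.csv(file.path(dir, paste0("params_", nm, ".csv")),
                              check.names = FALSE)))
  structure(list(stats = as.matrix(d[, -1, drop = FALSE]),
                 scenario = factor(d$scenario, levels = lev),
                 params = params, n_loci = n_loci, scenarios = scenarios),
            class = "abc_reference")
}

#' Combine reference tables built in batches
#'
#' Row-binds tables built from the same scenario list (e.g., successive
#' seeded batches) into one larger table.
#'
#' @param ... \code{abc_reference} objects with identical scenario levels
#'   and statistics.
#' @return A single \code{abc_reference}.
#' @export
combine_reference_tables <- function(...) {
  refs <- list(...)
  if (length(refs) < 1) stop("nothing to combine")
  lev <- levels(refs[[1]]$scenario)
  for (r in refs)
    if (!identical(levels(r$scenario), lev) ||
        !identical(colnames(r$stats), colnames(refs[[1]]$stats)))
      stop("reference tables were built from different scenario sets")
  structure(list(
    stats = do.call(rbind, lapply(refs, `[[`, "stats")),
    scenario = factor(unlist(lapply(refs, function(r) as.character(r$scenario))),
                      levels = lev),
    params = stats::setNames(lapply(lev, function(nm)
      do.call(rbind, lapply(refs, function(r) r$params[[nm]]))), lev),
    n_loci = refs[[1]]$n_loci,
    scenarios = refs[[1]]$scenarios),
    class = "abc_reference")
}
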