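#' Prior set for the demographic scenario parameters
#'
#' Defaults follow the study design: ancestral/pre-management effective size
#' N_e ~ U(10, 10000); bottleneck sizes N_b ~ U(2, 100); expanded resistant
#' sizes N_r ~ U(10, 100000); bottleneck start times t ~ U(1, 150)
#' generations (one generation per year, annual life cycle) with durations b
#' constrained by t > b; lineage divergence times uniform between the
#' bottleneck start and 10000; recent admixture times U(1, 40) (after the
#' herbicide came into use); historical admixture older than 40 generations;
#' admixture rates U(0.001, 0.999); locus mutation rate mu log-uniform
#' (1e-5, 1e-4); GSM geometric coefficient P ~ U(0.10, 0.70).
#'
#' @param ... overrides as \code{name = c(lo, hi)}; names \code{mu} is
#'   log-uniform, all others uniform.
#' @return A named list of class \code{prior_set} with elements
#'   \code{list(dist, lo, hi)}.
#' @export
default_priors <- function(...) {
  pr <- list(
    Ne     = list(dist = "unif",    lo = 10,    hi = 10000),
    Nb     = list(dist = "unif",    lo = 2,     hi = 100),
    Nr     = list(dist = "unif",    lo = 10,    hi = 100000),
    t_bot  = list(dist = "unif",    lo = 1,     hi = 150),
    b_dur  = list(dist = "unif",    lo = 1,     hi = 150),
    t_div  = list(dist = "unif",    lo = 1,     hi = 10000),  # lower bound raised to t_bot at draw time
    t_radm = list(dist = "unif",    lo = 1,     hi = 40),
    t_hadm = list(dist = "unif",    lo = 41,    hi = 10000),
    r_adm  = list(dist = "unif",    lo = 0.001, hi = 0.999),
    mu     = list(dist = "logunif", lo = 1e-5,  hi = 1e-4),
    gsm_p  = list(dist = "unif",    lo = 0.10,  hi = 0.70))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(pr)) stop("unknown prior: ", nm)
    pr[[nm]]$lo <- ov[[nm]][1]; pr[[nm]]$hi <- ov[[nm]][2]
  }
  structure(pr, class = "prior_set")
}

.draw1 <- function(spec, lo = spec$lo) {
  if (lo > spec$hi) stop("empty prior support")
  if (spec$dist == "logunif") exp(stats::runif(1, log(lo), log(spec$hi)))
  else stats::runif(1, lo, spec$hi)
}

#' Build a demographic scenario graph
#'
#' Constructs the backward-time event graph of one scenario from the three
#' scenario families:
#' \describe{
#'   \item{A (A1-A7)}{2 susceptible + 2 resistant populations.  A1: all
#'     origins independent; A2-A4: historical admixture (older than 40
#'     generations) into P3, P4, or both; A5-A7: recent admixture (1-40
#'     generations) into P4, P3, or both.}
#'   \item{B (B1-B5)}{2 susceptible + 3 resistant.  B1: independent;
#'     B2/B3: historical admixture into P5/P4; B4/B5: recent admixture into
#'     P5 (donors P3, P4) / P4 (donors P3, P5).}
#'   \item{C (C1-C5)}{1 susceptible + 4 resistant.  C1: independent; C2/C3:
#'     historical admixture into P3/P5; C4/C5: recent admixture into P5
#'     (donors P3, P4) / P4 (donors P3, P5).}
#' }
#' All demes descend from two ancestral gene pools that diverged from a
#' single root population at t_a.  Each susceptible population is sampled as
#' two closely related lineages (equal halves) from its pool, each with its
#' own bottleneck start; susceptible lineages remain in bottleneck until the
#' present.  Resistant demes pass through a bottleneck (size N_b from t_i
#' back to t_i - b_i) and then expand to N_r until the present; recently
#' admixed resistant demes are expanded from their creation.
#'
#' @param set_id scenario ID: one of \code{A1..A7, B1..B5, C1..C5}.
#' @param n_diploid sampled diploid individuals per population.
#' @param priors a \code{\link{default_priors}} object.
#' @return An object of class \code{scenario_graph}.
#' @export
build_scenario <- function(set_id, n_diploid = 30L, priors = default_priors()) {
  set <- substr(set_id, 1, 1)
  num <- suppressWarnings(as.integer(substr(set_id, 2, nchar(set_id))))
  valid <- list(A = 1:7, B = 1:5, C = 1:5)
  if (!set %in% names(valid) || is.na(num) || !num %in% valid[[set]])
    stop("unknown scenario id: ", set_id)
  # population roles per set: susceptible pops are split into two lineages
  pops <- switch(set,
    A = data.frame(pop = c("P1", "P2", "P3", "P4"),
                   role = c("S", "S", "R", "R"),
                   pool = c("N", "S", "N", "S"), stringsAsFactors = FALSE),
    B = data.frame(pop = c("P1", "P2", "P3", "P4", "P5"),
                   role = c("S", "S", "R", "R", "R"),
                   pool = c("N", "S", "N", "S", "S"), stringsAsFactors = FALSE),
    C = data.frame(pop = c("P1", "P2", "P3", "P4", "P5"),
                   role = c("S", "R", "R", "R", "R"),
                   pool = c("N", "S", "N", "S", "S"), stringsAsFactors = FALSE))
  # admixture plan: list(target, donors, when)
  adm <- list()
  h <- function(target) list(target = target, donors = c("poolN", "poolS"),
                             when = "historical")
  if (set == "A") {
    if (num == 2) adm <- list(h("P3"))
    if (num == 3) adm <- list(h("P4"))
    if (num == 4) adm <- list(h("P3"), h("P4"))
    if (num == 5) adm <- list(list(target = "P4", donors = c("P3", "poolS"),
                                   when = "recent"))
    if (num == 6) adm <- list(list(target = "P3", donors = c("P4", "poolN"),
                                   when = "recent"))
    if (num == 7) adm <- list(list(target = "P4", donors = c("P3", "poolS"),
                                   when = "recent"),
                              list(target = "P3", donors = c("poolN", "poolS"),
                                   when = "recent"))
  } else if (set == "B") {
    if (num == 2) adm <- list(h("P5"))
    if (num == 3) adm <- list(h("P4"))
    if (num == 4) adm <- list(list(target = "P5", donors = c("P3", "P4"),
                                   when = "recent"))
    if (num == 5) adm <- list(list(target = "P4", donors = c("P3", "P5"),
                                   when = "recent"))
  } else {
    if (num == 2) adm <- list(h("P3"))
    if (num == 3) adm <- list(h("P5"))
    if (num == 4) adm <- list(list(target = "P5", donors = c("P3", "P4"),
                                   when = "recent"))
    if (num == 5) adm <- list(list(target = "P4", donors = c("P3", "P5"),
                                   when = "recent"))
  }
  structure(list(id = set_id, set = set, num = num, pops = pops,
                 admixture = adm, n_diploid = as.integer(n_diploid),
                 priors = priors),
            class = "scenario_graph")
}

#' @export
print.scenario_graph <- function(x, ...) {
  cat("scenario", x$id, ":", nrow(x$pops), "sampled populations (",
      sum(x$pops$role == "S"), "susceptible as 2 lineages each,",
      sum(x$pops$role == "R"), "resistant )\n")
  for (a in x$admixture)
    cat("  ", a$when, "admixture into", a$target, "from",
        paste(a$donors, collapse = " + "), "\n")
  invisible(x)
}

# demes of a scenario: susceptible pops contribute two lineages (_a, _b);
# resistant pops one deme; plus the two unsampled ancestral pools
.scenario_demes <- function(sc) {
  demes <- character(); pop_of <- character(); role <- character(); pool <- character()
  for (i in seq_len(nrow(sc$pops))) {
    p <- sc$pops$pop[i]
    if (sc$pops$role[i] == "S") {
      demes <- c(demes, paste0(p, "_a"), paste0(p, "_b"))
      pop_of <- c(pop_of, p, p)
      role <- c(role, "Slin", "Slin")
      pool <- c(pool, sc$pops$pool[i], sc$pops$pool[i])
    } else {
      demes <- c(demes, p); pop_of <- c(pop_of, p)
      role <- c(role, "R"); pool <- c(pool, sc$pops$pool[i])
    }
  }
  demes <- c(demes, "poolN", "poolS")
  pop_of <- c(pop_of, NA, NA)
  role <- c(role, "pool", "pool")
  pool <- c(pool, "N", "S")
  data.frame(deme = demes, pop = pop_of, role = role, pool = pool,
             stringsAsFactors = FALSE)
}

.recent_targets <- function(sc)
  vapply(Filter(function(a) a$when == "recent", sc$admixture),
         `[[`, "", "target")
.historical_targets <- function(sc)
  vapply(Filter(function(a) a$when == "historical", sc$admixture),
         `[[`, "", "target")

#' Draw scenario parameters from their priors
#'
#' Rejection-samples until the order constraints hold: every bottleneck start
#' exceeds its duration (t > b), divergence times exceed the corresponding
#' bottleneck starts, the root divergence t_a is the oldest event, admixture
#' events are younger than their donors' divergence times, and historical
#' admixture postdates (is older than) the target's bottleneck start.
#'
#' @param scenario a \code{\link{build_scenario}} object.
#' @param max_tries bound on rejection attempts.
#' @return A named list of parameter values (class \code{scenario_params}).
#' @export
draw_params <- function(scenario, max_tries = 1000L) {
  pr <- scenario$priors
  dm <- .scenario_demes(scenario)
  rec <- .recent_targets(scenario)
  hist <- .historical_targets(scenario)
  for (try in seq_len(max_tries)) {
    par <- list(Ne = .draw1(pr$Ne), mu = .draw1(pr$mu), gsm_p = .draw1(pr$gsm_p))
    ok <- TRUE
    tdivs <- numeric(0)
    for (i in which(dm$role %in% c("Slin", "R"))) {
      d <- dm$deme[i]
      if (d %in% rec) next  # no bottleneck parameters of its own
      t <- .draw1(pr$t_bot)
      par[[paste0("t_", d)]] <- t
      if (dm$role[i] == "R") {
        b <- .draw1(pr$b_dur)
        if (b >= t) { ok <- FALSE; break }
        par[[paste0("b_", d)]] <- b
        par[[paste0("Nr_", d)]] <- .draw1(pr$Nr)
      }
      par[[paste0("Nb_", d)]] <- .draw1(pr$Nb)
      if (!(d %in% hist)) {
        td <- .draw1(pr$t_div, lo = max(pr$t_div$lo, t))
        par[[paste0("tdiv_", d)]] <- td
        tdivs <- c(tdivs, td)
      }
    }
    if (!ok) next
    for (d in rec) par[[paste0("Nr_", d)]] <- .draw1(pr$Nr)
    par$ta <- .draw1(pr$t_div, lo = max(pr$t_div$lo, tdivs, 160))
    # admixture events
    prev_recent <- -Inf
    for (a in scenario$admixture) {
      if (a$when == "historical") {
        th <- .draw1(pr$t_hadm)
        if (th >= par$ta || th <= par[[paste0("t_", a$target)]]) { ok <- FALSE; break }
        par[[paste0("tadm_", a$target)]] <- th
      } else {
        tr <- .draw1(pr$t_radm)
        if (tr <= prev_recent) { ok <- FALSE; break }  # ordered multiple events
        prev_recent <- tr
        par[[paste0("tadm_", a$target)]] <- tr
      }
      par[[paste0("radm_", a$target)]] <- .draw1(pr$r_adm)
      # donors must still exist at the admixture time
      for (dn in a$donors) {
        td <- par[[paste0("tdiv_", dn)]]
        if (!is.null(td) && td <= par[[paste0("tadm_", a$target)]]) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok) return(structure(par, class = "scenario_params"))
  }
  stop("could not satisfy scenario constraints in ", max_tries, " tries")
}

# compile a scenario + parameter draw into the C++ demography encoding:
# sample sizes (gene copies), present-day sizes and the sorted event matrix
.compile_demography <- function(sc, par) {
  dm <- .scenario_demes(sc)
  D <- nrow(dm)
  id <- setNames(seq_len(D), dm$deme)
  rec <- .recent_targets(sc)
  half <- sc$n_diploid %/% 2L
  samp <- integer(D); init <- numeric(D)
  ev <- list()
  add <- function(time, type, a, b = 0L, x = 0) {
    ev[[length(ev) + 1L]] <<- c(time, type, a, b, x)
  }
  for (i in seq_len(D)) {
    d <- dm$deme[i]
    if (dm$role[i] == "Slin") {
      samp[i] <- 2L * (if (endsWith(d, "_a")) sc$n_diploid - half else half)
      init[i] <- par[[paste0("Nb_", d)]]
      add(par[[paste0("t_", d)]], 0, id[d], 0, par$Ne)
      add(par[[paste0("tdiv_", d)]], 1, id[d],
          id[paste0("pool", dm$pool[i])])
    } else if (dm$role[i] == "R") {
      samp[i] <- 2L * sc$n_diploid
      init[i] <- par[[paste0("Nr_", d)]]
      if (d %in% rec) {
        a <- Filter(function(a) a$target == d, sc$admixture)[[1]]
        tadm <- par[[paste0("tadm_", d)]]
        add(tadm, 2, id[d], id[a$donors[1]], par[[paste0("radm_", d)]])
        add(tadm, 1, id[d], id[a$donors[2]])
      } else {
        t <- par[[paste0("t_", d)]]; b <- par[[paste0("b_", d)]]
        add(t - b, 0, id[d], 0, par[[paste0("Nb_", d)]])
        add(t, 0, id[d], 0, par$Ne)
        if (d %in% .historical_targets(sc)) {
          a <- Filter(function(a) a$target == d, sc$admixture)[[1]]
          tadm <- par[[paste0("tadm_", d)]]
          add(tadm, 2, id[d], id[a$donors[1]], par[[paste0("radm_", d)]])
          add(tadm, 1, id[d], id[a$donors[2]])
        } else {
          add(par[[paste0("tdiv_", d)]], 1, id[d],
              id[paste0("pool", dm$pool[i])])
        }
      }
    } else {  # pool
      samp[i] <- 0L
      init[i] <- par$Ne
    }
  }
  add(par$ta, 1, id["poolS"], id["poolN"])
  events <- do.call(rbind, ev)
  events <- events[order(events[, 1]), , drop = FALSE]
  pop_labels <- rep(dm$pop[samp > 0], times = samp[samp > 0] / 2L)
  list(sample_sizes = samp, init_sizes = init, events = events,
       pop = pop_labels, demes = dm)
}

#' Simulate a microsatellite dataset under a demographic scenario
#'
#' Runs the backward-time structured coalescent per locus under the
#' scenario's size changes, splits and admixture events, then superimposes
#' generalized-stepwise-model mutations: counts Poisson(mu x branch length),
#' step sizes geometric with coefficient P (P(S = s) = (1-P) P^(s-1)),
#' direction equiprobable, allele states reflected into a 40-state window
#' with the root allele at state 20.  Diploid individuals pair two
#' independent gene copies from their deme; both lineages of a susceptible
#' population carry its population label.
#'
#' @param scenario a \code{\link{build_scenario}} object.
#' @param params a \code{\link{draw_params}} draw (or compatible list).
#' @param n_loci number of microsatellite loci.
#' @return A \code{\link{genotype_matrix}} with populations P1, P2, ...
#' @export
simulate_dataset <- function(scenario, params, n_loci = 12L) {
  cd <- .compile_demography(scenario, params)
  mat <- .sim_loci_cpp(cd$sample_sizes, cd$init_sizes, cd$events,
                       as.integer(n_loci), params$mu, params$gsm_p)
  odd <- seq(1, nrow(mat), by = 2)
  genotype_matrix(mat[odd, , drop = FALSE], mat[odd + 1, , drop = FALSE],
                  pop = factor(cd$pop, levels = unique(cd$pop)))
}
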