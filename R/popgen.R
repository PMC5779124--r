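#' Per-locus diversity and differentiation summaries
#'
#' For each locus: total allele count, observed heterozygosity, within- and
#' overall expected heterozygosity (Nei unbiased gene diversity), and the
#' Weir-Cockerham (1984) F_IS and F_ST with randomization p-values.
#' Multi-locus F-statistics are ratios of summed variance components, not
#' averages of per-locus ratios.  F_IS significance permutes alleles among
#' individuals within populations; F_ST significance permutes whole
#' multilocus genotypes among populations (random mating not assumed).
#' Monomorphic loci report \code{NA} F-statistics.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param n_perm randomizations for the p-values (0 disables).
#' @return A data.frame with one row per locus plus an \code{"overall"} row,
#'   columns \code{locus, T_A, H_O, H_S, H_T, F_IS, F_ST, p_FIS, p_FST}.
#' @export
locus_summaries <- function(G, n_perm = 1000L) {
  pi <- pop_index(G)
  L <- n_loci(G)
  comp <- .wc_components_cpp(G$a1, G$a2, pi$idx, pi$k)
  het <- .locus_het(G)
  fis <- 1 - comp[, 3] / (comp[, 2] + comp[, 3])
  fst <- if (pi$k >= 2) comp[, 1] / rowSums(comp) else rep(NA_real_, L)
  tot <- colSums(rbind(comp))
  overall_fis <- 1 - tot[3] / (tot[2] + tot[3])
  overall_fst <- if (pi$k >= 2) tot[1] / sum(tot) else NA_real_
  p_fis <- p_fst <- rep(NA_real_, L)
  if (n_perm > 0) {
    p_fis <- .perm_fis_pvalues(G, n_perm)
    if (pi$k >= 2) p_fst <- .perm_fst_pvalues(G, n_perm)
  }
  out <- data.frame(
    locus = c(G$loci, "overall"),
    T_A = c(het$TA, sum(het$TA)),
    H_O = c(het$HO, mean(het$HO, na.rm = TRUE)),
    H_S = c(het$HS, mean(het$HS, na.rm = TRUE)),
    H_T = c(het$HT, mean(het$HT, na.rm = TRUE)),
    F_IS = c(fis, overall_fis),
    F_ST = c(fst, overall_fst),
    p_FIS = c(p_fis, NA_real_),
    p_FST = c(p_fst, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# per-locus allele totals and heterozygosities; HS = mean over populations of
# Nei-Chesser unbiased within-population gene diversity, HT from pooled
# frequencies (unbiased)
.locus_het <- function(G) {
  L <- n_loci(G)
  pops <- levels(G$pop)
  TA <- integer(L); HO <- HS <- HT <- numeric(L)
  for (l in seq_len(L)) {
    x <- G$a1[, l]; y <- G$a2[, l]
    ok <- !is.na(x)
    TA[l] <- length(unique(c(x[ok], y[ok])))
    HO[l] <- mean((x != y)[ok])
    hs <- vapply(pops, function(p) {
      s <- ok & G$pop == p
      nn <- sum(s)
      if (nn < 2) return(NA_real_)
      f <- table(c(x[s], y[s])) / (2 * nn)
      ho <- mean((x != y)[s])
      nn / (nn - 1) * (1 - sum(f^2) - ho / (2 * nn))
    }, 0)
    HS[l] <- mean(hs, na.rm = TRUE)
    NN <- sum(ok)
    if (NN >= 2) {
      f <- table(c(x[ok], y[ok])) / (2 * NN)
      HT[l] <- NN / (NN - 1) * (1 - sum(f^2) - HO[l] / (2 * NN))
    } else HT[l] <- NA_real_
  }
  # monomorphic loci: diversity 0 by definition
  mono <- TA <= 1L
  HO[mono] <- 0; HS[mono] <- 0; HT[mono] <- 0
  list(TA = TA, HO = HO, HS = HS, HT = HT)
}

.multilocus_fst <- function(a1, a2, idx, k) {
  comp <- .wc_components_cpp(a1, a2, idx, k)
  tot <- colSums(comp, na.rm = TRUE)
  if (sum(tot) == 0) return(NA_real_)
  tot[1] / sum(tot)
}

.perm_fst_pvalues <- function(G, n_perm) {
  pi <- pop_index(G)
  L <- n_loci(G)
  obs_comp <- .wc_components_cpp(G$a1, G$a2, pi$idx, pi$k)
  obs <- obs_comp[, 1] / rowSums(obs_comp)
  ge <- integer(L)
  for (b in seq_len(n_perm)) {
    idx <- sample(pi$idx)
    comp <- .wc_components_cpp(G$a1, G$a2, idx, pi$k)
    stat <- comp[, 1] / rowSums(comp)
    ge <- ge + as.integer(!is.na(stat) & !is.na(obs) & stat >= obs)
  }
  p <- (1 + ge) / (n_perm + 1)
  p[is.na(obs)] <- NA_real_
  p
}

# permute alleles among individuals within each population (F_IS null)
.perm_fis_pvalues <- function(G, n_perm) {
  pi <- pop_index(G)
  L <- n_loci(G)
  comp <- .wc_components_cpp(G$a1, G$a2, pi$idx, pi$k)
  obs <- 1 - comp[, 3] / (comp[, 2] + comp[, 3])
  ge <- integer(L)
  n <- n_ind(G)
  for (b in seq_len(n_perm)) {
    b1 <- G$a1; b2 <- G$a2
    for (p in seq_len(pi$k)) {
      rows <- which(pi$idx == p)
      for (l in seq_len(L)) {
        pool <- c(b1[rows, l], b2[rows, l])
        pool <- sample(pool)
        b1[rows, l] <- pool[seq_along(rows)]
        b2[rows, l] <- pool[length(rows) + seq_along(rows)]
      }
    }
    cb <- .wc_components_cpp(b1, b2, pi$idx, pi$k)
    stat <- 1 - cb[, 3] / (cb[, 2] + cb[, 3])
    ge <- ge + as.integer(!is.na(stat) & !is.na(obs) & stat >= obs)
  }
  p <- (1 + ge) / (n_perm + 1)
  p[is.na(obs)] <- NA_real_
  p
}

#' Permutation test for multilocus F_ST
#'
#' Permutes whole multilocus diploid genotypes among populations (random
#' mating within populations is not assumed), recomputes the multilocus
#' Weir-Cockerham F_ST and returns the upper-tail p-value
#' \code{(1 + #permuted >= observed) / (n_perm + 1)}.
#'
#' @param G a \code{\link{genotype_matrix}} with >= 2 populations.
#' @param n_perm number of permutations (>= 1).
#' @return A list with \code{fst} (observed) and \code{p}.
#' @export
permute_for_fst <- function(G, n_perm = 1000L) {
  if (n_perm <= 0) stop("n_perm must be positive")
  pi <- pop_index(G)
  if (pi$k < 2) stop("need at least two populations")
  obs <- .multilocus_fst(G$a1, G$a2, pi$idx, pi$k)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    stat <- .multilocus_fst(G$a1, G$a2, sample(pi$idx), pi$k)
    if (!is.na(stat) && stat >= obs) ge <- ge + 1L
  }
  list(fst = obs, p = (1 + ge) / (n_perm + 1))
}

#' Per-population diversity summaries
#'
#' Sample size, rarefied allelic richness, unbiased expected and observed
#' heterozygosity, the within-population Weir-Cockerham F_IS, and the
#' selfing rate s = 2 F_IS / (1 + F_IS).  Allelic richness uses hypergeometric
#' rarefaction to a common number of gene copies (by default twice the
#' smallest per-population complete-genotype count over loci), averaged over
#' loci.  Populations monomorphic across loci report \code{NA} F_IS and s.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param rarefaction_n rarefaction size in diploid individuals, or
#'   \code{"auto"}.
#' @return A data.frame with one row per population.
#' @export
population_summaries <- function(G, rarefaction_n = "auto") {
  pops <- levels(G$pop)
  L <- n_loci(G)
  counts <- vapply(pops, function(p) {
    min(vapply(seq_len(L), function(l) sum(!is.na(G$a1[G$pop == p, l])), 0L))
  }, 0L)
  if (identical(rarefaction_n, "auto")) {
    rarefaction_n <- min(counts[counts > 0])
  } else {
    rarefaction_n <- as.integer(rarefaction_n)
    if (rarefaction_n > min(counts[counts > 0]))
      stop("rarefaction_n exceeds the smallest complete-genotype count")
  }
  g2 <- 2L * rarefaction_n
  out <- lapply(pops, function(p) {
    rows <- which(G$pop == p)
    A <- HE <- numeric(0)
    ho_all <- numeric(0)
    for (l in seq_len(L)) {
      x <- G$a1[rows, l]; y <- G$a2[rows, l]
      ok <- !is.na(x)
      nn <- sum(ok)
      if (nn == 0) next
      cnt <- table(c(x[ok], y[ok]))
      N <- 2 * nn
      A <- c(A, sum(1 - exp(lchoose(N - cnt, g2) - lchoose(N, g2))))
      f <- cnt / N
      ho <- mean((x != y)[ok])
      HE <- c(HE, if (nn >= 2) nn / (nn - 1) * (1 - sum(f^2) - ho / N) else NA_real_)
      ho_all <- c(ho_all, ho)
    }
    sub <- subset_genotypes(G, pops = p)
    comp <- .wc_components_cpp(sub$a1, sub$a2, rep(1L, n_ind(sub)), 1L)
    tot <- colSums(comp, na.rm = TRUE)
    fis <- if (all(is.na(comp[, 3])) || (tot[2] + tot[3]) == 0) NA_real_ else
      1 - tot[3] / (tot[2] + tot[3])
    data.frame(population = p, n = length(rows),
               A = mean(A), H_E = mean(HE, na.rm = TRUE),
               H_O = mean(ho_all, na.rm = TRUE),
               F_IS = fis,
               s = if (is.na(fis)) NA_real_ else selfing_rate(fis),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Selfing rate from the inbreeding coefficient
#'
#' At inbreeding equilibrium under partial self-fertilization,
#' F_IS = s / (2 - s), hence s = 2 F_IS / (1 + F_IS).
#'
#' @param fis inbreeding coefficient(s) in (-1, 1].
#' @return Selfing rate(s); strictly increasing in F_IS.
#' @export
selfing_rate <- function(fis) {
  if (any(!is.na(fis) & fis <= -1))
    stop("selfing rate undefined for F_IS <= -1")
  2 * fis / (1 + fis)
}

#' Nei (1972) standard genetic distance between all population pairs
#'
#' D = -ln( J_xy / sqrt(J_x J_y) ) with gene identities summed over loci.
#' Pairs sharing no allele at any locus have infinite distance and are
#' returned as \code{Inf}.  Optional locus bootstrap (resampling loci with
#' replacement) supports downstream tree confidence.
#'
#' @param G a \code{\link{genotype_matrix}} with >= 2 populations.
#' @param n_boot bootstrap replicates over loci (0 disables).
#' @return A list of class \code{nei_distance}: \code{D} (symmetric matrix,
#'   zero diagonal) and \code{boot} (array pair x pair x replicate or
#'   \code{NULL}).
#' @export
nei_distance_matrix <- function(G, n_boot = 0L) {
  pops <- levels(G$pop)
  if (length(pops) < 2) stop("need at least two populations")
  fr <- .allele_freq_list(G)
  nei_from <- function(loci) {
    k <- length(pops)
    Jx <- numeric(k); Jxy <- matrix(0, k, k)
    for (l in loci) {
      f <- fr[[l]]
      Jx <- Jx + colSums(f^2)
      Jxy <- Jxy + crossprod(f)
    }
    D <- matrix(0, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      I <- Jxy[i, j] / sqrt(Jx[i] * Jx[j])
      D[i, j] <- D[j, i] <- if (I <= 0) Inf else max(0, -log(I))
    }
    D
  }
  L <- n_loci(G)
  D <- nei_from(seq_len(L))
  boot <- NULL
  if (n_boot > 0) {
    boot <- array(NA_real_, c(length(pops), length(pops), n_boot),
                  dimnames = list(pops, pops, NULL))
    for (b in seq_len(n_boot))
      boot[, , b] <- nei_from(sample.int(L, L, replace = TRUE))
  }
  structure(list(D = D, boot = boot), class = "nei_distance")
}

# allele frequency matrices per locus (allele x population), zero-filled
.allele_freq_list <- function(G) {
  pops <- levels(G$pop)
  lapply(seq_len(n_loci(G)), function(l) {
    x <- G$a1[, l]; y <- G$a2[, l]
    ok <- !is.na(x)
    alleles <- sort(unique(c(x[ok], y[ok])))
    f <- matrix(0, length(alleles), length(pops),
                dimnames = list(alleles, pops))
    for (p in seq_along(pops)) {
      s <- ok & G$pop == pops[p]
      if (!any(s)) next
      cnt <- table(factor(c(x[s], y[s]), levels = alleles))
      f[, p] <- cnt / sum(cnt)
    }
    f
  })
}

#' Pairwise multilocus F_ST with permutation significance
#'
#' Weir-Cockerham multilocus F_ST for every population pair; significance by
#' permuting multilocus genotypes among the two populations, Bonferroni
#' correction across all pairs tested.
#'
#' @param G a \code{\link{genotype_matrix}} with >= 2 populations.
#' @param n_perm permutations per pair (0 disables testing).
#' @param alpha family-wise significance level before Bonferroni division.
#' @return A list of class \code{pairwise_fst}: \code{fst} matrix, \code{p}
#'   matrix, logical \code{significant} matrix (after Bonferroni), and
#'   \code{n_tests}.
#' @export
pairwise_fst <- function(G, n_perm = 1000L, alpha = 0.05) {
  pi <- pop_index(G)
  if (pi$k < 2) stop("need at least two populations")
  fst <- .pairwise_fst_cpp(G$a1, G$a2, pi$idx, pi$k)
  dimnames(fst) <- list(pi$labels, pi$labels)
  n_tests <- pi$k * (pi$k - 1) / 2
  p <- matrix(NA_real_, pi$k, pi$k, dimnames = dimnames(fst))
  if (n_perm > 0) {
    for (i in seq_len(pi$k - 1)) for (j in (i + 1):pi$k) {
      sub <- subset_genotypes(G, pops = pi$labels[c(i, j)])
      p[i, j] <- p[j, i] <- permute_for_fst(sub, n_perm)$p
    }
  }
  structure(list(fst = fst, p = p,
                 significant = !is.na(p) & p < alpha / n_tests,
                 n_tests = n_tests),
            class = "pairwise_fst")
}

#' Garza-Williamson M ratio
#'
#' M = k / (r + 1) per population and locus, where k is the number of alleles
#' and r the allele-size range in repeat units; monomorphic loci give M = 1.
#' Depressed M indicates a past bottleneck.
#'
#' @param G a \code{\link{genotype_matrix}} (allele states in repeat units).
#' @return A list: \code{per_locus} (population x locus matrix) and
#'   \code{mean} (per-population mean over loci).
#' @export
gw_m <- function(G) {
  pops <- levels(G$pop)
  L <- n_loci(G)
  m <- matrix(NA_real_, length(pops), L, dimnames = list(pops, G$loci))
  for (p in seq_along(pops)) for (l in seq_len(L)) {
    s <- G$pop == pops[p] & !is.na(G$a1[, l])
    if (!any(s)) next
    al <- c(G$a1[s, l], G$a2[s, l])
    m[p, l] <- length(unique(al)) / (diff(range(al)) + 1)
  }
  list(per_locus = m, mean = rowMeans(m, na.rm = TRUE))
}

#' Mean genic diversity and allele-size variance per population
#'
#' Unbiased gene diversity (Nei 1987) and the sample variance of allele size,
#' per locus and averaged over loci.  These are the held-out test statistics
#' of the posterior predictive model check.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return A data.frame: population, \code{genic_diversity},
#'   \code{size_variance}.
#' @export
genic_diversity_and_size_variance <- function(G) {
  pi <- pop_index(G)
  m <- .gendiv_sizevar_cpp(G$a1, G$a2, pi$idx, pi$k)
  data.frame(population = pi$labels,
             genic_diversity = m[, 1], size_variance = m[, 2],
             stringsAsFactors = FALSE)
}

#' Mean individual assignment log-likelihoods between populations
#'
#' Rannala-Mountain assignment: the log-likelihood of each individual's
#' multilocus genotype under the posterior-mean allele frequencies of a
#' reference population (Dirichlet(1/k) prior, k = number of alleles at the
#' locus), leave-one-out when the reference is the individual's own
#' population; averaged over individuals for every ordered population pair.
#'
#' @param G a \code{\link{genotype_matrix}} with >= 2 populations.
#' @return A matrix (origin population x reference population) of mean
#'   log-likelihoods.
#' @export
assignment_likelihood <- function(G) {
  pi <- pop_index(G)
  if (pi$k < 2) stop("need at least two populations")
  m <- .assign_loglik_cpp(G$a1, G$a2, pi$idx, pi$k)
  dimnames(m) <- list(pi$labels, pi$labels)
  m
}

#' Shared allele distance between populations
#'
#' DAS = 1 - mean proportion of alleles shared between cross-population
#' individual pairs, averaged over loci and pairs (Chakraborty-Jin).
#'
#' @param G a \code{\link{genotype_matrix}} with >= 2 populations.
#' @return A symmetric matrix with zero diagonal.
#' @export
shared_allele_distance <- function(G) {
  pi <- pop_index(G)
  if (pi$k < 2) stop("need at least two populations")
  m <- .das_cpp(G$a1, G$a2, pi$idx, pi$k)
  dimnames(m) <- list(pi$labels, pi$labels)
  m
}

#' Write a distance matrix in PHYLIP lower-triangular format
#'
#' For external least-squares or neighbor-joining tree programs.  Infinite
#' sentinel distances are written as a large finite value (999.9999).
#'
#' @param D a square symmetric numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(D, path) {
  k <- nrow(D)
  D[!is.finite(D)] <- 999.9999
  lab <- sprintf("%-10s", substr(rownames(D), 1, 10))
  out <- sprintf("%5d", k)
  for (i in seq_len(k)) {
    row <- if (i == 1) "" else paste(sprintf("%9.6f", D[i, seq_len(i - 1)]),
                                     collapse = " ")
    out <- c(out, trimws(paste(lab[i], row), which = "right"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Per-population selfing rates with the single-lineage variant convention
#'
#' Computes s = 2 F_IS / (1 + F_IS) per population.  In an essentially
#' clonal population -- one dominant multilocus genotype plus a few rare
#' variants of it -- the only heterozygosity comes from fresh mutations or
#' residual heterozygous tracts within the same selfing lineage, and the raw
#' F_IS collapses toward 0 even though the population is a single lineage.
#' Following standard practice for selfing-weed surveys, with
#' \code{adjust_single_lineage = TRUE} (default) such populations (dominant
#' MLG at frequency >= \code{dominant_min}, every minor MLG differing from
#' it at no more than one locus) have their observed heterozygosity treated
#' as zero, giving s = 1.  Populations with no polymorphism at all report
#' \code{NA}.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param adjust_single_lineage apply the convention above.
#' @param dominant_min minimum frequency of the dominant MLG.
#' @return A named numeric vector of selfing rates per population.
#' @export
selfing_rates <- function(G, adjust_single_lineage = TRUE,
                          dominant_min = 0.8) {
  ps <- population_summaries(G, rarefaction_n = 1)
  s <- setNames(ps$s, ps$population)
  if (!adjust_single_lineage) return(s)
  for (p in names(s)) {
    if (is.na(s[p]) || s[p] == 1) next
    sub <- subset_genotypes(G, pops = p)
    m <- identify_mlgs(sub)
    if (nrow(m$mlgs) < 2) next
    cnt <- m$counts[, p]
    top <- which.max(cnt)
    if (cnt[top] / sum(cnt) < dominant_min) next
    split_loci <- function(gs) strsplit(gs, ";", fixed = TRUE)[[1]]
    topg <- split_loci(m$mlgs$genotype[top])
    one_locus <- vapply(m$mlgs$genotype[-top], function(gs)
      sum(split_loci(gs) != topg) <= 1L, TRUE)
    if (all(one_locus)) s[p] <- 1
  }
  s
}
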