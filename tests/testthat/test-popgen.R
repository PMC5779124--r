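test_that("Weir-Cockerham components equal the literal variance-components oracle", {
  set.seed(11)
  for (rep in 1:12) {
    G <- random_genotypes(npop = sample(1:4, 1), n = sample(3:10, 1),
                          L = sample(1:4, 1), k = sample(2:5, 1),
                          miss = sample(c(0, 0.1), 1))
    pi <- ssrabc:::pop_index(G)
    got <- ssrabc:::.wc_components_cpp(G$a1, G$a2, pi$idx, pi$k)
    want <- wc_oracle(G)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("frozen W&C values: HWE-shaped toy and fixed difference", {
  # 1 AA, 2 Aa, 1 aa in one population: the small-sample W&C estimator gives
  # F_IS = 1/7, not 0 (finite-sample correction)
  G <- toy_genotypes(p = c("10/10", "10/11", "10/11", "11/11"))
  comp <- ssrabc:::.wc_components_cpp(G$a1, G$a2, rep(1L, 4), 1L)
  expect_equal(1 - comp[3] / (comp[2] + comp[3]), 1 / 7, tolerance = 1e-12)
  # two populations fixed for different alleles, all homozygous: F_ST = 1
  G2 <- toy_genotypes(p1 = rep("10/10", 4), p2 = rep("12/12", 4))
  s <- locus_summaries(G2, n_perm = 0)
  expect_equal(s$F_ST[1], 1)
})

test_that("pooled identical populations give non-positive mean F_ST", {
  set.seed(12)
  vals <- replicate(60, {
    a <- matrix(sample(c(10L, 11L), 40 * 3, replace = TRUE), 40, 3)
    b <- matrix(sample(c(10L, 11L), 40 * 3, replace = TRUE), 40, 3)
    G <- genotype_matrix(a, b, pop = rep(c("x", "y"), each = 20))
    pi <- ssrabc:::pop_index(G)
    ssrabc:::.multilocus_fst(G$a1, G$a2, pi$idx, pi$k)
  })
  expect_lte(mean(vals), 0.005)
})

test_that("monomorphic loci report zero diversity and missing F-statistics", {
  G <- toy_genotypes(p1 = c("10/10;5/6", "10/10;5/5"),
                     p2 = c("10/10;6/6", "10/10;5/6"))
  s <- locus_summaries(G, n_perm = 0)
  expect_equal(s$H_S[1], 0)
  expect_equal(s$H_O[1], 0)
  expect_true(is.na(s$F_IS[1]) && is.na(s$F_ST[1]))
  expect_false(is.na(s$F_ST[2]))
})

test_that("selfing rate formula, bounds and monotonicity", {
  expect_equal(round(selfing_rate(0.837), 3), 0.911)
  expect_equal(round(selfing_rate(0.629), 3), 0.772)
  expect_equal(selfing_rate(0), 0)
  expect_equal(selfing_rate(1), 1)
  expect_error(selfing_rate(-1), "undefined")
  x <- seq(-0.99, 1, by = 0.01)
  expect_true(all(diff(selfing_rate(x)) > 0))
})

test_that("rarefied allelic richness equals the exhaustive subsampling oracle", {
  # one population, one locus with gene copies 4 x allele a, 2 x allele b:
  # 3 individuals 10/10, 10/11, 10/11 -> copies (10,10,10,11,10,11)
  G <- toy_genotypes(p = c("10/10", "10/11", "10/11"))
  ps <- population_summaries(G, rarefaction_n = 2)
  copies <- c(G$a1[, 1], G$a2[, 1])
  expect_equal(ps$A, rarefaction_oracle(copies, 4), tolerance = 1e-12)
  # monomorphic population: A = 1, H_E = H_O = 0
  Gm <- toy_genotypes(p = rep("10/10", 5))
  psm <- population_summaries(Gm)
  expect_equal(psm$A, 1)
  expect_equal(psm$H_E, 0)
  expect_equal(psm$H_O, 0)
  expect_true(is.na(psm$F_IS) && is.na(psm$s))
})

test_that("population summaries reproduce the equilibrium selfing chain", {
  # F_IS = 0.837 gives s = 0.911 through the same path used for survey data
  expect_equal(round(selfing_rate(0.837), 3), 0.911)
  # and the per-population F_IS feeds s: highly inbred toy
  G <- toy_genotypes(p = c("10/10;7/7", "10/10;7/7", "11/11;8/8",
                           "11/11;8/8", "10/11;7/8"))
  ps <- population_summaries(G)
  expect_equal(ps$s, selfing_rate(ps$F_IS))
})

test_that("Nei 1972 distance: hand value, zero and infinite sentinels", {
  # pop1 fixed for allele 10; pop2 at 0.5/0.5 for alleles 10/11:
  # D = -ln(0.5 / sqrt(1 * 0.5)) = 0.34657
  G <- toy_genotypes(p1 = rep("10/10", 4),
                     p2 = c("10/10", "10/10", "11/11", "11/11"))
  nd <- nei_distance_matrix(G)
  expect_equal(nd$D["p1", "p2"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(diag(nd$D), c(p1 = 0, p2 = 0))
  expect_equal(nd$D, t(nd$D))
  # identical frequencies -> 0
  Gi <- toy_genotypes(p1 = c("10/10", "11/11"), p2 = c("10/10", "11/11"))
  expect_equal(nei_distance_matrix(Gi)$D["p1", "p2"], 0)
  # disjoint allele sets -> infinite sentinel
  Gd <- toy_genotypes(p1 = rep("10/10", 3), p2 = rep("12/12", 3))
  expect_true(is.infinite(nei_distance_matrix(Gd)$D["p1", "p2"]))
})

test_that("locus bootstrap over loci has the right shape", {
  set.seed(13)
  G <- random_genotypes(3, 8, 5)
  nd <- nei_distance_matrix(G, n_boot = 25)
  expect_equal(dim(nd$boot), c(3, 3, 25))
  expect_true(all(nd$boot[!is.infinite(nd$boot)] >= 0))
})

test_that("Garza-Williamson M follows k/(r+1)", {
  G <- toy_genotypes(p = c("10/11", "11/12", "10/12"))  # alleles 10,11,12
  expect_equal(unname(gw_m(G)$mean), 1)
  G2 <- toy_genotypes(p = c("10/10", "12/12"))          # k=2, range 2
  expect_equal(unname(gw_m(G2)$mean), 2 / 3)
  G3 <- toy_genotypes(p = rep("10/10", 3))
  expect_equal(unname(gw_m(G3)$mean), 1)
})

test_that("genic diversity and size variance match hand arithmetic and brute force", {
  # two equifrequent alleles, 2 individuals: (2n/(2n-1)) (1 - 0.5) = 2/3
  G <- toy_genotypes(p = c("10/12", "10/12"))
  gv <- genic_diversity_and_size_variance(G)
  expect_equal(gv$genic_diversity, 2 / 3, tolerance = 1e-12)
  expect_equal(gv$size_variance, stats::var(c(10, 12, 10, 12)), tolerance = 1e-12)
  Gm <- toy_genotypes(p = rep("10/10", 4))
  gvm <- genic_diversity_and_size_variance(Gm)
  expect_equal(gvm$genic_diversity, 0)
  expect_equal(gvm$size_variance, 0)
  # brute force on random tiny matrices
  set.seed(14)
  for (i in 1:5) {
    Gr <- random_genotypes(2, 5, 3, k = 3)
    got <- genic_diversity_and_size_variance(Gr)
    for (p in 1:2) {
      rows <- Gr$pop == paste0("p", p)
      gd <- sv <- numeric(0)
      for (l in 1:3) {
        copies <- c(Gr$a1[rows, l], Gr$a2[rows, l])
        N <- length(copies)
        f <- table(copies) / N
        gd <- c(gd, N / (N - 1) * (1 - sum(f^2)))
        sv <- c(sv, stats::var(copies))
      }
      expect_equal(got$genic_diversity[p], mean(gd), tolerance = 1e-12)
      expect_equal(got$size_variance[p], mean(sv), tolerance = 1e-12)
    }
  }
})

test_that("assignment likelihood: hand oracle, prior positivity, self > cross", {
  # one locus: pop1 = {10/10, 10/11}, pop2 = {12/12, 12/12}
  G <- toy_genotypes(p1 = c("10/10", "10/11"), p2 = c("12/12", "12/12"))
  al <- assignment_likelihood(G)
  # hand: alleles {10,11,12}, k=3; ind1 (10/10) vs pop2: counts 0 of 4,
  # p = (0 + 1/3)/5; loglik = 2*log(1/15)
  ll_1_2 <- 2 * log((1 / 3) / 5)
  # ind2 (10/11) vs pop2: log(2 * 1/15 * 1/15)
  ll_2_2 <- log(2 * (1 / 15)^2)
  expect_equal(al["p1", "p2"], mean(c(ll_1_2, ll_2_2)), tolerance = 1e-12)
  # leave-one-out diagonal, hand-computed: ind1 vs own pop minus itself:
  # remaining copies (10,11), p10 = (1+1/3)/3; ind2: remaining (10,10),
  # p10 = (2+1/3)/3, p11 = (0+1/3)/3
  ll_1_1 <- 2 * log((1 + 1 / 3) / 3)
  ll_2_1 <- log(2 * ((2 + 1 / 3) / 3) * ((1 / 3) / 3))
  expect_equal(al["p1", "p1"], mean(c(ll_1_1, ll_2_1)), tolerance = 1e-12)
  # absent alleles keep finite likelihood
  expect_true(all(is.finite(al)))
  # diverged populations: self-assignment beats cross-assignment
  set.seed(15)
  a <- matrix(sample(10:12, 60, TRUE), 20, 3)
  b <- matrix(sample(18:20, 60, TRUE), 20, 3)
  Gd <- genotype_matrix(rbind(a, b), rbind(a, b),
                        pop = rep(c("x", "y"), each = 20))
  ald <- assignment_likelihood(Gd)
  expect_gt(ald["x", "x"], ald["x", "y"])
  expect_gt(ald["y", "y"], ald["y", "x"])
})

test_that("shared allele distance: limits and brute force", {
  Gi <- toy_genotypes(p1 = c("10/11;7/7"), p2 = c("10/11;7/7"))
  expect_equal(shared_allele_distance(Gi)["p1", "p2"], 0)
  Gd <- toy_genotypes(p1 = c("10/10;7/7"), p2 = c("12/12;9/9"))
  expect_equal(shared_allele_distance(Gd)["p1", "p2"], 1)
  set.seed(16)
  G <- random_genotypes(2, 4, 3, k = 3)
  das <- shared_allele_distance(G)["p1", "p2"]
  share_pair <- function(g1, g2) {
    shared <- sum(vapply(unique(c(g1, g2)), function(a)
      min(sum(g1 == a), sum(g2 == a)), 0))
    shared / 2
  }
  acc <- c()
  for (i in which(G$pop == "p1")) for (j in which(G$pop == "p2"))
    for (l in 1:3)
      acc <- c(acc, share_pair(c(G$a1[i, l], G$a2[i, l]),
                               c(G$a1[j, l], G$a2[j, l])))
  expect_equal(das, 1 - mean(acc), tolerance = 1e-12)
})

test_that("heterozygosities and distances respect their ranges", {
  set.seed(17)
  for (i in 1:5) {
    G <- random_genotypes(3, 8, 4, k = 5, miss = 0.05)
    s <- locus_summaries(G, n_perm = 0)
    expect_true(all(s$H_O >= 0 & s$H_O <= 1, na.rm = TRUE))
    expect_true(all(s$H_S >= 0 & s$H_S <= 1, na.rm = TRUE))
    expect_true(all(s$H_T >= 0 & s$H_T <= 1, na.rm = TRUE))
    das <- shared_allele_distance(G)
    expect_true(all(das >= 0 & das <= 1))
    expect_equal(das, t(das))
  }
})

test_that("PHYLIP export writes a readable lower-triangular matrix", {
  D <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile(fileext = ".phy")
  write_phylip(D, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 2)
  expect_match(lines[3], "0\\.2")
})
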