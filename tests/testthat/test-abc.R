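test_that("summary vector is deterministic and consistent across modules", {
  set.seed(51)
  G <- random_genotypes(3, 10, 4, k = 4)
  s <- abc_summary_stats(G)
  # cross-module consistency: the vector equals independently computed stats
  expect_equal(unname(s["M_p1"]), unname(gw_m(G)$mean["p1"]))
  pf <- pairwise_fst(G, n_perm = 0)
  expect_equal(unname(s["FST_p1.p2"]), unname(pf$fst["p1", "p2"]))
  al <- assignment_likelihood(G)
  expect_equal(unname(s["AL_p2.p1"]), unname(al["p2", "p1"]))
  k_manual <- mean(vapply(1:4, function(l) {
    rows <- G$pop == "p1"
    length(unique(c(G$a1[rows, l], G$a2[rows, l])))
  }, 0))
  expect_equal(unname(s["NAL_p1"]), k_manual)
  # held-out model-check statistics never enter the selection vector
  expect_false(any(grepl("^GD_|^VAR_|^DAS_", names(s))))
})

test_that("monomorphic data yields unit allele counts and imputed zero F_ST", {
  G <- toy_genotypes(p1 = rep("20/20", 4), p2 = rep("20/20", 4))
  s <- abc_summary_stats(G)
  expect_equal(unname(s["NAL_p1"]), 1)
  expect_equal(unname(s["M_p2"]), 1)
  expect_equal(unname(s["FST_p1.p2"]), 0)  # undefined, imputed finite
  expect_true(all(is.finite(s)))
})

test_that("reference tables are shaped and seed-reproducible", {
  scens <- list(B1 = build_scenario("B1", n_diploid = 6L),
                B4 = build_scenario("B4", n_diploid = 6L))
  set.seed(52); r1 <- build_reference_table(scens, 30, n_loci = 4)
  set.seed(52); r2 <- build_reference_table(scens, 30, n_loci = 4)
  expect_equal(nrow(r1$stats), 60)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$params, r2$params)
  expect_error(build_reference_table(scens, 0), ">= 1")
  # scenario means differ between admixed and independent histories
  expect_false(isTRUE(all.equal(
    colMeans(r1$stats[r1$scenario == "B1", ]),
    colMeans(r1$stats[r1$scenario == "B4", ]))))
})

test_that("posteriors sum to one and split evenly for duplicated scenarios", {
  set.seed(53)
  scens <- list(X = build_scenario("B1", n_diploid = 8L),
                Y = build_scenario("B1", n_diploid = 8L))
  ref <- build_reference_table(scens, 150, n_loci = 6)
  G <- simulate_dataset(scens$X, draw_params(scens$X), 6)
  post <- scenario_posterior(ref, abc_summary_stats(G), 60)
  expect_equal(sum(post$table$posterior), 1, tolerance = 1e-9)
  expect_true(all(post$table$ci_lo <= post$table$posterior + 1e-9))
  expect_true(all(post$table$ci_hi >= post$table$posterior - 1e-9))
  # exchangeable scenarios split evenly on average (single fits fluctuate
  # at this desk scale)
  ps <- replicate(10, {
    Gk <- simulate_dataset(scens$X, draw_params(scens$X), 6)
    scenario_posterior(ref, abc_summary_stats(Gk), 60)$table$posterior[1]
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_error(scenario_posterior(ref, abc_summary_stats(G), 1e6),
               "exceeds")
})

test_that("well-separated scenarios are recovered with high posterior", {
  set.seed(54)
  scens <- list(B1 = build_scenario("B1"), B4 = build_scenario("B4"))
  ref <- build_reference_table(scens, 500, n_loci = 12)
  hits <- 0
  for (i in 1:5) {
    G <- simulate_dataset(scens$B4, draw_params(scens$B4), 12)
    post <- scenario_posterior(ref, abc_summary_stats(G), 100)
    if (post$table$posterior[post$table$scenario == "B4"] > 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the compiled multinomial logit matches nnet::multinom", {
  skip_if_not_installed("nnet")
  set.seed(55)
  n <- 400
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  beta <- matrix(c(0.3, 1, -1, 0.5, -0.2, -1, 1, 0.3), 4, 2)
  eta <- cbind(X %*% beta, 0)
  p <- exp(eta) / rowSums(exp(eta))
  y <- apply(p, 1, function(q) sample(1:3, 1, prob = q))
  w <- runif(n, 0.5, 1.5)
  fit <- ssrabc:::.multinom_irls_cpp(X, as.integer(y), w, 3L, ridge = 0)
  d <- data.frame(y = factor(y), X[, -1])
  nn <- nnet::multinom(y ~ ., data = d, weights = w, trace = FALSE,
                       reltol = 1e-12)
  # compare fitted class probabilities at a new point
  x0 <- c(1, 0.3, -0.2, 0.1)
  eta_cpp <- c(crossprod(fit$coef, x0), 0)
  p_cpp <- exp(eta_cpp - max(eta_cpp)); p_cpp <- p_cpp / sum(p_cpp)
  p_nn <- predict(nn, newdata = data.frame(X1 = 0.3, X2 = -0.2, X3 = 0.1),
                  type = "probs")
  expect_equal(unname(p_cpp), unname(p_nn), tolerance = 1e-4)
})

test_that("parameter estimation identity cases behave as specified", {
  set.seed(56)
  sc <- build_scenario("B1", n_diploid = 6L)
  ref <- build_reference_table(list(B1 = sc), 40, n_loci = 4)
  # observed = one reference row, n_closest = 1 -> that row's parameters
  est <- suppressWarnings(
    estimate_parameters(ref, "B1", ref$stats[7, ], n_closest = 1))
  expect_equal(unname(est$sample[1, ]), unname(ref$params$B1[7, ]),
               tolerance = 1e-8)
  # identical retained statistics -> singular regression -> rejection sample
  ref2 <- ref
  ref2$stats[] <- rep(colMeans(ref$stats), each = nrow(ref$stats))
  est2 <- suppressWarnings(
    estimate_parameters(ref2, "B1", colMeans(ref$stats), n_closest = 10,
                        ridge = 0))
  expect_equal(unname(est2$sample), unname(ref2$params$B1[1:10, ]),
               tolerance = 1e-12)
  expect_error(estimate_parameters(ref, "B1", ref$stats[1, ], 1e5), "exceeds")
})

test_that("zero-slope adjustment reduces to the rejection posterior", {
  set.seed(57)
  sc <- build_scenario("B1", n_diploid = 6L)
  ref <- build_reference_table(list(B1 = sc), 60, n_loci = 4)
  # decouple parameters from statistics: slopes fit on shuffled parameters
  # with a huge ridge are ~0, so adjusted draws equal the retained draws
  est <- estimate_parameters(ref, "B1", ref$stats[1, ], n_closest = 30,
                             ridge = 1e9)
  nz <- ssrabc:::.normalize_stats(ref$stats[ref$scenario == "B1", ])
  obs <- (ref$stats[1, colnames(nz$z)] - nz$center) / nz$scale
  d <- sqrt(rowSums(sweep(nz$z, 2, obs)^2))
  sel <- order(d)[1:30]
  expect_equal(unname(est$sample), unname(ref$params$B1[sel, ]),
               tolerance = 1e-4)
})

test_that("model check returns calibrated-looking BH-adjusted tail probabilities", {
  set.seed(58)
  sc <- build_scenario("A1", n_diploid = 8L)
  ref <- build_reference_table(list(A1 = sc), 200, n_loci = 6)
  par <- draw_params(sc)
  G <- simulate_dataset(sc, par, 6)
  est <- suppressWarnings(
    estimate_parameters(ref, "A1", abc_summary_stats(G), 40))
  chk <- model_check(ref, est, G, n_sims = 120)
  expect_true(all(chk$p >= 0 & chk$p <= 1))
  expect_true(all(chk$p_adj >= chk$p - 1e-12))
  # hand-rolled BH agrees with the reported adjustment
  m <- length(chk$p); o <- order(chk$p)
  bh <- rev(cummin(rev(chk$p[o] * m / seq_len(m))))
  expect_equal(chk$p_adj[o], pmin(1, bh), tolerance = 1e-12)
  # data simulated from the model should rarely be flagged
  expect_lt(mean(chk$p_adj < 0.05), 0.25)
  # statistics used for checking are the held-out ones
  expect_true(all(grepl("^GD_|^VAR_|^DAS_", chk$statistic)))
})

test_that("confidence in choice handles degenerate one-scenario input", {
  set.seed(59)
  sc <- build_scenario("B1", n_diploid = 6L)
  ref <- build_reference_table(list(B1 = sc), 60, n_loci = 4)
  conf <- suppressWarnings(
    confidence_in_choice(ref, n_pods = 4, n_closest = 20))
  expect_equal(unname(conf$freq["B1", "B1"]), 1)
  expect_equal(unname(conf$type1["B1"]), 0)
})

test_that("reference tables persist, reload and combine in batches", {
  set.seed(60)
  scens <- list(B1 = build_scenario("B1", n_diploid = 6L),
                B4 = build_scenario("B4", n_diploid = 6L))
  r1 <- build_reference_table(scens, 15, n_loci = 4)
  r2 <- build_reference_table(scens, 10, n_loci = 4)
  both <- combine_reference_tables(r1, r2)
  expect_equal(nrow(both$stats), 50)
  expect_equal(nrow(both$params$B4), 25)
  d <- file.path(tempdir(), "reftab")
  write_reference_table(both, d)
  back <- read_reference_table(d, scens)
  expect_equal(back$stats, both$stats, tolerance = 1e-12)
  expect_identical(as.character(back$scenario), as.character(both$scenario))
  expect_equal(back$params$B1, both$params$B1, tolerance = 1e-12)
  expect_equal(back$n_loci, 4L)
  # a reloaded table supports posterior computation
  post <- scenario_posterior(back, both$stats[3, ], 20)
  expect_equal(sum(post$table$posterior), 1, tolerance = 1e-9)
})
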