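test_that("clonal copies collapse to one MLG with per-population counts", {
  G <- toy_genotypes(p1 = rep("10/11;7/7", 3), p2 = rep("10/11;7/7", 2))
  m <- identify_mlgs(G)
  expect_equal(nrow(m$mlgs), 1)
  expect_equal(unname(m$counts[1, ]), c(3, 2))
  expect_true(m$mlgs$shared)
  # heterozygote order does not matter
  G2 <- toy_genotypes(p1 = c("10/11", "11/10"))
  expect_equal(nrow(identify_mlgs(G2)$mlgs), 1)
})

test_that("all-distinct genotypes give one MLG per individual", {
  G <- toy_genotypes(p1 = c("10/10", "11/11", "12/12", "10/11"))
  m <- identify_mlgs(G)
  expect_equal(nrow(m$mlgs), 4)
  expect_true(all(m$mlgs$singleton))
})

test_that("missing-call policies behave as documented", {
  G <- toy_genotypes(p1 = c("10/10;7/7", "10/10;?", "10/10;?"))
  strict <- identify_mlgs(G, "strict")
  expect_equal(nrow(strict$assignment), 1)   # incomplete profiles excluded
  loose <- identify_mlgs(G, "ignore_missing_loci")
  expect_equal(nrow(loose$assignment), 3)
  expect_equal(nrow(loose$mlgs), 2)          # the two ?-profiles group together
})

test_that("single-step mutational variants are recognized", {
  # parent (10/10, 7/7) x2; query (10/10, 8/8): allele 8 is one repeat away
  # and otherwise absent in the population
  G <- toy_genotypes(p1 = c("10/10;7/7", "10/10;7/7", "10/10;8/8"))
  m <- identify_mlgs(G)
  cl <- classify_lineages(m, G, "p1")
  expect_equal(cl$class[cl$count == 2], "nonrecombinant")
  expect_equal(cl$class[cl$count == 1], "single_step_variant")
  # same variant but allele 8 present in another lineage: not single-step
  G2 <- toy_genotypes(p1 = c("10/10;7/7", "10/10;7/7", "10/10;8/8",
                             "12/12;8/8", "12/12;8/8"))
  cl2 <- classify_lineages(identify_mlgs(G2), G2, "p1")
  expect_false(any(cl2$class == "single_step_variant"))
})

test_that("locus-wise chimeras of two abundant parents are recombinant", {
  # parents A = (10/10, 7/7, 5/5), B = (12/12, 9/9, 5/5); query mixes them
  G <- toy_genotypes(p1 = c(rep("10/10;7/7;5/5", 2), rep("12/12;9/9;5/5", 2),
                            "10/10;9/9;5/5"))
  m <- identify_mlgs(G)
  cl <- classify_lineages(m, G, "p1")
  rec <- cl[cl$count == 1, ]
  expect_equal(rec$class, "recombinant")
  expect_setequal(strsplit(rec$parents, ";")[[1]],
                  cl$mlg[cl$count == 2])
})

test_that("private distant alleles stay nonrecombinant", {
  G <- toy_genotypes(p1 = c(rep("10/10;7/7", 2), "13/13;7/7"))
  cl <- classify_lineages(identify_mlgs(G), G, "p1")
  expect_equal(cl$class[cl$count == 1], "nonrecombinant")
})

test_that("classification is stable under individual and locus reordering", {
  set.seed(31)
  G <- toy_genotypes(p1 = c(rep("10/10;7/7;5/5", 3), rep("12/12;9/9;5/5", 2),
                            "10/10;9/9;5/5", "10/10;8/8;5/5"))
  cl <- classify_lineages(identify_mlgs(G), G, "p1")
  perm <- sample(length(G$individuals))
  Gp <- genotype_matrix(G$a1[perm, 3:1], G$a2[perm, 3:1], pop = G$pop[perm])
  clp <- classify_lineages(identify_mlgs(Gp), Gp, "p1")
  key <- function(d) d[order(-d$count, d$class), c("count", "class")]
  expect_equal(key(cl), key(clp), ignore_attr = TRUE)
})

test_that("classify_lineages validates its inputs", {
  G <- toy_genotypes(p1 = c("10/10", "10/10"), p2 = "11/11")
  m <- identify_mlgs(G)
  expect_error(classify_lineages(m, G, "nope"), "unknown population")
  expect_error(classify_lineages(m, G, "p1", abundance_min = 1), ">= 2")
})

test_that("seeded outcross products in synthetic data classify as recombinant", {
  # two abundant selfing lineages plus their F1-style chimera, as produced by
  # an outcross event in the forward generator
  A <- "10/10;7/7;5/5;20/20"; B <- "14/14;9/9;5/5;22/22"
  child <- "10/14;7/9;5/5;20/22"  # heterozygous at differing loci
  G <- toy_genotypes(p1 = c(rep(A, 4), rep(B, 3), child))
  cl <- classify_lineages(identify_mlgs(G), G, "p1")
  # the heterozygous F1 matches neither parent locus-wise: nonrecombinant
  # under the locus-matching rule (the rule targets selfed descendants)
  expect_equal(cl$class[cl$count == 1], "nonrecombinant")
  # after one selfing generation the chimera fixes a mosaic of parental
  # alleles and matches the recombinant rule
  selfed <- "10/10;9/9;5/5;20/20"
  G2 <- toy_genotypes(p1 = c(rep(A, 4), rep(B, 3), selfed))
  cl2 <- classify_lineages(identify_mlgs(G2), G2, "p1")
  expect_equal(cl2$class[cl2$count == 1], "recombinant")
})

test_that("highly resistant report filters populations by R threshold", {
  G <- toy_genotypes(hi = c(rep("10/10", 3), "11/11"), lo = rep("12/12", 3))
  m <- identify_mlgs(G)
  rep <- mlg_report(m, G, resistance = c(hi = 0.99, lo = 0.10))
  expect_true(all(rep$population == "hi"))
  expect_equal(sum(rep$count), 4)
})
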