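# Independent oracles and toy-data builders used across the suite.

# Build a genotype_matrix from a compact list: one character vector per
# population, each element "a1/a2;a1/a2;..." over loci ("?" = missing call).
toy_genotypes <- function(...) {
  pops <- list(...)
  a1 <- list(); a2 <- list(); pop <- character()
  for (p in names(pops)) {
    for (ind in pops[[p]]) {
      calls <- strsplit(ind, ";", fixed = TRUE)[[1]]
      pair <- lapply(calls, function(s) {
        if (s == "?") return(c(NA_integer_, NA_integer_))
        as.integer(strsplit(s, "/", fixed = TRUE)[[1]])
      })
      a1[[length(a1) + 1L]] <- vapply(pair, `[`, 0L, 1)
      a2[[length(a2) + 1L]] <- vapply(pair, `[`, 0L, 2)
      pop <- c(pop, p)
    }
  }
  genotype_matrix(do.call(rbind, a1), do.call(rbind, a2),
                  pop = factor(pop, levels = names(pops)))
}

# Literal Weir & Cockerham (1984) variance components, written directly from
# the published formulas with plain loops -- the brute-force oracle the
# compiled implementation is checked against.
wc_oracle <- function(G) {
  L <- length(G$loci)
  out <- matrix(NA_real_, L, 3)
  pops <- levels(G$pop)
  for (l in seq_len(L)) {
    x <- G$a1[, l]; y <- G$a2[, l]
    keep <- !is.na(x)
    use <- pops[vapply(pops, function(p) any(keep & G$pop == p), TRUE)]
    r <- length(use)
    if (r == 0) next
    alleles <- unique(c(x[keep], y[keep]))
    if (length(alleles) < 2) next
    ni <- vapply(use, function(p) sum(keep & G$pop == p), 0)
    nbar <- mean(ni); nsum <- sum(ni)
    suma <- sumb <- sumc <- 0
    for (al in alleles) {
      pi <- vapply(use, function(p) {
        s <- keep & G$pop == p
        (sum(x[s] == al) + sum(y[s] == al)) / (2 * sum(s))
      }, 0)
      hi <- vapply(use, function(p) {
        s <- keep & G$pop == p
        sum((x[s] == al | y[s] == al) & x[s] != y[s]) / sum(s)
      }, 0)
      pbar <- sum(ni * pi) / nsum
      hbar <- sum(ni * hi) / nsum
      if (r == 1) {
        nn <- ni[1]
        sumb <- sumb + nn / (nn - 1) *
          (pi[1] * (1 - pi[1]) - (2 * nn - 1) / (4 * nn) * hi[1])
        sumc <- sumc + hbar / 2
      } else {
        nc <- (nsum - sum(ni^2) / nsum) / (r - 1)
        s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
        a <- nbar / nc * (s2 - 1 / (nbar - 1) *
          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
        b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
          (2 * nbar - 1) / (4 * nbar) * hbar)
        suma <- suma + a; sumb <- sumb + b; sumc <- sumc + hbar / 2
      }
    }
    out[l, ] <- c(suma, sumb, sumc)
  }
  out
}

# random diploid dataset with npop populations of n individuals, k alleles
random_genotypes <- function(npop, n, L, k = 4, miss = 0) {
  a1 <- matrix(sample.int(k, npop * n * L, replace = TRUE), npop * n, L)
  a2 <- matrix(sample.int(k, npop * n * L, replace = TRUE), npop * n, L)
  if (miss > 0) {
    drop <- matrix(runif(npop * n * L) < miss, npop * n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  genotype_matrix(a1, a2, pop = rep(paste0("p", seq_len(npop)), each = n))
}

# exhaustive rarefaction oracle: expected allele count in all gene-copy
# subsets of size m, enumerated with combn
rarefaction_oracle <- function(gene_copies, m) {
  combos <- utils::combn(length(gene_copies), m)
  mean(apply(combos, 2, function(ix) length(unique(gene_copies[ix]))))
}
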