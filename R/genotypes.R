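#' Diploid microsatellite genotype matrix
#'
#' Container for diploid microsatellite calls: two integer allele matrices
#' (individuals x loci, allele states in repeat units, \code{NA} = missing)
#' plus a population factor.  Both alleles of a call are missing or neither
#' is; the pair is stored unordered (smaller state in \code{a1}).
#'
#' @param a1,a2 integer matrices of allele states (repeat counts, positive).
#' @param pop population label per individual (coerced to factor).
#' @param individuals optional individual IDs (default from rownames or
#'   \code{ind1...}).
#' @param loci optional locus IDs (default from colnames or \code{L1...}).
#' @param motif repeat-motif length in bp per locus (integer, recycled);
#'   carried as metadata, statistics operate in repeat units.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(a1, a2, pop, individuals = NULL, loci = NULL,
                            motif = 1L) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (L < 1L) stop("at least one locus is required")
  if (length(pop) != n) stop("pop must have one entry per individual")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing calls are not allowed; single-state calls are homozygotes")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele states must be positive integers (repeat counts)")
  if (is.null(individuals)) individuals <- rownames(a1)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(a1 = a1, a2 = a2, pop = factor(pop),
         individuals = as.character(individuals), loci = as.character(loci),
         motif = as.integer(rep_len(motif, L))),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci,", nlevels(x$pop), "populations\n")
  miss <- mean(is.na(x$a1))
  cat("populations:", paste(utils::head(levels(x$pop), 8), collapse = ", "),
      if (nlevels(x$pop) > 8) "..." else "", "\n")
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  tab <- table(object$pop)
  cat("genotype_matrix with", nlevels(object$pop), "populations\n")
  print(tab)
  invisible(tab)
}

n_ind <- function(G) length(G$individuals)
n_loci <- function(G) length(G$loci)

#' Subset a genotype matrix by individuals and/or populations
#'
#' @param G a \code{genotype_matrix}.
#' @param individuals logical or integer index over individuals.
#' @param pops character vector of population labels to keep.
#' @return A \code{genotype_matrix} (population factor levels dropped).
#' @export
subset_genotypes <- function(G, individuals = NULL, pops = NULL) {
  keep <- rep(TRUE, n_ind(G))
  if (!is.null(individuals)) {
    sel <- rep(FALSE, n_ind(G)); sel[individuals] <- TRUE; keep <- keep & sel
  }
  if (!is.null(pops)) keep <- keep & (as.character(G$pop) %in% pops)
  genotype_matrix(G$a1[keep, , drop = FALSE], G$a2[keep, , drop = FALSE],
                  factor(as.character(G$pop[keep]), levels = unique(c(pops, as.character(G$pop[keep])))[
                    unique(c(pops, as.character(G$pop[keep]))) %in% as.character(G$pop[keep])]),
                  individuals = G$individuals[keep], loci = G$loci,
                  motif = G$motif)
}

# population index vector (1-based integers) and count, for the C++ kernels
pop_index <- function(G) {
  list(idx = as.integer(G$pop), k = nlevels(G$pop), labels = levels(G$pop))
}
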