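#' Identify multilocus genotypes (MLGs)
#'
#' Groups individuals by their canonical multilocus genotype string (loci in
#' input order, each call as a sorted allele pair).  In a highly selfing
#' species an MLG is a proxy for a selfing lineage; MLGs shared across
#' populations indicate seed-mediated dispersal.  Under the default
#' \code{"strict"} policy individuals with any missing call are excluded from
#' matching; under \code{"ignore_missing_loci"} they are grouped by their
#' full pattern including the missing mask.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param missing_policy \code{"strict"} or \code{"ignore_missing_loci"}.
#' @return An object of class \code{mlg_table}: data.frame \code{mlgs} (MLG
#'   id, canonical string, total count, singleton flag, shared flag), matrix
#'   \code{counts} (MLG x population), and \code{assignment} (per retained
#'   individual).
#' @export
identify_mlgs <- function(G, missing_policy = c("strict", "ignore_missing_loci")) {
  missing_policy <- match.arg(missing_policy)
  key <- .mlg_keys(G)
  keep <- if (missing_policy == "strict") !is.na(key) else rep(TRUE, n_ind(G))
  key[is.na(key)] <- vapply(which(is.na(key)), function(i)
    .mlg_key_one(G$a1[i, ], G$a2[i, ], keep_na = TRUE), "")
  key <- key[keep]
  pop <- factor(as.character(G$pop[keep]), levels = levels(G$pop))
  uk <- unique(key)
  id <- paste0("MLG", seq_along(uk))
  names(id) <- uk
  counts <- table(factor(id[key], levels = id), pop)
  counts <- matrix(counts, nrow = length(uk),
                   dimnames = list(id, levels(pop)))
  total <- rowSums(counts)
  mlgs <- data.frame(
    mlg = id, genotype = uk, total = as.integer(total),
    singleton = total == 1L,
    shared = rowSums(counts > 0) > 1L,
    stringsAsFactors = FALSE)
  rownames(mlgs) <- NULL
  structure(list(
    mlgs = mlgs, counts = counts,
    assignment = data.frame(individual = G$individuals[keep],
                            population = as.character(pop),
                            mlg = id[key], stringsAsFactors = FALSE),
    missing_policy = missing_policy),
    class = "mlg_table")
}

.mlg_key_one <- function(x, y, keep_na = FALSE) {
  if (!keep_na && anyNA(x)) return(NA_character_)
  paste(ifelse(is.na(x), "?", paste0(pmin(x, y), "-", pmax(x, y))),
        collapse = ";")
}

.mlg_keys <- function(G) {
  vapply(seq_len(n_ind(G)), function(i)
    .mlg_key_one(G$a1[i, ], G$a2[i, ]), "")
}

#' @export
print.mlg_table <- function(x, ...) {
  cat("mlg_table:", nrow(x$mlgs), "distinct MLGs among",
      nrow(x$assignment), "individuals\n")
  cat("  shared among populations:", sum(x$mlgs$shared),
      "| singletons:", sum(x$mlgs$singleton), "\n")
  invisible(x)
}

#' Classify MLGs within a population by lineage relationship
#'
#' Within one population, each MLG is compared to the more abundant MLGs
#' present there: an MLG differing from a more abundant one at exactly one
#' allele by exactly one repeat unit, where the new allele occurs nowhere
#' else in the population, is a \code{single_step_variant} (plausibly the
#' same selfing lineage after one microsatellite mutation).  An MLG whose
#' differing loci each match some more abundant MLG, requiring at least two
#' distinct such parents, is \code{recombinant} (an outcross product).
#' Otherwise \code{nonrecombinant}; ambiguous cases are
#' \code{unclassified}.
#'
#' @param mlg_table an \code{\link{identify_mlgs}} result.
#' @param G the \code{\link{genotype_matrix}} the table was built from.
#' @param population population label to classify within.
#' @param abundance_min minimum copy number for an MLG to act as a parent.
#' @return A data.frame: mlg, count, class, parents.
#' @export
classify_lineages <- function(mlg_table, G, population, abundance_min = 2L) {
  if (abundance_min < 2) stop("abundance_min must be >= 2")
  if (!population %in% colnames(mlg_table$counts))
    stop("unknown population: ", population)
  cnt <- mlg_table$counts[, population]
  present <- names(cnt)[cnt > 0]
  if (!length(present)) stop("population ", population, " is empty")
  geno <- setNames(mlg_table$mlgs$genotype, mlg_table$mlgs$mlg)
  parse_geno <- function(s) {
    pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    t(vapply(pairs, function(p)
      if (identical(p, "?")) c(NA_integer_, NA_integer_) else as.integer(p),
      integer(2)))
  }
  gmat <- lapply(geno[present], parse_geno)
  L <- nrow(gmat[[1]])
  out <- lapply(present, function(m) {
    more <- present[cnt[present] > max(cnt[m], abundance_min - 1L)]
    more <- setdiff(more, m)
    cls <- "nonrecombinant"; parents <- ""
    if (length(more)) {
      g <- gmat[[m]]
      # single-step variant: exactly one locus differs, by exactly one novel
      # allele state one repeat unit from a parental state (a single mutation,
      # heterozygous or already fixed by selfing), the novel state otherwise
      # absent in the population
      sstep <- vapply(more, function(pm) {
        pg <- gmat[[pm]]
        diffs <- which(rowSums(g != pg, na.rm = TRUE) > 0)
        if (length(diffs) != 1L) return(FALSE)
        l <- diffs
        sc <- unique(g[l, ]); sp <- unique(pg[l, ])
        novel <- setdiff(sc, sp)
        if (length(novel) != 1L) return(FALSE)
        if (!any(abs(novel - sp) == 1L)) return(FALSE)
        # otherwise absent: carried only by this MLG in the population
        others <- unique(unlist(lapply(setdiff(present, m), function(q)
          gmat[[q]][l, ])))
        !(novel %in% others)
      }, FALSE)
      if (any(sstep)) {
        cls <- "single_step_variant"; parents <- paste(more[sstep], collapse = ";")
      } else {
        # recombinant: every differing locus matched by some more abundant MLG,
        # needing >= 2 distinct parents
        match_mat <- vapply(more, function(pm) {
          pg <- gmat[[pm]]
          rowSums(g != pg, na.rm = TRUE) == 0
        }, logical(L))
        match_mat <- matrix(match_mat, nrow = L,
                            dimnames = list(NULL, more))
        covered <- rowSums(match_mat) > 0
        full_parent <- colSums(match_mat) == L
        if (all(covered) && !any(full_parent)) {
          # minimum number of parents needed >= 2 when no single parent covers
          cls <- "recombinant"
          parents <- paste(more[colSums(match_mat) > 0], collapse = ";")
        } else if (all(covered) && any(full_parent)) {
          cls <- "unclassified"  # identical to an abundant MLG at all loci? tie
          parents <- paste(more[full_parent], collapse = ";")
        }
      }
    }
    data.frame(mlg = m, count = as.integer(cnt[m]), class = cls,
               parents = parents, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$count), ]
}

#' MLG sharing and classification report for highly resistant populations
#'
#' Tabulates MLG counts per population, restricted to populations whose
#' resistance frequency meets a threshold, and classifies each MLG there.
#'
#' @param mlg_table an \code{\link{identify_mlgs}} result.
#' @param G the underlying \code{\link{genotype_matrix}}.
#' @param resistance named vector of population resistance frequencies R.
#' @param r_min threshold defining "highly resistant" (default 0.95).
#' @param path optional CSV output path.
#' @return A data.frame: population, mlg, count, class.
#' @export
mlg_report <- function(mlg_table, G, resistance, r_min = 0.95, path = NULL) {
  pops <- names(resistance)[!is.na(resistance) & resistance >= r_min]
  pops <- intersect(pops, colnames(mlg_table$counts))
  rows <- lapply(pops, function(p) {
    cl <- classify_lineages(mlg_table, G, p)
    cbind(population = p, cl)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), mlg = character(),
               count = integer(), class = character(), parents = character())
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
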