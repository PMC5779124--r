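#' Read microsatellite genotypes from GenePop or delimited-table files
#'
#' Two dialects are supported.  \emph{GenePop}: first line is a title, then
#' locus names (one per line, or one comma-separated line), then blocks
#' introduced by \code{Pop} lines; each individual line is
#' \code{id , 010012 008008 ...} with 3-digit allele codes equal to repeat
#' counts and \code{000} for missing.  Individual IDs written by
#' \code{\link{write_genotypes}} carry the population label as
#' \code{pop:ind}; on reading, IDs of that shape are split back, otherwise
#' populations are named \code{pop1, pop2, ...} in block order.
#' \emph{Table}: comma- or tab-delimited with columns \code{individual},
#' \code{population}, then one column per locus holding \code{a1/a2}
#' (\code{000/000} = missing).
#'
#' @param path file path.
#' @param format \code{"genepop"} or \code{"table"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("genepop", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") read_genepop(path) else read_genotype_table(path)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("malformed GenePop file: fewer than 3 lines")
  ispop <- tolower(trimws(lines)) == "pop"
  first_pop <- which(ispop)[1]
  if (is.na(first_pop)) stop("malformed GenePop file: no 'Pop' line")
  loci_lines <- lines[2:(first_pop - 1)]
  loci <- if (length(loci_lines) == 1 && grepl(",", loci_lines))
    trimws(strsplit(loci_lines, ",")[[1]]) else trimws(loci_lines)
  L <- length(loci)
  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  for (k in seq(first_pop, length(lines))) {
    if (ispop[k]) { pop_i <- pop_i + 1L; next }
    ln <- lines[k]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("malformed GenePop file at line ", k, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    gt <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(gt) != L)
      stop("malformed GenePop file at line ", k, ": expected ", L,
           " genotypes, found ", length(gt))
    if (any(!grepl("^[0-9]{4}$|^[0-9]{6}$", gt)))
      stop("non-numeric or malformed allele codes at line ", k)
    w <- nchar(gt[1]) / 2
    x1 <- as.integer(substr(gt, 1, w)); x2 <- as.integer(substr(gt, w + 1, 2 * w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    half <- xor(is.na(x1), is.na(x2))  # single-state call -> homozygote
    x1[half & is.na(x1)] <- x2[half & is.na(x1)]
    x2[half & is.na(x2)] <- x1[half & is.na(x2)]
    if (grepl(":", id)) {
      pops <- c(pops, sub(":.*$", "", id)); ids <- c(ids, sub("^[^:]*:", "", id))
    } else {
      pops <- c(pops, paste0("pop", pop_i)); ids <- c(ids, id)
    }
    rows1[[length(rows1) + 1L]] <- x1; rows2[[length(rows2) + 1L]] <- x2
  }
  if (!length(rows1)) stop("malformed GenePop file: no individuals")
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                  pop = factor(pops, levels = unique(pops)),
                  individuals = ids, loci = loci)
}

read_genotype_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  d <- utils::read.csv(path, sep = sep, check.names = FALSE,
                       colClasses = "character")
  need <- c("individual", "population")
  if (!all(need %in% names(d)))
    stop("table dialect needs columns 'individual' and 'population'")
  loci <- setdiff(names(d), need)
  if (!length(loci)) stop("no locus columns found")
  parse_call <- function(s, locus) {
    bits <- strsplit(s, "/", fixed = TRUE)
    bad <- vapply(bits, function(b) length(b) != 2 || anyNA(suppressWarnings(as.integer(b))),
                  logical(1))
    if (any(bad))
      stop("malformed call in locus ", locus, " row ", which(bad)[1],
           ": expected 'a1/a2' integers")
    m <- vapply(bits, function(b) as.integer(b), integer(2))
    m[m == 0L] <- NA_integer_
    m
  }
  A <- lapply(loci, function(l) parse_call(d[[l]], l))
  a1 <- vapply(A, function(m) m[1, ], integer(nrow(d)))
  a2 <- vapply(A, function(m) m[2, ], integer(nrow(d)))
  if (nrow(d) == 1) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  half <- xor(is.na(a1), is.na(a2))
  a1[half & is.na(a1)] <- a2[half & is.na(a1)]
  a2[half & is.na(a2)] <- a1[half & is.na(a2)]
  genotype_matrix(a1, a2, pop = factor(d$population, levels = unique(d$population)),
                  individuals = d$individual, loci = loci)
}

#' Write microsatellite genotypes
#'
#' Inverse of \code{\link{read_genotypes}}; \code{read(write(G))} is the
#' identity in both dialects.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @param format \code{"genepop"} or \code{"table"}.
#' @param title first line of the GenePop file.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("genepop", "table"),
                            title = "ssrabc genotypes") {
  format <- match.arg(format)
  if (format == "genepop") {
    code <- function(m) { m[is.na(m)] <- 0L; sprintf("%03d", m) }
    c1 <- matrix(code(G$a1), nrow = n_ind(G)); c2 <- matrix(code(G$a2), nrow = n_ind(G))
    out <- c(title, G$loci)
    for (p in levels(G$pop)) {
      out <- c(out, "Pop")
      for (i in which(as.character(G$pop) == p)) {
        gt <- paste0(c1[i, ], c2[i, ], collapse = " ")
        out <- c(out, paste0(p, ":", G$individuals[i], " , ", gt))
      }
    }
    writeLines(out, path)
  } else {
    cell <- function(x, y) {
      x[is.na(x)] <- 0L; y[is.na(y)] <- 0L
      sprintf("%03d/%03d", x, y)
    }
    d <- data.frame(individual = G$individuals,
                    population = as.character(G$pop),
                    check.names = FALSE, stringsAsFactors = FALSE)
    for (l in seq_along(G$loci)) d[[G$loci[l]]] <- cell(G$a1[, l], G$a2[, l])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Raw (possibly multiallelic) genotype calls
#'
#' Fragment analysis of a diploid can report more than two allele states at a
#' locus when the sample is contaminated or an interspecific polyploid hybrid
#' (e.g., a co-occurring hexaploid congener).  \code{raw_calls} holds one
#' integer vector of detected states per individual and locus so such
#' profiles can be flagged before building a \code{\link{genotype_matrix}}.
#'
#' @param calls a list (one element per individual) of lists (one integer
#'   vector of allele states per locus); empty vectors are missing calls.
#' @param pop population label per individual.
#' @param individuals,loci optional IDs.
#' @return An object of class \code{raw_calls}.
#' @export
raw_calls <- function(calls, pop, individuals = NULL, loci = NULL) {
  n <- length(calls)
  if (length(pop) != n) stop("pop must have one entry per individual")
  L <- if (n) length(calls[[1]]) else 0L
  if (n && any(vapply(calls, length, 0L) != L))
    stop("all individuals must have the same number of loci")
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(max(L, 1L)))
  structure(list(calls = calls, pop = factor(pop),
                 individuals = as.character(individuals),
                 loci = as.character(loci)),
            class = "raw_calls")
}

#' Flag individuals with more than two allele states at any locus
#'
#' Individuals whose profile shows three or more states at one or more loci
#' are putative polyploid hybrids and are flagged for exclusion from diploid
#' population-genetic analyses.
#'
#' @param raw a \code{\link{raw_calls}} object.
#' @return A list of class \code{qc_report}: \code{flagged} (data.frame of
#'   individual and offending loci) and \code{n_excluded}.
#' @export
qc_flag_multiallelic <- function(raw) {
  stopifnot(inherits(raw, "raw_calls"))
  flg <- list()
  for (i in seq_along(raw$calls)) {
    k <- vapply(raw$calls[[i]], function(v) length(unique(v)), 0L)
    if (any(k > 2L))
      flg[[length(flg) + 1L]] <- data.frame(
        individual = raw$individuals[i],
        loci = paste(raw$loci[k > 2L], collapse = ";"),
        stringsAsFactors = FALSE)
  }
  flagged <- if (length(flg)) do.call(rbind, flg) else
    data.frame(individual = character(), loci = character(),
               stringsAsFactors = FALSE)
  structure(list(flagged = flagged, n_excluded = nrow(flagged)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_excluded, "individual(s) with >2 allele states\n")
  if (x$n_excluded) print(x$flagged)
  invisible(x)
}

#' Apply multiallelic-profile quality control
#'
#' Converts raw calls to a diploid \code{\link{genotype_matrix}}.  Policy
#' \code{"drop"} (default) removes flagged individuals; \code{"keep_flagged"}
#' keeps them but masks their multiallelic locus calls as missing.
#' Single-state calls become homozygotes; empty calls are missing.
#'
#' @param raw a \code{\link{raw_calls}} object.
#' @param policy \code{"drop"} or \code{"keep_flagged"}.
#' @return A list: \code{genotypes} (\code{genotype_matrix}) and
#'   \code{report} (\code{qc_report}).
#' @export
qc_apply <- function(raw, policy = c("drop", "keep_flagged")) {
  policy <- match.arg(policy)
  rep <- qc_flag_multiallelic(raw)
  keep <- if (policy == "drop")
    !(raw$individuals %in% rep$flagged$individual) else
    rep(TRUE, length(raw$individuals))
  if (!any(keep)) stop("no individuals left after QC")
  L <- length(raw$loci)
  n <- sum(keep)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  r <- 0L
  for (i in which(keep)) {
    r <- r + 1L
    for (l in seq_len(L)) {
      v <- unique(raw$calls[[i]][[l]])
      if (length(v) == 1L) { a1[r, l] <- v; a2[r, l] <- v }
      else if (length(v) == 2L) { a1[r, l] <- min(v); a2[r, l] <- max(v) }
      # 0 states -> missing; >2 states (keep_flagged) -> missing
    }
  }
  G <- genotype_matrix(a1, a2, pop = factor(as.character(raw$pop[keep])),
                       individuals = raw$individuals[keep], loci = raw$loci)
  list(genotypes = G, report = rep)
}
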