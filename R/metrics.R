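#' Allele count A
#'
#' Total number of distinct alleles (repeat counts) present in the
#' population, summed over loci.
#'
#' @param pop population matrix.
#' @return integer, at least one per locus.
#' @export
allele_count <- function(pop) {
  pop <- pop_matrix(pop)
  if (nrow(pop) < 1L) stop("empty population")
  L <- ncol(pop) %/% 2L
  sum(vapply(seq_len(L), function(i) {
    length(unique(c(pop[, i], pop[, i + L])))
  }, integer(1)))
}

#' Multilocus genotype count G
#'
#' Number of distinct phase-invariant multilocus genotypes (MLGs); each MLG
#' approximates one clonal lineage.
#'
#' @param pop population matrix.
#' @return integer in `[1, N]`.
#' @export
mlg_count <- function(pop) {
  pop <- pop_matrix(pop)
  if (nrow(pop) < 1L) stop("empty population")
  length(unique(mlg_keys(pop)))
}

#' Observed heterozygosity H
#'
#' Fraction of individuals whose two homologs differ, averaged over loci.
#'
#' @param pop population matrix.
#' @return numeric in `[0, 1]`.
#' @export
heterozygosity <- function(pop) {
  pop <- pop_matrix(pop)
  if (nrow(pop) < 1L) stop("empty population")
  L <- ncol(pop) %/% 2L
  mean(pop[, seq_len(L), drop = FALSE] != pop[, L + seq_len(L), drop = FALSE])
}

#' Genotypic diversity R
#'
#' Clonal richness relative to sample size: `R = (G - 1) / (N - 1)`
#' (Dorken--Eckert style), 0 for a monoclonal population and 1 when every
#' individual is a distinct MLG. Undefined (NA) for `N < 2`.
#'
#' @param G number of distinct MLGs.
#' @param N population size.
#' @return numeric in `[0, 1]`, or `NA` when `N < 2`.
#' @export
genotypic_diversity <- function(G, N) {
  ifelse(N < 2, NA_real_, (G - 1) / (N - 1))
}

#' All per-snapshot metrics at once
#'
#' @param pop population matrix.
#' @return list with `N`, `A`, `G`, `H`, `R`.
#' @export
compute_metrics <- function(pop) {
  pop <- pop_matrix(pop)
  N <- nrow(pop)
  G <- mlg_count(pop)
  list(N = N, A = allele_count(pop), G = G, H = heterozygosity(pop),
       R = genotypic_diversity(G, N))
}

# Per-locus sorted allele sets of one snapshot (compact presence record).
allele_presence <- function(pop) {
  pop <- pop_matrix(pop)
  L <- ncol(pop) %/% 2L
  lapply(seq_len(L), function(i) sort(unique(c(pop[, i], pop[, i + L]))))
}

#' Allele presence/absence matrix across sampling days
#'
#' Builds the binary days-by-(locus, allele) incidence matrix used for the
#' binomial dissimilarity and nMDS. Columns are labelled `"l<locus>:<allele>"`
#' and span the union of alleles observed on any day.
#'
#' @param x a `diatom_sim`, a list of per-day presence records (as stored in
#'   `sim$presence`), or a list of population matrices.
#' @return binary integer matrix; row names are the day labels.
#' @export
presence_matrix <- function(x) {
  if (inherits(x, "diatom_sim")) x <- x$presence
  stopifnot(length(x) >= 1)
  if (is.matrix(x[[1]])) x <- lapply(x, allele_presence)
  L <- length(x[[1]])
  labels <- lapply(x, function(day) {
    unlist(lapply(seq_len(L), function(i) {
      paste0("l", i - 1L, ":", day[[i]])
    }))
  })
  cols <- sort(unique(unlist(labels)))
  m <- matrix(0L, nrow = length(x), ncol = length(cols),
              dimnames = list(names(x), cols))
  for (r in seq_along(labels)) {
    m[r, labels[[r]]] <- 1L
  }
  m
}

#' Binomial deviance dissimilarity between day profiles
#'
#' For two rows x, y the dissimilarity is
#' `sum_c [x_c log(x_c/n_c) + y_c log(y_c/n_c) + n_c log 2] / n_c` with
#' `n_c = x_c + y_c`; columns with `n_c = 0` contribute nothing and
#' `0 log 0 = 0`. On presence/absence data this reduces to `log(2)` times
#' the number of mismatched columns. Computed with
#' [vegan::vegdist()]`(method = "binomial")`.
#'
#' @param m a presence/absence (or count) matrix, days in rows.
#' @return symmetric day-by-day distance matrix with zero diagonal.
#' @export
binomial_distance <- function(m) {
  stopifnot(nrow(m) >= 2)
  as.matrix(vegan::vegdist(m, method = "binomial"))
}

#' Write a combined metrics table as CSV
#'
#' @param metrics data frame of per-day metrics.
#' @param file output path.
#' @export
write_metrics <- function(metrics, file) {
  utils::write.csv(metrics, file, row.names = FALSE)
  invisible(file)
}
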