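# Genotype representation
# -----------------------
# A population is an integer matrix with one row per diploid individual and
# 2 * n_loci columns: columns 1..L hold the repeat counts of homolog "a" at
# loci 0..L-1, columns L+1..2L those of homolog "b". A single individual is a
# one-row matrix (or a length-2L vector, accepted everywhere).

pop_matrix <- function(x, L) {
  if (is.matrix(x)) return(x)
  matrix(as.integer(x), nrow = 1L)
}

#' Create a founder population of maximal microsatellite diversity
#'
#' Draws `n` diploid individuals whose repeat counts are uniform on
#' `[min_repeats, max_repeats]` independently at every locus and homolog.
#' Starting from maximal diversity lets the burn-in prune the population to a
#' mutation--drift quasi-equilibrium before sampling begins.
#'
#' @param founder_seed integer seed; the same seed yields the same founders,
#'   which is how replicate runs are made to start from one input population.
#' @param n number of individuals.
#' @param layout a `chrom_layout`.
#' @return integer matrix, `n` rows by `2 * n_loci` columns.
#' @export
founder_population <- function(founder_seed, n, layout) {
  L <- n_loci(layout)
  with_seed(founder_seed, {
    m <- matrix(sample(seq.int(layout$min_repeats, layout$max_repeats),
                       n * 2L * L, replace = TRUE),
                nrow = n, ncol = 2L * L)
    colnames(m) <- c(paste0("l", seq_len(L) - 1L, "_a"),
                     paste0("l", seq_len(L) - 1L, "_b"))
    m
  })
}

#' Mitotic stepwise mutation of microsatellite repeat counts
#'
#' Each (locus, homolog) slot mutates independently with probability
#' `mut_rate` per division. A mutation changes the repeat count by one unit,
#' up or down with equal probability (single-step stepwise mutation model),
#' reflecting at the repeat bounds: a step below `min_repeats` lands on
#' `min_repeats + 1`, a step above `max_repeats` on `max_repeats - 1`.
#'
#' @param pop population matrix (rows = individuals) or a single individual.
#' @param mut_rate per-locus, per-homolog mutation probability in \[0, 1\].
#' @param min_repeats,max_repeats repeat-count bounds.
#' @return a new matrix of the same shape; the input is not modified.
#' @export
mutate_mitotic <- function(pop, mut_rate, min_repeats = 5L, max_repeats = 50L) {
  stopifnot(mut_rate >= 0, mut_rate <= 1)
  pop <- pop_matrix(pop)
  n <- length(pop)
  k <- stats::rbinom(1L, n, mut_rate)
  if (k > 0L) {
    idx <- sample.int(n, k)
    v <- pop[idx] + sample(c(-1L, 1L), k, replace = TRUE)
    v[v < min_repeats] <- min_repeats + 1L
    v[v > max_repeats] <- max_repeats - 1L
    pop[idx] <- v
  }
  pop
}

#' Draw crossover breakpoints outside microsatellite intervals
#'
#' The number of breakpoints is Binomial(`chrom_len`, `rec_rate`) -- one
#' Bernoulli trial per inter-base position -- and positions are uniform on
#' the chromosome. A breakpoint at position p cuts between bases p-1 and p;
#' any position that would cut strictly inside a microsatellite interval
#' (the maximal extent `[start, start + motif_len * max_repeats)`) is
#' redrawn until it falls outside, so crossovers never break a tandem
#' repeat. Positions are returned sorted and deduplicated.
#'
#' @param layout a `chrom_layout`.
#' @param rec_rate per-base breakpoint probability in \[0, 1\].
#' @return sorted integer vector of breakpoint positions (possibly empty).
#' @export
draw_breakpoints <- function(layout, rec_rate) {
  stopifnot(rec_rate >= 0, rec_rate <= 1)
  k <- stats::rbinom(1L, layout$chrom_len, rec_rate)
  if (k == 0L) return(integer(0))
  pos <- sample.int(layout$chrom_len, k, replace = TRUE) - 1L
  reject_inside_loci(pos, layout)
}

# Redraw positions lying strictly inside any locus interval.
reject_inside_loci <- function(pos, layout) {
  s <- layout$loci$start
  e <- layout$loci$end
  repeat {
    bad <- rowSums(outer(pos, s, ">") & outer(pos, e, "<")) > 0
    if (!any(bad)) break
    pos[bad] <- sample.int(layout$chrom_len, sum(bad), replace = TRUE) - 1L
  }
  sort(unique(pos))
}

#' Form one gamete by meiosis with crossover recombination
#'
#' The starting homolog is chosen uniformly; walking left to right along the
#' chromosome the source homolog switches at every breakpoint drawn by
#' [draw_breakpoints()]. Each locus inherits the repeat count of the homolog
#' active over its interval (well defined because breakpoints never fall
#' inside a locus).
#'
#' @param ind a single individual (one-row matrix or length-`2L` vector).
#' @param layout a `chrom_layout`.
#' @param rec_rate per-base breakpoint probability.
#' @return integer vector of length `n_loci`: the gamete haplotype.
#' @export
meiosis_gamete <- function(ind, layout, rec_rate) {
  ind <- pop_matrix(ind)
  meiosis_gametes(ind, 1L, layout, rec_rate)[1L, ]
}

# Vectorised meiosis: one gamete per entry of `rows` (parent row indices in
# `pop`). The common zero-breakpoint case is handled in bulk.
meiosis_gametes <- function(pop, rows, layout, rec_rate) {
  L <- n_loci(layout)
  ng <- length(rows)
  k <- stats::rbinom(ng, layout$chrom_len, rec_rate)
  start_hom <- sample.int(2L, ng, replace = TRUE) - 1L  # 0 = hap a, 1 = hap b
  src <- matrix(start_hom, nrow = ng, ncol = L)
  starts <- layout$loci$start
  for (j in which(k > 0L)) {
    pos <- sample.int(layout$chrom_len, k[j], replace = TRUE) - 1L
    bp <- reject_inside_loci(pos, layout)
    src[j, ] <- (start_hom[j] + findInterval(starts, bp)) %% 2L
  }
  g <- matrix(0L, nrow = ng, ncol = L)
  for (i in seq_len(L)) {
    g[, i] <- pop[cbind(rows, i + src[, i] * L)]
  }
  g
}

#' Fuse two gametes into a diploid zygote
#'
#' @param g1,g2 gamete haplotypes (integer vectors of equal length).
#' @return a one-row population matrix with `g1` as homolog a, `g2` as b.
#' @export
fuse_gametes <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  matrix(as.integer(c(g1, g2)), nrow = 1L)
}

#' Canonical multilocus genotype (MLG) keys
#'
#' One key per individual: the tuple of unordered allele pairs across loci.
#' Keys are phase-invariant -- swapping the two homologs of an individual
#' yields the same key -- so distinct keys count distinct clonal lineages.
#'
#' @param pop population matrix.
#' @return character vector of length `nrow(pop)`.
#' @export
mlg_keys <- function(pop) {
  pop <- pop_matrix(pop)
  L <- ncol(pop) %/% 2L
  a <- pop[, seq_len(L), drop = FALSE]
  b <- pop[, L + seq_len(L), drop = FALSE]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  parts <- lapply(seq_len(L), function(i) paste0(lo[, i], "/", hi[, i]))
  do.call(paste, c(parts, list(sep = "|")))
}
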