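# Independent oracles and small fixtures used across the suite.

# A tiny population of three printed genotypes over 5 loci (hap a | hap b):
#   ind1: (10,11,12,13,14 | 10,20,12,13,14)  -> het at locus 1
#   ind2: (10,11,12,13,14 | 10,20,12,13,14)  -> clone of ind1
#   ind3: (10,11,12,13,15 | 10,11,12,13,15)  -> fully homozygous, new allele 15
# Hand counts: alleles per locus = {10}, {11,20}, {12}, {13}, {14,15}
#   => A = 1 + 2 + 1 + 1 + 2 = 7; G = 2; H = (0 + 2/3 + 0 + 0 + 0)/5 = 2/15.
fixture_population <- function() {
  rbind(c(10, 11, 12, 13, 14, 10, 20, 12, 13, 14),
        c(10, 11, 12, 13, 14, 10, 20, 12, 13, 14),
        c(10, 11, 12, 13, 15, 10, 11, 12, 13, 15))
}

# Brute-force meiosis oracle: realises the per-base Bernoulli breakpoint law
# literally (one coin per inter-base position), redraws positions landing
# strictly inside a locus interval, and walks base by base. Independent of
# the package's findInterval-based path.
oracle_gamete <- function(ind, layout, rec_rate) {
  L <- nrow(layout$loci)
  k <- stats::rbinom(1L, layout$chrom_len, rec_rate)
  pos <- integer(0)
  if (k > 0L) {
    pos <- sample.int(layout$chrom_len, k, replace = TRUE) - 1L
    s <- layout$loci$start
    e <- layout$loci$end
    repeat {
      bad <- vapply(pos, function(p) any(p > s & p < e), logical(1))
      if (!any(bad)) break
      pos[bad] <- sample.int(layout$chrom_len, sum(bad), replace = TRUE) - 1L
    }
    pos <- sort(unique(pos))
  }
  hom <- sample(0:1, 1L)
  gam <- integer(L)
  for (i in seq_len(L)) {
    n_switch <- sum(pos <= layout$loci$start[i])
    src <- (hom + n_switch) %% 2L
    gam[i] <- ind[i + src * L]
  }
  gam
}

# Independent single-locus drift simulator: n diploid individuals, division
# (duplication) every `period` days followed by uniform down-sampling to n;
# returns the per-day fraction of heterozygotes.
oracle_drift_h <- function(n, days, period, n_alleles) {
  a <- sample.int(n_alleles, n, replace = TRUE)
  b <- sample.int(n_alleles, n, replace = TRUE)
  h <- numeric(days)
  for (t in seq_len(days) - 1L) {
    if (t %% period == 0L) {
      a <- c(a, a)
      b <- c(b, b)
      keep <- sample.int(length(a), n)
      a <- a[keep]
      b <- b[keep]
    }
    h[t + 1L] <- mean(a != b)
  }
  h
}

# Hand implementation of the binomial deviance dissimilarity between two
# profile rows (0 log 0 taken as 0).
oracle_binomial_d <- function(x, y) {
  n <- x + y
  term <- function(v) ifelse(v == 0, 0, v * log(v / n))
  sum(ifelse(n == 0, 0, (term(x) + term(y) + n * log(2)) / n))
}

# Small layout/config builders.
toy_layout <- function(seed = 7, chrom_len = 2000, n_loci = 2) {
  make_layout(seed, chrom_len = chrom_len, n_loci = n_loci)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(mut_rate = 1e-3, rec_rate = 1e-6, sex_rate = 0.35,
         K_bloom = 500, burn_in_years = 0L, sample_years = 1L),
    list(...))
  do.call(sim_config, args)
}
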