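#' Build a chromosome layout with randomly placed microsatellite loci
#'
#' Places `n_loci` microsatellite loci at random, non-overlapping coordinates
#' on a single chromosome. Each locus has a motif length drawn uniformly from
#' 1--6 bp and occupies, for the purpose of recombination exclusion, its
#' maximal possible extent of `motif_len * max_repeats` bases, so that
#' crossover breakpoints can be excluded from repeats independently of any
#' individual's current repeat counts. Alleles at a locus are tandem-repeat
#' counts bounded in `[min_repeats, max_repeats]`.
#'
#' The layout is fully reproducible from `layout_seed` and is intended to be
#' shared by every condition and replicate of one experiment.
#'
#' @param layout_seed integer seed controlling locus placement.
#' @param chrom_len chromosome length in base pairs.
#' @param n_loci number of microsatellite loci.
#' @param min_repeats,max_repeats bounds on the tandem-repeat count.
#' @param max_tries bound on rejection-sampling attempts before giving up.
#' @return An object of class `chrom_layout`: a list with `chrom_len`,
#'   `loci` (data frame with `locus_id`, `start`, `motif_len`, `end`;
#'   0-based half-open intervals), `min_repeats`, `max_repeats`,
#'   `layout_seed`.
#' @examples
#' lay <- make_layout(1, chrom_len = 1e5)
#' lay$loci
#' @export
make_layout <- function(layout_seed, chrom_len = 1e5, n_loci = 5,
                        min_repeats = 5L, max_repeats = 50L,
                        max_tries = 10000L) {
  stopifnot(n_loci >= 1, min_repeats < max_repeats, chrom_len >= 1)
  chrom_len <- as.integer(chrom_len)
  loci <- with_seed(layout_seed, {
    starts <- integer(0)
    lens <- integer(0)
    motifs <- integer(0)
    tries <- 0L
    while (length(starts) < n_loci) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", n_loci, " disjoint microsatellite intervals ",
             "on a chromosome of ", chrom_len, " bp after ", max_tries,
             " attempts; increase chrom_len")
      }
      motif <- sample.int(6L, 1L)
      len <- motif * as.integer(max_repeats)
      if (len > chrom_len) next
      s <- sample.int(chrom_len - len + 1L, 1L) - 1L
      if (length(starts) && any(s < starts + lens & starts < s + len)) next
      starts <- c(starts, s)
      lens <- c(lens, len)
      motifs <- c(motifs, motif)
    }
    ord <- order(starts)
    data.frame(locus_id = seq_len(n_loci) - 1L,
               start = starts[ord],
               motif_len = motifs[ord],
               end = starts[ord] + lens[ord])
  })
  structure(list(chrom_len = chrom_len, loci = loci,
                 min_repeats = as.integer(min_repeats),
                 max_repeats = as.integer(max_repeats),
                 layout_seed = layout_seed),
            class = "chrom_layout")
}

#' @export
print.chrom_layout <- function(x, ...) {
  cat("Chromosome layout:", x$chrom_len, "bp,", nrow(x$loci),
      "microsatellite loci (repeats in [", x$min_repeats, ",",
      x$max_repeats, "])\n")
  print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Write / read a chromosome layout as a tab-separated table
#'
#' Serialises the locus map (`locus_id`, `start`, `motif_len`) with a header
#' line; coordinates are 0-based half-open. `read_layout` needs the scalar
#' fields (`chrom_len`, repeat bounds) back as arguments since the table only
#' stores the map.
#'
#' @param layout a `chrom_layout`.
#' @param file path to the table.
#' @rdname layout_io
#' @export
write_layout <- function(layout, file) {
  utils::write.table(layout$loci[, c("locus_id", "start", "motif_len")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @param chrom_len,min_repeats,max_repeats scalar layout fields (see
#'   [make_layout()]).
#' @rdname layout_io
#' @export
read_layout <- function(file, chrom_len = 1e5, min_repeats = 5L,
                        max_repeats = 50L) {
  loci <- utils::read.table(file, header = TRUE, sep = "\t")
  loci$end <- loci$start + loci$motif_len * as.integer(max_repeats)
  loci <- loci[order(loci$start), ]
  structure(list(chrom_len = as.integer(chrom_len), loci = loci,
                 min_repeats = as.integer(min_repeats),
                 max_repeats = as.integer(max_repeats),
                 layout_seed = NA_integer_),
            class = "chrom_layout")
}

n_loci <- function(layout) nrow(layout$loci)
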