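#' Calendar state for an absolute simulation day
#'
#' Derives the year, day-of-year and the day's event flags from an absolute
#' day index `t >= 0`. Bloom days are the `bloom_len` days starting at
#' day-of-year `bloom_start`; the single sexual event of the year falls on
#' bloom day `sex_day`; stationary-phase clonal divisions happen on absolute
#' days divisible by `stationary_division_period`.
#'
#' @param t absolute day index (0-based).
#' @param cfg a `sim_config`.
#' @return list with `t`, `year`, `day_of_year`, `is_bloom`, `is_sex`,
#'   `is_division`.
#' @export
calendar <- function(t, cfg) {
  doy <- t %% cfg$year_len
  is_bloom <- cfg$bloom_len > 0 &&
    doy >= cfg$bloom_start && doy < cfg$bloom_start + cfg$bloom_len
  list(t = t,
       year = t %/% cfg$year_len,
       day_of_year = doy,
       is_bloom = is_bloom,
       is_sex = is_bloom && doy == cfg$bloom_start + cfg$sex_day - 1L,
       is_division = is_bloom || t %% cfg$stationary_division_period == 0L)
}

#' Carrying capacity in force on a given day
#'
#' @param cal a calendar state from [calendar()].
#' @param cfg a `sim_config`.
#' @return `K_bloom` on bloom days, `K_stationary` otherwise.
#' @export
current_capacity <- function(cal, cfg) {
  if (cal$is_bloom) cfg$K_bloom else cfg$K_stationary
}

#' One day of clonal reproduction
#'
#' On a bloom day every cell undergoes `bloom_divisions_per_day` successive
#' binary fissions (each parent is replaced by two daughters, each daughter
#' independently passed through [mutate_mitotic()]); on a stationary division
#' day every cell divides once; on other stationary days the population is
#' returned unchanged.
#'
#' @param pop population matrix.
#' @param cal calendar state.
#' @param cfg a `sim_config`.
#' @return the post-division population matrix.
#' @export
clonal_step <- function(pop, cal, cfg) {
  divisions <- if (cal$is_bloom) cfg$bloom_divisions_per_day
               else if (cal$is_division) 1L else 0L
  for (i in seq_len(divisions)) {
    pop <- mutate_mitotic(rbind(pop, pop), cfg$mut_rate)
  }
  pop
}

#' The annual sexual event
#'
#' A fraction `sex_rate` of the population (rounded down to an even count)
#' is drawn uniformly without replacement, paired at random into disjoint
#' mating pairs, and each pair is removed and replaced by
#' `offspring_per_mating` zygotes. Every zygote fuses two independent meiotic
#' gametes, one from each parent, so recombinant multilocus genotypes enter
#' the population here. Non-participants are unchanged. If fewer than two
#' participants are requested the event is skipped.
#'
#' @param pop population matrix.
#' @param cfg a `sim_config`.
#' @param layout a `chrom_layout`.
#' @return the post-sex population matrix.
#' @export
sex_event <- function(pop, cfg, layout) {
  N <- nrow(pop)
  n_part <- 2L * floor(cfg$sex_rate * N / 2)
  if (n_part < 2L) return(pop)
  part <- sample.int(N, n_part)
  m <- n_part %/% 2L
  p1 <- part[seq_len(m)]
  p2 <- part[m + seq_len(m)]
  off <- cfg$offspring_per_mating
  r1 <- rep(p1, each = off)
  r2 <- rep(p2, each = off)
  g1 <- meiosis_gametes(pop, r1, layout, cfg$rec_rate)
  g2 <- meiosis_gametes(pop, r2, layout, cfg$rec_rate)
  zygotes <- cbind(g1, g2)
  colnames(zygotes) <- colnames(pop)
  rbind(pop[-part, , drop = FALSE], zygotes)
}

#' Neutral regulation to the day's carrying capacity
#'
#' If the population exceeds `K`, a uniform random subset of size `K` is
#' kept (sampling without replacement, blind to genotype); otherwise the
#' population is returned unchanged. This daily sampling step is the only
#' source of mortality and produces the post-bloom bottlenecks.
#'
#' @param pop population matrix.
#' @param K carrying capacity (individuals).
#' @return the regulated population matrix.
#' @export
regulate <- function(pop, K) {
  N <- nrow(pop)
  if (N > K) pop <- pop[sample.int(N, K), , drop = FALSE]
  pop
}

#' Advance the population by one day
#'
#' Composition order: clonal division, then the sexual event (on the sex day,
#' when `sex_rate > 0`), then regulation to the day's carrying capacity.
#'
#' @param pop population matrix.
#' @param t absolute day index.
#' @param cfg a `sim_config`.
#' @param layout a `chrom_layout`.
#' @return the end-of-day population matrix.
#' @export
step_day <- function(pop, t, cfg, layout) {
  cal <- calendar(t, cfg)
  pop <- clonal_step(pop, cal, cfg)
  if (cal$is_sex && cfg$sex_rate > 0) {
    pop <- sex_event(pop, cfg, layout)
  }
  pop <- regulate(pop, current_capacity(cal, cfg))
  if (nrow(pop) < 1L) {
    stop("population went extinct on day ", t)
  }
  pop
}

#' Run one simulation
#'
#' Initialises the founder population, iterates [step_day()] over
#' `(burn_in_years + sample_years) * year_len` days, and records the
#' population-genetics metrics (and allele presence profiles) at the end of
#' every requested sampling day. Fully reproducible from the three seeds in
#' `cfg`: runs sharing `layout_seed` and `founder_seed` but differing in
#' `process_seed` start from the same input population and diverge from
#' day 0.
#'
#' @param cfg a `sim_config`.
#' @param layout optional pre-built `chrom_layout`; built from
#'   `cfg$layout_seed` when omitted.
#' @param sample_days absolute day indices at which to record state, or a
#'   `sampling_schedule` from [sampling_days()]; defaults to the standard
#'   cadence.
#' @param keep_genotypes if `TRUE`, the full genotype matrix of every
#'   sampled day is retained in the result (memory permitting).
#' @return An object of class `diatom_sim`: list with `config`, `layout`,
#'   `metrics` (data frame: `day`, `N`, `A`, `G`, `H`, `R`), `presence`
#'   (per-day, per-locus allele lists), optionally `genotypes`, and
#'   `final_pop`.
#' @examples
#' cfg <- sim_config(mut_rate = 1e-3, sex_rate = 0, K_bloom = 500,
#'                   burn_in_years = 0, sample_years = 1, profile = "desk")
#' sim <- run_simulation(cfg)
#' head(sim$metrics)
#' @export
run_simulation <- function(cfg, layout = NULL, sample_days = NULL,
                           keep_genotypes = FALSE) {
  validate_config(cfg)
  if (is.null(layout)) {
    layout <- make_layout(cfg$layout_seed, cfg$chrom_len, cfg$n_loci)
  }
  if (is.null(sample_days)) {
    sample_days <- sampling_days("standard", cfg)
  }
  if (inherits(sample_days, "sampling_schedule")) {
    sample_days <- sample_days$days
  }
  sample_days <- sort(unique(as.integer(sample_days)))
  pop <- founder_population(cfg$founder_seed, cfg$founder_size, layout)
  total_days <- (cfg$burn_in_years + cfg$sample_years) * cfg$year_len
  record <- logical(total_days)
  record[sample_days[sample_days < total_days] + 1L] <- TRUE

  rows <- vector("list", sum(record))
  presence <- vector("list", sum(record))
  genotypes <- if (keep_genotypes) vector("list", sum(record)) else NULL
  ri <- 0L

  with_seed(cfg$process_seed, {
    for (t in seq_len(total_days) - 1L) {
      pop <- step_day(pop, t, cfg, layout)
      if (record[t + 1L]) {
        ri <- ri + 1L
        met <- compute_metrics(pop)
        rows[[ri]] <- data.frame(day = t, N = met$N, A = met$A, G = met$G,
                                 H = met$H, R = met$R)
        presence[[ri]] <- allele_presence(pop)
        if (keep_genotypes) genotypes[[ri]] <- pop
      }
    }
  })
  metrics <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(metrics)) {
    metrics <- data.frame(day = integer(0), N = integer(0), A = integer(0),
                          G = integer(0), H = numeric(0), R = numeric(0))
  }
  names(presence) <- metrics$day
  if (keep_genotypes) names(genotypes) <- metrics$day
  structure(list(config = cfg, layout = layout, metrics = metrics,
                 presence = presence[seq_len(ri)],
                 genotypes = if (keep_genotypes) genotypes[seq_len(ri)],
                 final_pop = pop),
            class = "diatom_sim")
}

#' @export
print.diatom_sim <- function(x, ...) {
  cfg <- x$config
  cat("Diatom microevolution run:", nrow(x$metrics), "sampled days over",
      cfg$burn_in_years + cfg$sample_years, "years\n")
  cat(sprintf("  rates: mut %.2g, rec %.2g, sex %.2g; K %d/%d\n",
              cfg$mut_rate, cfg$rec_rate, cfg$sex_rate,
              cfg$K_stationary, cfg$K_bloom))
  if (nrow(x$metrics)) {
    cat("  last sampled day:\n")
    print(utils::tail(x$metrics, 1L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.diatom_sim <- function(object, ...) {
  m <- object$metrics
  cat("Sampled-day metric ranges (", nrow(m), " days):\n", sep = "")
  print(rbind(min = vapply(m[-1], min, numeric(1)),
              mean = vapply(m[-1], mean, numeric(1)),
              max = vapply(m[-1], max, numeric(1))))
  invisible(object)
}

#' Plot a metric trajectory of a run
#'
#' Draws the chosen metric against the sampling day, shading bloom windows.
#'
#' @param x a `diatom_sim`.
#' @param metric one of `"R"`, `"H"`, `"A"`, `"G"`, `"N"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diatom_sim <- function(x, metric = "R", ...) {
  m <- x$metrics
  cfg <- x$config
  graphics::plot(m$day, m[[metric]], type = "l", xlab = "day",
                 ylab = metric, ...)
  yrs <- unique(m$day %/% cfg$year_len)
  for (y in yrs) {
    graphics::rect(y * cfg$year_len + cfg$bloom_start,
                   graphics::par("usr")[3],
                   y * cfg$year_len + cfg$bloom_start + cfg$bloom_len,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
  }
  graphics::lines(m$day, m[[metric]])
  invisible(x)
}

#' Write sampled genotypes as a tidy CSV
#'
#' One row per individual per sampled day; requires a run performed with
#' `keep_genotypes = TRUE`.
#'
#' @param sim a `diatom_sim`.
#' @param file output path.
#' @export
write_snapshots <- function(sim, file) {
  if (is.null(sim$genotypes)) {
    stop("run_simulation() must be called with keep_genotypes = TRUE")
  }
  tabs <- lapply(names(sim$genotypes), function(d) {
    g <- sim$genotypes[[d]]
    cbind(data.frame(day = as.integer(d)), as.data.frame(g))
  })
  utils::write.csv(do.call(rbind, tabs), file, row.names = FALSE)
  invisible(file)
}
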