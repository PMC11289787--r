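#' Simulation configuration
#'
#' Collects every rate, capacity, calendar constant and seed that defines one
#' simulation run. Defaults reproduce the full study conditions: carrying
#' capacity switching between 1e2 (stationary phase) and 1e5 (bloom)
#' individuals, a 30-day bloom each 365-day year with one sexual event at
#' mid-bloom, two clonal divisions per day during blooms and one every five
#' days otherwise, an 11-year burn-in and 5 sampled years. The `"desk"`
#' profile is a scaled-down configuration (K_bloom = 1e4, 2 + 2 years) that
#' preserves the full dynamical structure at a fraction of the cost.
#'
#' @param mut_rate per-locus, per-homolog mitotic mutation probability.
#' @param rec_rate per-base crossover breakpoint probability at meiosis.
#' @param sex_rate fraction of the population participating in the annual
#'   sexual event; 0 disables sex (obligate clonality).
#' @param K_stationary,K_bloom carrying capacities (individuals) outside and
#'   inside blooms.
#' @param year_len days per year.
#' @param bloom_len bloom duration in days.
#' @param bloom_start day-of-year (0-based) on which the bloom begins.
#' @param sex_day 1-based day offset of the sexual event within the bloom.
#' @param stationary_division_period days between clonal divisions in the
#'   stationary phase.
#' @param bloom_divisions_per_day clonal divisions per day during blooms.
#' @param burn_in_years unmonitored years before sampling starts.
#' @param sample_years monitored years.
#' @param offspring_per_mating zygotes produced per mating pair; 2 keeps the
#'   population size unchanged by sex.
#' @param chrom_len chromosome length in bp.
#' @param n_loci number of microsatellite loci.
#' @param founder_size founder population size.
#' @param layout_seed,founder_seed,process_seed seeds for, respectively,
#'   locus placement, the founder population, and all per-day randomness.
#' @param profile `"paper"` for the full-scale defaults, `"desk"` for the
#'   scaled-down profile.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(mut_rate = 1e-3, rec_rate = 1e-6, sex_rate = 0.35,
#'                   profile = "desk")
#' @export
sim_config <- function(mut_rate = 1e-3, rec_rate = 1e-6, sex_rate = 0.35,
                       K_stationary = 1e2, K_bloom = 1e5,
                       year_len = 365L, bloom_len = 30L, bloom_start = 1L,
                       sex_day = 15L, stationary_division_period = 5L,
                       bloom_divisions_per_day = 2L,
                       burn_in_years = 11L, sample_years = 5L,
                       offspring_per_mating = 2L,
                       chrom_len = 1e5, n_loci = 5L, founder_size = 1e2,
                       layout_seed = 1L, founder_seed = 2L, process_seed = 3L,
                       profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (missing(K_bloom)) K_bloom <- 1e4
    if (missing(burn_in_years)) burn_in_years <- 2L
    if (missing(sample_years)) sample_years <- 2L
  }
  cfg <- list(mut_rate = mut_rate, rec_rate = rec_rate, sex_rate = sex_rate,
              K_stationary = as.integer(K_stationary),
              K_bloom = as.integer(K_bloom),
              year_len = as.integer(year_len),
              bloom_len = as.integer(bloom_len),
              bloom_start = as.integer(bloom_start),
              sex_day = as.integer(sex_day),
              stationary_division_period = as.integer(stationary_division_period),
              bloom_divisions_per_day = as.integer(bloom_divisions_per_day),
              burn_in_years = as.integer(burn_in_years),
              sample_years = as.integer(sample_years),
              offspring_per_mating = as.integer(offspring_per_mating),
              chrom_len = as.integer(chrom_len), n_loci = as.integer(n_loci),
              founder_size = as.integer(founder_size),
              layout_seed = as.integer(layout_seed),
              founder_seed = as.integer(founder_seed),
              process_seed = as.integer(process_seed),
              profile = profile)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$mut_rate >= 0, cfg$mut_rate <= 1,
            cfg$rec_rate >= 0, cfg$rec_rate <= 1,
            cfg$sex_rate >= 0, cfg$sex_rate <= 1,
            cfg$K_bloom >= cfg$K_stationary, cfg$K_stationary >= 2,
            cfg$bloom_len >= 0,
            cfg$bloom_start + cfg$bloom_len <= cfg$year_len,
            cfg$bloom_len == 0 || (cfg$sex_day >= 1 && cfg$sex_day <= cfg$bloom_len),
            cfg$stationary_division_period >= 1,
            cfg$bloom_divisions_per_day >= 1,
            cfg$burn_in_years >= 0, cfg$sample_years >= 1,
            cfg$offspring_per_mating >= 1,
            cfg$founder_size >= 2)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (", x$profile, " profile)\n", sep = "")
  cat(sprintf("  rates: mut %.2g, rec %.2g, sex %.2g\n",
              x$mut_rate, x$rec_rate, x$sex_rate))
  cat(sprintf("  capacity: %d stationary / %d bloom; bloom %d d from day %d, sex on bloom day %d\n",
              x$K_stationary, x$K_bloom, x$bloom_len, x$bloom_start, x$sex_day))
  cat(sprintf("  horizon: %d burn-in + %d sampled years of %d days\n",
              x$burn_in_years, x$sample_years, x$year_len))
  cat(sprintf("  seeds: layout %d, founder %d, process %d\n",
              x$layout_seed, x$founder_seed, x$process_seed))
  invisible(x)
}

#' Read / write a simulation configuration as a YAML file
#'
#' @param cfg a `sim_config`.
#' @param file path.
#' @rdname config_io
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname config_io
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  vals <- vals[names(vals) != "profile"]
  do.call(sim_config, c(vals, list(profile = "paper")))
}
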