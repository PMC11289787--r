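#' Enumerate the factorial condition grid
#'
#' The full cross of 3 mutation rates, 4 recombination rates and 3 sex rates
#' (36 sexual conditions) plus one obligate-clonal control per mutation rate
#' (sex rate 0, recombination irrelevant), for 39 conditions in total. The
#' recombination regimes span 1e-8 to 1e-2; 1e-6 completes the four-regime
#' ladder and is the value used by the high-resolution runs.
#'
#' @param mut_rates,rec_rates,sex_rates factor levels.
#' @return data frame with `condition_id`, `mut_rate`, `rec_rate`,
#'   `sex_rate`, `is_asexual`, in a deterministic order.
#' @examples
#' g <- build_grid()
#' nrow(g)              # 39
#' sum(!g$is_asexual)   # 36
#' @export
build_grid <- function(mut_rates = c(1e-4, 1e-3, 1e-2),
                       rec_rates = c(1e-8, 1e-6, 1e-4, 1e-2),
                       sex_rates = c(0.2, 0.35, 0.5)) {
  sexual <- expand.grid(mut_rate = mut_rates, rec_rate = rec_rates,
                        sex_rate = sex_rates, KEEP.OUT.ATTRS = FALSE)
  asexual <- data.frame(mut_rate = mut_rates, rec_rate = 0, sex_rate = 0)
  g <- rbind(sexual, asexual)
  g$is_asexual <- g$sex_rate == 0
  g$condition_id <- ifelse(g$is_asexual,
                           sprintf("m%.0e_asex", g$mut_rate),
                           sprintf("m%.0e_r%.0e_s%.2f",
                                   g$mut_rate, g$rec_rate, g$sex_rate))
  rownames(g) <- NULL
  g[, c("condition_id", "mut_rate", "rec_rate", "sex_rate", "is_asexual")]
}

#' Sampling schedules over the monitored years
#'
#' The standard cadence records every 7 days inside blooms and every 60 days
#' outside; the high cadence records daily inside blooms and every 10 days
#' outside. Both include the last pre-bloom day and the first post-bloom day
#' of every monitored year. All days are absolute indices at or after the end
#' of the burn-in.
#'
#' @param resolution `"standard"` or `"high"`.
#' @param cfg a `sim_config`.
#' @return object of class `sampling_schedule`: list with `resolution` and
#'   sorted absolute `days`.
#' @export
sampling_days <- function(resolution = c("standard", "high"), cfg) {
  resolution <- match.arg(resolution)
  in_step <- if (resolution == "high") 1L else 7L
  out_step <- if (resolution == "high") 10L else 60L
  bs <- cfg$bloom_start
  be <- cfg$bloom_start + cfg$bloom_len        # first post-bloom day-of-year
  doy <- c(if (bs >= 1L) bs - 1L,              # last pre-bloom day
           if (cfg$bloom_len > 0L) seq.int(bs, be - 1L, by = in_step),
           if (be < cfg$year_len) seq.int(be, cfg$year_len - 1L, by = out_step))
  doy <- sort(unique(doy))
  years <- seq.int(cfg$burn_in_years,
                   cfg$burn_in_years + cfg$sample_years - 1L)
  days <- sort(unique(as.integer(outer(doy, years * cfg$year_len, "+"))))
  structure(list(resolution = resolution, days = days),
            class = "sampling_schedule")
}

#' Run a grid of simulation experiments
#'
#' Executes `replicates` runs for every condition of `grid`, all sharing one
#' chromosome layout and one founder population (so replicates of a condition
#' start identically and diverge through process randomness), and collects
#' the per-day metrics into one tidy table. Failures of individual cells are
#' caught and flagged in the manifest rather than aborting the grid.
#'
#' @param grid data frame as from [build_grid()] (any subset works).
#' @param replicates runs per condition.
#' @param resolution sampling cadence, see [sampling_days()].
#' @param base_cfg a `sim_config` providing the demographic constants and
#'   seeds; the grid overrides its rates per condition.
#' @param keep_presence if `TRUE`, per-run presence records are retained in
#'   the result (`$presence`, keyed by `condition_id.replicate`).
#' @return object of class `diatom_experiment`: list with `metrics` (tidy
#'   data frame), `manifest` (per-run status and seed), `grid`, `config`,
#'   `layout`, `schedule`, optionally `presence`.
#' @export
run_experiment <- function(grid = build_grid(), replicates = 6,
                           resolution = c("standard", "high"),
                           base_cfg = sim_config(), keep_presence = FALSE) {
  resolution <- match.arg(resolution)
  layout <- make_layout(base_cfg$layout_seed, base_cfg$chrom_len,
                        base_cfg$n_loci)
  schedule <- sampling_days(resolution, base_cfg)
  metrics <- list()
  manifest <- list()
  presence <- if (keep_presence) list()
  for (ci in seq_len(nrow(grid))) {
    for (rep in seq_len(replicates)) {
      seed <- derive_seed(base_cfg$process_seed, ci, rep)
      cfg <- base_cfg
      cfg$mut_rate <- grid$mut_rate[ci]
      cfg$rec_rate <- grid$rec_rate[ci]
      cfg$sex_rate <- grid$sex_rate[ci]
      cfg$process_seed <- as.integer(seed)
      key <- paste0(grid$condition_id[ci], ".", rep)
      status <- "ok"
      msg <- ""
      sim <- tryCatch(
        run_simulation(cfg, layout = layout, sample_days = schedule),
        error = function(e) {
          status <<- "failed"
          msg <<- conditionMessage(e)
          NULL
        })
      if (!is.null(sim) && nrow(sim$metrics)) {
        m <- sim$metrics
        m$condition_id <- grid$condition_id[ci]
        m$replicate <- rep
        m$mut_rate <- grid$mut_rate[ci]
        m$rec_rate <- grid$rec_rate[ci]
        m$sex_rate <- grid$sex_rate[ci]
        metrics[[key]] <- m
        if (keep_presence) presence[[key]] <- sim$presence
      }
      manifest[[key]] <- data.frame(condition_id = grid$condition_id[ci],
                                    replicate = rep, process_seed = seed,
                                    status = status, message = msg)
    }
  }
  structure(list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
                 manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
                 grid = grid, config = base_cfg, layout = layout,
                 schedule = schedule,
                 presence = presence),
            class = "diatom_experiment")
}

#' @export
print.diatom_experiment <- function(x, ...) {
  cat("Diatom microevolution experiment:", nrow(x$grid), "conditions x",
      max(x$manifest$replicate), "replicates (",
      sum(x$manifest$status == "ok"), "ok /",
      sum(x$manifest$status != "ok"), "failed )\n")
  cat("  sampling:", x$schedule$resolution, "resolution,",
      length(x$schedule$days), "days per run\n")
  invisible(x)
}
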