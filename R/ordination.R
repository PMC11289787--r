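#' Build the index matrix (days x metrics) from a metrics table
#'
#' Rows with `N < 2` (where R is undefined) are dropped.
#'
#' @param metrics data frame with columns `A`, `G`, `H`, `R` (and `N`).
#' @return numeric matrix with columns A, G, H, R.
#' @export
index_matrix <- function(metrics) {
  keep <- if ("N" %in% names(metrics)) metrics$N >= 2 else TRUE
  m <- as.matrix(metrics[keep, c("A", "G", "H", "R")])
  storage.mode(m) <- "double"
  m
}

#' PCA of the index matrix
#'
#' Columns are centred and (by default) scaled to unit variance, then
#' decomposed by singular value decomposition. Constant columns cannot be
#' scaled and are dropped with a warning.
#'
#' @param m numeric matrix, days in rows, indices in columns.
#' @param scale scale columns to unit variance before decomposition.
#' @return list with `scores`, `loadings`, `var_frac` (variance fraction per
#'   component) and `sdev`.
#' @export
pca_indices <- function(m, scale = TRUE) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 3)
  if (scale) {
    v <- apply(m, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(m)[v == 0], collapse = ", "))
      m <- m[, v > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  list(scores = p$x, loadings = p$rotation,
       var_frac = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimisation by iterative monotone regression from
#' multiple random starts, via [vegan::metaMDS()]; the best configuration
#' and its stress are returned. Deterministic given `seed`.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param dims embedding dimension.
#' @param n_starts random starts.
#' @param max_iter iterations per start.
#' @param seed optional integer seed.
#' @return list with `points` (configuration), `stress` (fraction in
#'   `[0, 1]`) and `converged`.
#' @export
nmds <- function(d, dims = 2, n_starts = 20, max_iter = 300, seed = NULL) {
  d <- stats::as.dist(d)
  fit_one <- function() {
    vegan::metaMDS(d, k = dims, try = n_starts, trymax = n_starts,
                   maxit = max_iter, trace = 0)
  }
  fit <- if (is.null(seed)) fit_one() else with_seed(seed, fit_one())
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || is.numeric(fit$converged))
}

least_squares_slope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}

#' Detect the three-stage within-bloom diversity signature
#'
#' Operationalises the three stages of the within-bloom trajectory of
#' genotypic diversity R, given daily values over one bloom:
#' \describe{
#'   \item{stage1_drop}{the minimum of R over the first `drop_window` bloom
#'     days falls below the last pre-bloom value (density rises, lineage
#'     count does not);}
#'   \item{stage2_rise}{positive least-squares slope of R from bloom day
#'     `drop_window` to the day before the sexual event (new lineages from
#'     mutation and recombination accumulate);}
#'   \item{sex_spike}{R the day after the sexual event exceeds R the day
#'     before it (recombinant genotypes enter at once); structurally FALSE
#'     for asexual runs;}
#'   \item{stage3_decay}{negative least-squares slope from two days after
#'     the sexual event to the end of the bloom (drift erodes diversity).}
#' }
#'
#' @param r_bloom numeric vector of daily R values on bloom days 1..bloom_len.
#' @param pre_bloom_r R on the last day before the bloom.
#' @param sex_day 1-based bloom-day offset of the sexual event.
#' @param sexual whether a sexual event actually occurred in this run.
#' @param drop_window number of initial bloom days inspected for the drop.
#' @return one-row data frame with the four logical flags and their effect
#'   sizes (`drop_depth`, `rise_slope`, `spike_height`, `decay_slope`).
#' @export
bloom_signature <- function(r_bloom, pre_bloom_r, sex_day, sexual = TRUE,
                            drop_window = 5L) {
  n <- length(r_bloom)
  if (n < sex_day + 2L || anyNA(r_bloom) || is.na(pre_bloom_r)) {
    stop("bloom_signature needs complete daily R values over the bloom")
  }
  drop_depth <- pre_bloom_r - min(r_bloom[seq_len(drop_window)])
  rise_days <- seq.int(drop_window, sex_day - 1L)
  rise_slope <- least_squares_slope(rise_days, r_bloom[rise_days])
  spike_height <- if (sexual) r_bloom[sex_day + 1L] - r_bloom[sex_day - 1L]
                  else NA_real_
  decay_days <- seq.int(sex_day + 2L, n)
  decay_slope <- least_squares_slope(decay_days, r_bloom[decay_days])
  data.frame(stage1_drop = drop_depth > 0,
             stage2_rise = rise_slope > 0,
             sex_spike = isTRUE(spike_height > 0),
             stage3_decay = decay_slope < 0,
             drop_depth = drop_depth, rise_slope = rise_slope,
             spike_height = spike_height, decay_slope = decay_slope)
}

#' Signature report over every bloom of an experiment
#'
#' Applies [bloom_signature()] to each (condition, replicate, year) bloom
#' for which the metrics table has daily coverage (high-resolution
#' sampling) plus the pre-bloom day.
#'
#' @param metrics tidy metrics table with `day`, `R` and, if present,
#'   `condition_id`, `replicate`, `sex_rate`.
#' @param cfg the `sim_config` the runs used (for the bloom calendar).
#' @param drop_window passed to [bloom_signature()].
#' @return data frame: one row per detected bloom with identifiers, year and
#'   the signature flags/effect sizes.
#' @export
signature_report <- function(metrics, cfg, drop_window = 5L) {
  if (is.null(metrics$condition_id)) metrics$condition_id <- "run"
  if (is.null(metrics$replicate)) metrics$replicate <- 1L
  out <- list()
  for (key in unique(paste(metrics$condition_id, metrics$replicate))) {
    m <- metrics[paste(metrics$condition_id, metrics$replicate) == key, ]
    sexual <- if (!is.null(m$sex_rate)) m$sex_rate[1] > 0 else TRUE
    for (y in unique(m$day %/% cfg$year_len)) {
      base <- y * cfg$year_len
      bloom_days <- base + cfg$bloom_start + seq_len(cfg$bloom_len) - 1L
      pre_day <- base + cfg$bloom_start - 1L
      idx <- match(bloom_days, m$day)
      pre <- match(pre_day, m$day)
      if (anyNA(idx) || is.na(pre)) next
      sig <- bloom_signature(m$R[idx], m$R[pre], cfg$sex_day,
                             sexual = sexual, drop_window = drop_window)
      out[[paste(key, y)]] <- cbind(
        data.frame(condition_id = m$condition_id[1],
                   replicate = m$replicate[1], year = y),
        sig)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Linear trend of heterozygosity over time
#'
#' Least-squares slope of H against the sampling day, with its standard
#' error. Sexual runs are expected to show a larger (more positive) slope
#' than matched asexual runs: bottleneck sampling preferentially removes
#' clonal lines that contribute little heterozygosity, and sex keeps
#' re-creating heterozygotes.
#'
#' @param metrics data frame with columns `day` and `H` (one run).
#' @return named numeric vector: `slope` (per day) and `se`.
#' @export
h_trend <- function(metrics) {
  stopifnot(nrow(metrics) >= 10)
  fit <- stats::lm(H ~ day, data = metrics)
  co <- summary(fit)$coefficients
  c(slope = unname(co["day", "Estimate"]), se = unname(co["day", "Std. Error"]))
}
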