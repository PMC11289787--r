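# Daily demographic loop: capacity switching, division schedule, sex,
# regulation, and whole-run reproducibility.

test_that("carrying capacity switches with the bloom calendar", {
  cfg <- sim_config()
  expect_equal(current_capacity(calendar(1, cfg), cfg), 1e5)    # bloom day
  expect_equal(current_capacity(calendar(200, cfg), cfg), 1e2)  # stationary
  cal0 <- calendar(0, cfg)  # with bloom_start = 1, day 0 is stationary
  expect_false(cal0$is_bloom)
  expect_equal(current_capacity(cal0, cfg), 1e2)
})

test_that("the calendar has one sex day per year, inside the bloom", {
  cfg <- sim_config()
  cals <- lapply(0:(2 * 365 - 1), calendar, cfg = cfg)
  sex <- vapply(cals, `[[`, logical(1), "is_sex")
  bloom <- vapply(cals, `[[`, logical(1), "is_bloom")
  expect_equal(sum(sex[1:365]), 1)
  expect_equal(sum(sex), 2)
  expect_true(all(bloom[sex]))
  expect_equal(sum(bloom), 2 * cfg$bloom_len)
})

test_that("clonal division follows the period-dependent schedule", {
  cfg <- sim_config(mut_rate = 0)
  pop <- founder_population(1, 100, make_layout(1))
  bloom <- clonal_step(pop, calendar(1, cfg), cfg)
  expect_equal(nrow(bloom), 400)                      # two doublings
  expect_setequal(mlg_keys(bloom), mlg_keys(pop))     # all clones of parents
  div <- clonal_step(pop, calendar(200, cfg), cfg)    # 200 %% 5 == 0
  expect_equal(nrow(div), 200)
  idle <- clonal_step(pop, calendar(202, cfg), cfg)
  expect_identical(idle, pop)
})

test_that("the sex event pairs the right number of cells and conserves N", {
  set.seed(21)
  lay <- make_layout(1)
  cfg <- sim_config(sex_rate = 0.2, rec_rate = 1e-4, mut_rate = 0)
  pop <- founder_population(1, 1000, lay)
  expect_identical(sex_event(pop, sim_config(sex_rate = 0), lay), pop)
  after <- sex_event(pop, cfg, lay)
  # 200 participants -> 100 matings x 2 offspring: N unchanged
  expect_equal(nrow(after), 1000)
  # odd participant request is rounded down to an even pairing
  cfg$sex_rate <- 0.35
  expect_equal(nrow(sex_event(pop[1:21, ], cfg, lay)), 21)
})

test_that("offspring of distinct homozygous parents are heterozygous", {
  set.seed(5)
  lay <- make_layout(1)
  cfg <- sim_config(sex_rate = 1, rec_rate = 0, mut_rate = 0)
  pop <- rbind(matrix(10L, 1, 10), matrix(30L, 1, 10))
  kids <- sex_event(pop, cfg, lay)
  expect_equal(nrow(kids), 2)
  expect_equal(heterozygosity(kids), 1)
})

test_that("sex preserves per-locus allele frequencies in expectation", {
  set.seed(31)
  lay <- make_layout(1)
  cfg <- sim_config(sex_rate = 1, rec_rate = 1e-4, mut_rate = 0)
  pop <- founder_population(4, 200, lay)
  focal <- pop[1, 1]  # focal allele at locus 0
  freq <- function(m) mean(c(m[, 1], m[, 6]) == focal)
  f0 <- freq(pop)
  reps <- 400
  f1 <- vapply(seq_len(reps), function(i) freq(sex_event(pop, cfg, lay)),
               numeric(1))
  se <- stats::sd(f1) / sqrt(reps)
  expect_lt(abs(mean(f1) - f0), 3 * se + 1e-8)
})

test_that("regulation keeps at most K individuals, neutrally", {
  set.seed(13)
  pop <- founder_population(1, 400, make_layout(1))
  expect_equal(nrow(regulate(pop, 100)), 100)
  expect_identical(regulate(pop[1:50, ], 100), pop[1:50, ])
  focal <- pop[1, 1]
  freq <- function(m) mean(c(m[, 1], m[, 6]) == focal)
  f0 <- freq(pop)
  f1 <- vapply(1:1000, function(i) freq(regulate(pop, 100)), numeric(1))
  se <- stats::sd(f1) / sqrt(1000)
  expect_lt(abs(mean(f1) - f0), 3 * se)
})

test_that("a day composes division, sex and regulation in order", {
  set.seed(17)
  lay <- make_layout(1)
  cfg <- sim_config(mut_rate = 0, rec_rate = 0, sex_rate = 0)
  pop <- founder_population(1, 100, lay)
  # first bloom day from stationary: 100 -> 400, under K_bloom
  expect_equal(nrow(step_day(pop, 1, cfg, lay)), 400)
  # first post-bloom day: bloom-sized population collapses to K_stationary
  big <- founder_population(2, 5000, lay)
  post <- step_day(big, 31, cfg, lay)  # day-of-year 31, not a division day
  expect_equal(nrow(post), 100)
})

test_that("with all rates zero no new multilocus genotypes ever appear", {
  set.seed(23)
  lay <- make_layout(1)
  cfg <- sim_config(mut_rate = 0, rec_rate = 0, sex_rate = 0,
                    K_bloom = 2000)
  pop <- founder_population(1, 100, lay)
  seen <- unique(mlg_keys(pop))
  for (t in 0:99) {
    pop <- step_day(pop, t, cfg, lay)
    expect_true(all(mlg_keys(pop) %in% seen))
  }
})

test_that("with all rates zero drift only removes diversity", {
  cfg <- tiny_config(mut_rate = 0, rec_rate = 0, sex_rate = 0,
                     founder_seed = 9L, process_seed = 77L)
  sim <- run_simulation(cfg, sample_days = 0:364, keep_genotypes = TRUE)
  m <- sim$metrics
  expect_true(all(diff(m$A) <= 0))
  expect_true(all(diff(m$G) <= 0))
  # clonal lineages inherit their heterozygosity unchanged, so while the
  # population mean H drifts (removing a low-H lineage raises it), every
  # individual's heterozygosity value must already exist among the founders
  lay <- sim$layout
  founder_h <- apply(founder_population(cfg$founder_seed, cfg$founder_size,
                                        lay), 1,
                     function(x) mean(x[1:5] != x[6:10]))
  for (g in sim$genotypes[c(1, 100, 365)]) {
    ind_h <- apply(g, 1, function(x) mean(x[1:5] != x[6:10]))
    expect_true(all(ind_h %in% founder_h))
    expect_lte(max(ind_h), max(founder_h))
  }
  expect_true(all(m$H <= max(founder_h) + 1e-12))
})

test_that("runs are reproducible from seeds and replicates share founders", {
  cfg <- tiny_config()
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  cfg2 <- cfg
  cfg2$process_seed <- cfg$process_seed + 1L
  c <- run_simulation(cfg2)
  expect_identical(founder_population(cfg$founder_seed, 10, a$layout),
                   founder_population(cfg2$founder_seed, 10, a$layout))
  expect_false(identical(a$metrics, c$metrics))
})

test_that("the default horizon spans 16 simulated years", {
  cfg <- sim_config()
  expect_equal((cfg$burn_in_years + cfg$sample_years) * cfg$year_len, 5840)
})

test_that("bloom growth saturates at K_bloom within ceiling(log4(Kb/Ks)) days", {
  set.seed(41)
  lay <- make_layout(1)
  cfg <- sim_config(mut_rate = 0, rec_rate = 0, sex_rate = 0, K_bloom = 1e4)
  pop <- founder_population(1, 100, lay)
  sizes <- integer(10)
  for (t in 1:10) {  # bloom days 1..10
    pop <- step_day(pop, t, cfg, lay)
    sizes[t] <- nrow(pop)
  }
  reach <- ceiling(log(1e4 / 1e2, base = 4))  # = 4
  expect_true(all(sizes[reach:10] == 1e4))
  expect_true(all(sizes[seq_len(reach - 1)] < 1e4))
})

test_that("small-K heterozygosity decay matches an independent drift simulator", {
  # K = 20, divisions every 5 days, no blooms, no mutation or sex: the
  # engine's per-day mean H must track a separately coded single-locus
  # duplicate-and-sample simulator started from the same allele law.
  n_rep <- 500
  days <- 100
  cfg <- tiny_config(mut_rate = 0, rec_rate = 0, sex_rate = 0,
                     K_stationary = 20, K_bloom = 20, bloom_len = 0L,
                     founder_size = 20, year_len = days)
  set.seed(61)
  eng <- matrix(0, n_rep, days)
  for (r in seq_len(n_rep)) {
    c2 <- cfg
    c2$founder_seed <- 1000L + r
    c2$process_seed <- 5000L + r
    eng[r, ] <- run_simulation(c2, sample_days = seq_len(days) - 1L)$metrics$H
  }
  set.seed(62)
  orc <- t(vapply(seq_len(n_rep), function(r) oracle_drift_h(20, days, 5, 46),
                  numeric(days)))
  for (d in c(25, 50, 100)) {
    diff_se <- sqrt(stats::var(eng[, d]) / n_rep + stats::var(orc[, d]) / n_rep)
    expect_lt(abs(mean(eng[, d]) - mean(orc[, d])), 3 * diff_se + 1e-8)
  }
})
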