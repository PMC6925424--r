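small_sweep <- function(...) {
  sweep_config(delta_g_grid = c(1, 3, 5), runs_per_delta_g = 60L,
               rng_seed = 7L, ...)
}

test_that("the sweep is bit-reproducible for a fixed seed", {
  a <- run_sweep(small_sweep())
  b <- run_sweep(small_sweep())
  expect_identical(a$counts, b$counts)
  expect_identical(a$scatter, b$scatter)
})

test_that("the vectorised sweep agrees with a run_single loop over identical draws", {
  cfg <- small_sweep()
  res <- run_sweep(cfg)
  set.seed(cfg$rng_seed)
  n <- cfg$runs_per_delta_g
  for (g in seq_along(cfg$delta_g_grid)) {
    dg <- cfg$delta_g_grid[g]
    a_lake_l <- runif(n, cfg$alpha_ranges_large[1], cfg$alpha_ranges_large[2])
    a_stream_l <- runif(n, cfg$alpha_ranges_large[3], cfg$alpha_ranges_large[4])
    a_lake_s <- runif(n, cfg$alpha_ranges_small[1], cfg$alpha_ranges_small[2])
    a_stream_s <- runif(n, cfg$alpha_ranges_small[3], cfg$alpha_ranges_small[4])
    singles <- lapply(seq_len(n), function(i)
      run_single(dg, c(a_lake_l[i], a_stream_l[i], a_lake_s[i], a_stream_s[i]),
                 cfg$base_scenario, cfg$sizes, cfg$band_days))
    expect_identical(res$counts$matched[g],
                     sum(vapply(singles, `[[`, TRUE, "matched")))
    # matched runs must agree on the crossing days and (numerically) ratios
    matched_idx <- which(vapply(singles, `[[`, TRUE, "matched"))
    sl <- res$scatter[res$scatter$delta_g == dg &
                        res$scatter$size_class == "large", ]
    expect_equal(sl$day,
                 vapply(singles[matched_idx],
                        function(x) x$crossing_large$crossing_day, 1L))
    expect_equal(sl$ratio_lake,
                 vapply(singles[matched_idx],
                        function(x) x$crossing_large$ratio_lake_at_crossing, 1),
                 tolerance = 1e-12)
  }
})

test_that("an unmatchable band yields zero matched runs and an absent argmax", {
  cfg <- sweep_config(delta_g_grid = c(2, 4), runs_per_delta_g = 100L,
                      band_days = c(10000, 10001), rng_seed = 5L)
  res <- run_sweep(cfg)
  expect_true(all(res$counts$matched == 0L))
  expect_equal(nrow(res$scatter), 0L)
  expect_true(is.na(summarize_sweep(res)$argmax_delta_g))
})

test_that("identical vulnerabilities for both classes give a zero-day gap and never match", {
  base <- default_scenario()
  out <- run_single(4, c(2, 0.5, 2, 0.5), base)
  expect_equal(out$gap_days, 0L)
  expect_false(out$matched)
  none <- run_single(1, c(5, 0.01, 5, 0.1),
                     symmetric_scenario(p_lake = 100, p_stream = 1))
  expect_true(is.na(none$gap_days))
  expect_false(none$matched)
})

test_that("the reference vulnerability quadruple reproduces the 20-day differential and matches", {
  # crossing days 83 and 103 were frozen from an independent exhaustive
  # enumeration of the daily P/G curves for the reference classes
  out <- run_single(5, c(1.5, 0.55, 3.5, 0.55), default_scenario())
  expect_equal(out$crossing_large$crossing_day, 83L)
  expect_equal(out$crossing_small$crossing_day, 103L)
  expect_equal(out$gap_days, 20L)
  expect_true(out$matched)
})

test_that("every scatter point satisfies the matching criteria when re-checked", {
  res <- run_sweep(sweep_config(delta_g_grid = c(2.5, 3.5), runs_per_delta_g = 400L,
                                rng_seed = 11L))
  expect_gt(nrow(res$scatter), 0L)
  expect_true(all(res$scatter$ratio_stream >= 0))
  expect_true(all(res$scatter$ratio_lake >= 0))
  for (dg in unique(res$scatter$delta_g)) {
    block <- res$scatter[res$scatter$delta_g == dg, ]
    gaps <- block$day[block$size_class == "small"] -
      block$day[block$size_class == "large"]
    expect_true(all(gaps >= 10 & gaps <= 30))
    # at every recorded crossing the lake had become the favourable habitat
    expect_true(all(block$ratio_lake <= block$ratio_stream))
  }
})

test_that("matched runs are rarer at low growth differentials than near the peak", {
  cfg <- sweep_config(delta_g_grid = c(1, 3), runs_per_delta_g = 1000L,
                      rng_seed = 21L)
  res <- run_sweep(cfg)
  expect_lt(res$counts$matched[res$counts$delta_g == 1],
            res$counts$matched[res$counts$delta_g == 3])
})

test_that("a single-point grid is its own argmax and summaries are deterministic", {
  cfg <- sweep_config(delta_g_grid = 3, runs_per_delta_g = 200L, rng_seed = 9L)
  res <- run_sweep(cfg)
  s1 <- summarize_sweep(res); s2 <- summarize_sweep(res)
  expect_equal(s1$argmax_delta_g, 3)
  expect_identical(s1, s2)
})

test_that("the argmax growth differential is stable across seeds at large run counts", {
  grid <- seq(1, 10, by = 0.5)
  argmaxes <- vapply(1:10, function(s) {
    res <- run_sweep(sweep_config(delta_g_grid = grid,
                                  runs_per_delta_g = 32000L, rng_seed = s))
    summarize_sweep(res)$argmax_delta_g
  }, 1)
  expect_gte(max(table(argmaxes)), 8L)
})
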