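test_that("P/G ratio is zero without predators, infinite without growth, and symmetric for identical habitats", {
  sizes <- default_size_classes()
  sc <- symmetric_scenario(p_lake = 0)
  expect_equal(pg_ratio("lake", sizes$small, 100, sc), 0)
  # dead of winter in the default lake: temperature below the growth limit
  sc_cold <- symmetric_scenario(mean_temp = 2)
  expect_equal(pg_ratio("lake", sizes$small, 100, sc_cold), Inf)
  expect_equal(pg_ratio("stream", sizes$small, 100, sc_cold), Inf)
  sym <- symmetric_scenario()
  days <- 40:182
  expect_equal(pg_ratio("lake", 30, days, sym),
               pg_ratio("stream", 30, days, sym))
})

test_that("the migration condition fails in winter and holds under symmetry whenever growth is positive", {
  sc_cold <- symmetric_scenario(mean_temp = 1)  # max 3 C: below the growth limit all year
  expect_false(any(migration_condition(30, 1:365, sc_cold)))
  sym <- symmetric_scenario()
  days <- 1:365
  growing <- specific_growth(
    30, seasonal_temperature(days, sym$season_lake), sym$growth) > 0
  expect_equal(migration_condition(30, days, sym), growing)
})

test_that("crossing is immediate when the condition already holds at the window start", {
  sym <- symmetric_scenario()  # always in the growth window, equality holds
  cr <- crossing_day(size_class("x", mass = 30), sym)
  expect_equal(cr$crossing_day, 40L)
})

test_that("overwhelming lake predation with no growth advantage never favours migration", {
  sc <- symmetric_scenario(delta_g = 1, p_lake = 100, p_stream = 1)
  cr <- crossing_day(size_class("x", mass = 30), sc)
  expect_true(is.na(cr$crossing_day))
  expect_true(is.na(cr$reverse_crossing_day))
})

test_that("the crossing-day solver agrees exactly with the exhaustive daily-scan oracle on randomized scenarios", {
  sizes <- default_size_classes()
  for (seed in 1:50) {
    sc <- random_scenario(seed)
    for (s in sizes) {
      expect_identical(crossing_day(s, sc)$crossing_day,
                       oracle_crossing_day(s$mass, sc),
                       info = paste("seed", seed, s$label))
    }
  }
})

test_that("a reported reverse crossing is the first day the condition reverts", {
  found <- 0L
  for (seed in 1:40) {
    sc <- random_scenario(seed)
    cr <- crossing_day(default_size_classes()$small, sc)
    if (is.na(cr$crossing_day) || is.na(cr$reverse_crossing_day)) next
    found <- found + 1L
    expect_gt(cr$reverse_crossing_day, cr$crossing_day)
    expect_false(migration_condition(cr$size, cr$reverse_crossing_day, sc))
    expect_true(migration_condition(cr$size, cr$reverse_crossing_day - 1L, sc))
  }
  expect_gt(found, 5L)  # the check must actually have exercised cases
})

test_that("the default two-size scenario reports the ratio values at the crossing", {
  cr <- crossing_day(default_size_classes()$large, default_scenario())
  expect_false(is.na(cr$crossing_day))
  expect_lte(cr$ratio_lake_at_crossing, cr$ratio_stream_at_crossing)
  expect_gt(cr$ratio_lake_at_crossing, 0)
  # one day earlier the lake must still be unfavourable
  expect_false(migration_condition(cr$size, cr$crossing_day - 1L,
                                   default_scenario()))
})

test_that("the timing curve is deterministic and puts the largest fish first under size-selective lake predation", {
  sc <- default_scenario()
  sizes <- default_size_classes()
  twice <- timing_curve(list(sizes$small, sizes$small), sc)
  expect_equal(twice$crossing_day[1], twice$crossing_day[2])
  masses <- seq(sizes$small$mass, sizes$large$mass, length.out = 12)
  curve <- timing_curve(masses, sc)
  expect_false(anyNA(curve$crossing_day))
  expect_true(all(diff(curve$crossing_day) <= 0))
  expect_lt(curve$crossing_day[nrow(curve)], curve$crossing_day[1])
  expect_error(timing_curve(rev(masses), sc), "ascending")
})

test_that("without gape limitation every size crosses on the same day", {
  sizes <- default_size_classes()
  sr <- c(sizes$small$mass, sizes$large$mass)
  sc <- scenario_config(
    season_stream = season_params(5.5, 1.5, 215),
    season_lake = season_params(12, 8.5, 240),
    growth = growth_params(),
    predation_lake = predation_params(8, 2.5, 2.5, sr),
    predation_stream = predation_params(6, 0.55, 0.55, sr),
    delta_g = 5)
  curve <- timing_curve(seq(sr[1], sr[2], length.out = 8), sc)
  expect_equal(length(unique(curve$crossing_day)), 1L)
})

test_that("raising the lake growth differential never delays any size's migration", {
  sizes <- default_size_classes()
  for (mass in c(sizes$small$mass, 50, sizes$large$mass)) {
    days <- vapply(seq(0.5, 8, by = 0.5), function(dg)
      crossing_day(mass, default_scenario(delta_g = dg))$crossing_day, 1L)
    days_num <- ifelse(is.na(days), 366L, days)  # absent = later than any real day
    expect_true(all(diff(days_num) <= 0))
  }
})

test_that("the shipped YAML template parses to the documented default scenario", {
  path <- system.file("extdata", "scenario_default.yaml",
                      package = "migratiming")
  sc <- read_scenario(path)
  ref <- default_scenario(delta_g = 5)
  expect_equal(sc$season_stream, ref$season_stream)
  expect_equal(sc$season_lake, ref$season_lake)
  expect_equal(sc$growth, ref$growth)
  expect_equal(sc$delta_g, ref$delta_g)
  expect_equal(sc$day_window, ref$day_window)
  expect_equal(sc$predation_lake$p_max, ref$predation_lake$p_max)
  expect_equal(sc$predation_lake$size_range, ref$predation_lake$size_range,
               tolerance = 1e-9)
  # and it drives the solver to the same answer
  expect_identical(crossing_day(default_size_classes()$large, sc)$crossing_day,
                   crossing_day(default_size_classes()$large, ref)$crossing_day)
})
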