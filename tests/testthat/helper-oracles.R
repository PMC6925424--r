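# Independent oracles used across the suite.  These deliberately
# re-derive quantities from first principles (plain loops, closed forms,
# normal equations) rather than calling the package's own search or
# fitting code.

# Exhaustive daily-scan oracle for the crossing day: walk every day of
# the window, evaluate both P/G ratios from scratch, return the first
# day the migration condition holds (NA if none).
oracle_crossing_day <- function(mass, scenario) {
  temp_at <- function(day, season)
    season$mean_temp + season$amplitude *
      cos(2 * pi * (day - season$peak_day) / season$period)
  growth_at <- function(temp, gp) {
    f <- if (temp <= gp$temp_lower || temp >= gp$temp_upper) 0
    else if (temp <= gp$temp_opt)
      (temp - gp$temp_lower) / (gp$temp_opt - gp$temp_lower)
    else (gp$temp_upper - temp) / (gp$temp_upper - gp$temp_opt)
    gp$c_max * mass^(-gp$mass_exponent) * f
  }
  alpha_at <- function(pp) {
    lo <- pp$size_range[1]; hi <- pp$size_range[2]
    frac <- min(1, max(0, (mass - lo) / (hi - lo)))
    pp$alpha_small + frac * (pp$alpha_large - pp$alpha_small)
  }
  p_lake <- alpha_at(scenario$predation_lake) * scenario$predation_lake$p_max
  p_stream <- alpha_at(scenario$predation_stream) *
    scenario$predation_stream$p_max
  for (day in seq.int(scenario$day_window[1], scenario$day_window[2])) {
    g_lake <- scenario$delta_g *
      growth_at(temp_at(day, scenario$season_lake), scenario$growth)
    g_stream <- growth_at(temp_at(day, scenario$season_stream),
                          scenario$growth)
    if (g_lake <= 0) next
    ratio_lake <- p_lake / g_lake
    ratio_stream <- if (g_stream > 0) p_stream / g_stream else Inf
    if (ratio_lake <= ratio_stream) return(day)
  }
  NA_integer_
}

# Randomised but reproducible habitat-pair scenario for property tests.
random_scenario <- function(seed) {
  set.seed(seed)
  sizes <- default_size_classes()
  size_range <- c(sizes$small$mass, sizes$large$mass)
  a_lake_small <- runif(1, 1, 5)
  a_stream_small <- runif(1, 0.1, 2)
  scenario_config(
    season_stream = season_params(runif(1, 4, 10), runif(1, 1, 6),
                                  runif(1, 180, 230)),
    season_lake = season_params(runif(1, 8, 13), runif(1, 6, 10),
                                runif(1, 220, 260)),
    growth = growth_params(),
    predation_lake = predation_params(
      p_max = runif(1, 2, 12), alpha_small = a_lake_small,
      alpha_large = runif(1, 0.3, a_lake_small), size_range = size_range),
    predation_stream = predation_params(
      p_max = runif(1, 1, 8), alpha_small = a_stream_small,
      alpha_large = runif(1, 0.05, a_stream_small), size_range = size_range),
    delta_g = runif(1, 0.5, 8),
    day_window = c(40L, 182L)
  )
}

# Habitat pair with identical thermal regimes and constant vulnerability:
# the degenerate symmetric configuration used by several edge-case tests.
symmetric_scenario <- function(delta_g = 1, p_lake = 2, p_stream = 2,
                               mean_temp = 10) {
  season <- season_params(mean_temp, 2, 200)
  sizes <- default_size_classes()
  sr <- c(sizes$small$mass, sizes$large$mass)
  scenario_config(
    season_stream = season, season_lake = season,
    growth = growth_params(),
    predation_lake = predation_params(p_lake, 1, 1, sr),
    predation_stream = predation_params(p_stream, 1, 1, sr),
    delta_g = delta_g)
}

# Normal-equations least squares: solve X'X beta = X'y directly.
oracle_lm <- function(records) {
  records$stream_id <- factor(records$stream_id)
  records$year <- factor(records$year)
  X <- stats::model.matrix(~ total_length + stream_id + year, data = records)
  y <- records$migration_doy
  beta <- drop(solve(crossprod(X), crossprod(X, y)))
  resid <- y - drop(X %*% beta)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(beta = beta, r_squared = r2)
}

# Small deterministic record table for regression-oracle tests.
toy_records <- function(n = 30L, seed = 42L) {
  set.seed(seed)
  data.frame(
    fish_id = sprintf("T%03d", seq_len(n)),
    stream_id = sample(c("A", "B", "C"), n, replace = TRUE),
    year = sample(c(2015L, 2016L), n, replace = TRUE),
    total_length = round(runif(n, 105, 245), 1),
    migration_doy = as.integer(round(runif(n, 45, 175))),
    stringsAsFactors = FALSE)
}
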