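#' Predation-to-growth ratio for one habitat on given days
#'
#' The quantity whose habitat comparison defines the migration condition:
#' `P(M) / (delta_g * G(M, T_lake(day)))` for the lake and
#' `P(M) / G(M, T_stream(day))` for the stream.  Days on which the
#' habitat's growth is zero (temperature at or outside the thermal
#' limits) give a ratio of `+Inf`: a habitat without growth is never
#' favourable, however low its predation pressure.
#'
#' @param habitat `"lake"` or `"stream"`.
#' @param size A [size_class()] or body mass in g.
#' @param day Day(s) of year (vectorised).
#' @param scenario A [scenario_config()].
#' @return Dimensionless ratio(s); `+Inf` where growth is zero, `0` where
#'   predation is zero with positive growth.
#' @export
pg_ratio <- function(habitat = c("lake", "stream"), size, day, scenario) {
  habitat <- match.arg(habitat)
  stopifnot(inherits(scenario, "scenario_config"))
  mass <- as_mass(size)
  if (habitat == "lake") {
    temp <- seasonal_temperature(day, scenario$season_lake)
    g <- scenario$delta_g * specific_growth(mass, temp, scenario$growth)
    p <- predation_pressure(mass, scenario$predation_lake)
  } else {
    temp <- seasonal_temperature(day, scenario$season_stream)
    g <- specific_growth(mass, temp, scenario$growth)
    p <- predation_pressure(mass, scenario$predation_stream)
  }
  ifelse(g > 0, p / g, Inf)
}

#' Migration condition on given days
#'
#' `TRUE` on days when the lake's predation-to-growth ratio is less than
#' or equal to the stream's (non-strict, so equality triggers migration)
#' *and* lake growth is positive.  The growth guard keeps the dead of
#' winter — zero growth everywhere, both ratios infinite — from
#' spuriously satisfying the comparison: migrating into a habitat without
#' any growth potential is never optimal.
#'
#' @inheritParams pg_ratio
#' @return Logical vector, one element per `day`.
#' @export
migration_condition <- function(size, day, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  mass <- as_mass(size)
  lake_temp <- seasonal_temperature(day, scenario$season_lake)
  lake_growth <- scenario$delta_g *
    specific_growth(mass, lake_temp, scenario$growth)
  ratio_lake <- pg_ratio("lake", mass, day, scenario)
  ratio_stream <- pg_ratio("stream", mass, day, scenario)
  lake_growth > 0 & ratio_lake <= ratio_stream
}

#' Predicted migration day for one size class
#'
#' Scans the scenario's `day_window` on a daily grid and returns the
#' earliest day on which the migration condition holds — the crossing of
#' the lake and stream predation-to-growth curves, i.e. the model's
#' predicted migration date.  Also searched for (from the crossing to the
#' end of the year) is the first later day on which the condition reverts
#' to `FALSE`: the reverse crossing, the model's prediction of a
#' non-spawning return migration when the lake turns unfavourable again.
#'
#' @inheritParams pg_ratio
#' @return An object of class `"crossing_result"`: a list with `size`,
#'   `crossing_day` (integer day of year, or `NA` when the condition
#'   never holds in the window), `ratio_lake_at_crossing`,
#'   `ratio_stream_at_crossing`, and `reverse_crossing_day` (`NA` when
#'   the condition never reverts, or when there is no crossing).
#' @examples
#' crossing_day(default_size_classes()$large, default_scenario())
#' @export
crossing_day <- function(size, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  mass <- as_mass(size)
  window <- seq.int(scenario$day_window[1], scenario$day_window[2])
  cond <- migration_condition(mass, window, scenario)
  hit <- which(cond)
  if (length(hit) == 0L) {
    res <- list(size = size, crossing_day = NA_integer_,
                ratio_lake_at_crossing = NA_real_,
                ratio_stream_at_crossing = NA_real_,
                reverse_crossing_day = NA_integer_)
    return(structure(res, class = "crossing_result"))
  }
  cross <- window[hit[1]]
  # reverse crossing: first later day (to the end of the year) on which the
  # condition no longer holds while stream growth is still non-negative
  # (growth is never negative, so the guard is kept only for clarity).
  later <- seq.int(cross + 1L, scenario$season_stream$period)
  rev_day <- NA_integer_
  if (length(later)) {
    cond_later <- migration_condition(mass, later, scenario)
    stream_g <- specific_growth(
      mass, seasonal_temperature(later, scenario$season_stream),
      scenario$growth)
    off <- which(!cond_later & stream_g >= 0)
    if (length(off)) rev_day <- later[off[1]]
  }
  structure(
    list(size = size, crossing_day = cross,
         ratio_lake_at_crossing = pg_ratio("lake", mass, cross, scenario),
         ratio_stream_at_crossing = pg_ratio("stream", mass, cross, scenario),
         reverse_crossing_day = rev_day),
    class = "crossing_result"
  )
}

#' @export
print.crossing_result <- function(x, ...) {
  lab <- if (inherits(x$size, "size_class")) x$size$label else
    sprintf("%.1f g", as_mass(x$size))
  if (is.na(x$crossing_day)) {
    cat(sprintf("<crossing_result> %s: no crossing in window\n", lab))
  } else {
    cat(sprintf(
      "<crossing_result> %s: crossing day %d (P/G lake %.3f, stream %.3f)%s\n",
      lab, x$crossing_day, x$ratio_lake_at_crossing,
      x$ratio_stream_at_crossing,
      if (is.na(x$reverse_crossing_day)) "" else
        sprintf(", reverse crossing day %d", x$reverse_crossing_day)))
  }
  invisible(x)
}

#' Migration timing across a size spectrum
#'
#' Computes the crossing day for each size in an ascending series,
#' producing the model's size-versus-timing prediction: under
#' size-selective lake predation the crossing day is non-increasing in
#' mass — the largest fish migrate earliest and progressively smaller
#' fish follow as the season advances.
#'
#' @param sizes A list of [size_class()] objects (or a numeric vector of
#'   masses in g), sorted ascending in mass.
#' @param scenario A [scenario_config()].
#' @return A data frame with one row per size: `label`, `mass`,
#'   `total_length`, `crossing_day`, `ratio_lake_at_crossing`,
#'   `ratio_stream_at_crossing`, `reverse_crossing_day`.
#' @export
timing_curve <- function(sizes, scenario) {
  if (is.numeric(sizes)) sizes <- lapply(sizes, function(m) size_class(
    sprintf("%.1f g", m), mass = m))
  masses <- vapply(sizes, as_mass, 1)
  if (is.unsorted(masses))
    stop("`sizes` must be sorted ascending in mass", call. = FALSE)
  rows <- lapply(sizes, function(s) {
    cr <- crossing_day(s, scenario)
    data.frame(
      label = if (inherits(s, "size_class")) s$label else NA_character_,
      mass = as_mass(s),
      total_length = if (inherits(s, "size_class")) s$total_length else NA_real_,
      crossing_day = cr$crossing_day,
      ratio_lake_at_crossing = cr$ratio_lake_at_crossing,
      ratio_stream_at_crossing = cr$ratio_stream_at_crossing,
      reverse_crossing_day = cr$reverse_crossing_day,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
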