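#' Seasonal water-temperature parameters
#'
#' Describes a sinusoidal annual water-temperature cycle for one habitat.
#' Temperature is `mean_temp + amplitude * cos(2*pi*(day - peak_day)/period)`,
#' so it peaks at `peak_day` and bottoms out half a period later.
#'
#' @param mean_temp Annual mean water temperature (degrees C).
#' @param amplitude Seasonal half-range (degrees C, >= 0).
#' @param peak_day Day of year of the warmest water (1..period).
#' @param period Length of the cycle in days (default 365; leap years are
#'   ignored throughout the package).
#'
#' @return An object of class `"season_params"`.
#' @seealso [seasonal_temperature()]
#' @export
season_params <- function(mean_temp, amplitude, peak_day, period = 365) {
  stopifnot(is.numeric(mean_temp), length(mean_temp) == 1L)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(peak_day) || length(peak_day) != 1L ||
      peak_day < 1 || peak_day > period)
    stop("`peak_day` must lie in [1, period]", call. = FALSE)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive number", call. = FALSE)
  structure(
    list(mean_temp = mean_temp, amplitude = amplitude,
         peak_day = peak_day, period = period),
    class = "season_params"
  )
}

#' Water temperature on a given day of year
#'
#' Evaluates the sinusoidal seasonal temperature curve.  Days outside
#' `[1, period]` wrap around modulo the period, so the curve is periodic
#' and continuous across year boundaries.
#'
#' @param day Day of year (numeric vector; wrapped modulo the period).
#' @param season A [season_params()] object.
#' @return Water temperature(s) in degrees C.
#' @examples
#' s <- season_params(mean_temp = 10, amplitude = 8, peak_day = 200)
#' seasonal_temperature(200, s)  # warmest day: 18
#' @export
seasonal_temperature <- function(day, season) {
  stopifnot(inherits(season, "season_params"))
  season$mean_temp + season$amplitude *
    cos(2 * pi * (day - season$peak_day) / season$period)
}

#' Temperature- and mass-dependent growth parameters
#'
#' Parameters of the piecewise-linear (Elliott-type) specific-growth model
#' for brown trout: growth rises linearly from zero at `temp_lower` to its
#' maximum at `temp_opt`, falls linearly back to zero at `temp_upper`, and
#' scales with body mass as `mass^(-mass_exponent)` so that smaller fish
#' grow proportionally faster.  The defaults are literature values for
#' brown trout.
#'
#' @param c_max Maximum specific growth in % body mass per day for a fish
#'   of reference mass 1 g at the optimum temperature (default 2.8).
#' @param mass_exponent Allometric exponent of the mass scaling (> 0,
#'   default 0.31).
#' @param temp_lower Lower temperature limit for growth (degrees C,
#'   default 3.6).
#' @param temp_opt Optimum temperature (degrees C, default 13.1).
#' @param temp_upper Upper temperature limit for growth (degrees C,
#'   default 19.5).
#'
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(c_max = 2.8, mass_exponent = 0.31,
                          temp_lower = 3.6, temp_opt = 13.1,
                          temp_upper = 19.5) {
  if (!is.numeric(c_max) || length(c_max) != 1L || c_max <= 0)
    stop("`c_max` must be a single positive number", call. = FALSE)
  if (!is.numeric(mass_exponent) || length(mass_exponent) != 1L ||
      mass_exponent <= 0)
    stop("`mass_exponent` must be a single positive number", call. = FALSE)
  if (!(temp_lower < temp_opt && temp_opt < temp_upper))
    stop("growth temperature limits must satisfy temp_lower < temp_opt < temp_upper",
         call. = FALSE)
  structure(
    list(c_max = c_max, mass_exponent = mass_exponent,
         temp_lower = temp_lower, temp_opt = temp_opt,
         temp_upper = temp_upper),
    class = "growth_params"
  )
}

#' Convert total length to body mass
#'
#' Allometric length-mass conversion `mass = a * length^b`.  The defaults
#' (`a = 1e-5` g/mm^3, `b = 3`) correspond to isometric growth at a
#' Fulton condition factor of 1, a standard assumption for juvenile
#' salmonids; 160.7 mm maps to about 41.5 g.
#'
#' @param total_length Total length in mm (vector, all > 0).
#' @param a Condition-factor-like coefficient (g per mm^b).
#' @param b Allometric exponent.
#' @return Body mass in g.
#' @export
length_to_mass <- function(total_length, a = 1e-5, b = 3) {
  if (!is.numeric(total_length) || any(!is.finite(total_length)) ||
      any(total_length <= 0))
    stop("`total_length` must be positive and finite", call. = FALSE)
  a * total_length^b
}

#' Define a fish size class
#'
#' A size class is the unit the migration model reasons about: a body mass
#' (g), optionally derived from a total length (mm) via
#' [length_to_mass()], plus a free-text label.
#'
#' @param label Label for the class (e.g. `"small"`, `"large"`).
#' @param mass Body mass in g (> 0).  May be omitted when `total_length`
#'   is given.
#' @param total_length Total length in mm; when supplied together with
#'   `mass` the two must be consistent under [length_to_mass()].
#' @param ... Passed on to [length_to_mass()] (`a`, `b`).
#' @return An object of class `"size_class"` with fields `label`, `mass`
#'   and (possibly `NA`) `total_length`.
#' @export
size_class <- function(label, mass = NULL, total_length = NULL, ...) {
  if (is.null(mass) && is.null(total_length))
    stop("supply `mass` or `total_length`", call. = FALSE)
  if (is.null(mass)) mass <- length_to_mass(total_length, ...)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("`mass` must be a single positive number", call. = FALSE)
  if (!is.null(total_length) &&
      abs(mass - length_to_mass(total_length, ...)) > 1e-8 * mass)
    stop("`mass` is inconsistent with `total_length` under the allometric conversion",
         call. = FALSE)
  structure(
    list(label = as.character(label), mass = mass,
         total_length = if (is.null(total_length)) NA_real_ else total_length),
    class = "size_class"
  )
}

# Accept either a size_class or a bare mass in numeric form.
as_mass <- function(size) {
  if (inherits(size, "size_class")) return(size$mass)
  if (is.numeric(size) && all(size > 0)) return(size)
  stop("`size` must be a `size_class` or a positive mass in g", call. = FALSE)
}

# Temperature response on [0, 1]: piecewise linear, 1 at temp_opt,
# 0 at and beyond both limits.
temperature_response <- function(temperature, params) {
  lo <- params$temp_lower; op <- params$temp_opt; hi <- params$temp_upper
  out <- ifelse(
    temperature <= lo | temperature >= hi, 0,
    ifelse(temperature <= op,
           (temperature - lo) / (op - lo),
           (hi - temperature) / (hi - op))
  )
  out
}

#' Specific growth rate
#'
#' Piecewise-linear (Elliott-type) specific growth:
#' `G(M, T) = c_max * M^(-mass_exponent) * f(T)` where `f` rises linearly
#' from 0 at `temp_lower` to 1 at `temp_opt` and falls back to 0 at
#' `temp_upper`.  Growth is zero at and outside the thermal limits and
#' strictly decreasing in mass inside them.
#'
#' @param size A [size_class()] or a positive body mass in g.
#' @param temperature Water temperature in degrees C (vectorised).
#' @param params A [growth_params()] object.
#' @return Specific growth in % body mass per day (same length as
#'   `temperature`).
#' @examples
#' specific_growth(1, 13.1, growth_params())   # c_max = 2.8
#' specific_growth(50, 3.6, growth_params())   # 0 at the lower limit
#' @export
specific_growth <- function(size, temperature, params = growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  mass <- as_mass(size)
  params$c_max * mass^(-params$mass_exponent) *
    temperature_response(temperature, params)
}
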