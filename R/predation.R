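#' Size-specific predation parameters for one habitat
#'
#' Predation pressure on a fish of mass `M` is partitioned into the
#' fraction of the predator community capable of consuming it
#' (`alpha(M)`, shrinking with prey size because piscivores are gape
#' limited) and the habitat's predator carrying capacity `p_max`:
#' `P(M) = alpha(M) * p_max`.  `alpha` is interpolated linearly in mass
#' between `alpha_small` at `size_range[1]` and `alpha_large` at
#' `size_range[2]`, and clamped at the endpoints outside that range.
#'
#' `alpha` is treated as a dimensionless vulnerability multiplier rather
#' than a literal percentage: only products `alpha * p_max` and ratios
#' between habitats enter the migration condition, so absolute
#' normalisation is irrelevant.
#'
#' @param p_max Predator carrying capacity (dimensionless pressure scale,
#'   >= 0).
#' @param alpha_small Vulnerability of the smallest modeled size (> 0).
#' @param alpha_large Vulnerability of the largest modeled size
#'   (0 <= alpha_large <= alpha_small; gape limitation).
#' @param size_range Masses (g) `c(mass_min, mass_max)` between which
#'   `alpha` is interpolated.
#' @return An object of class `"predation_params"`.
#' @export
predation_params <- function(p_max, alpha_small, alpha_large,
                             size_range) {
  if (!is.numeric(p_max) || length(p_max) != 1L || p_max < 0)
    stop("`p_max` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(alpha_small) || length(alpha_small) != 1L || alpha_small <= 0)
    stop("`alpha_small` must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha_large) || length(alpha_large) != 1L ||
      alpha_large < 0 || alpha_large > alpha_small)
    stop("`alpha_large` must satisfy 0 <= alpha_large <= alpha_small",
         call. = FALSE)
  if (!is.numeric(size_range) || length(size_range) != 2L ||
      !(size_range[1] < size_range[2]) || any(size_range <= 0))
    stop("`size_range` must be positive masses c(mass_min, mass_max) with mass_min < mass_max",
         call. = FALSE)
  structure(
    list(p_max = p_max, alpha_small = alpha_small,
         alpha_large = alpha_large, size_range = as.numeric(size_range)),
    class = "predation_params"
  )
}

#' Fraction of predators capable of consuming a fish of a given size
#'
#' Monotone non-increasing linear interpolation of the vulnerability
#' multiplier `alpha` over body mass, clamped at the configured endpoints.
#'
#' @param size A [size_class()] or body mass in g (vectorised).
#' @param params A [predation_params()] object.
#' @return Dimensionless `alpha` value(s).
#' @export
alpha_of_size <- function(size, params) {
  stopifnot(inherits(params, "predation_params"))
  mass <- as_mass(size)
  lo <- params$size_range[1]; hi <- params$size_range[2]
  frac <- pmin(1, pmax(0, (mass - lo) / (hi - lo)))
  params$alpha_small + frac * (params$alpha_large - params$alpha_small)
}

#' Size-specific predation pressure
#'
#' `P(M) = alpha(M) * p_max`.  Pressure is constant over the season; all
#' seasonality in the migration model enters through growth.
#'
#' @inheritParams alpha_of_size
#' @return Dimensionless predation pressure (>= 0, non-increasing in
#'   mass).
#' @export
predation_pressure <- function(size, params) {
  alpha_of_size(size, params) * params$p_max
}
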