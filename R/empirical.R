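#' Validate a table of migration records
#'
#' A migration-record table has one row per outmigrating fish with
#' columns `fish_id`, `stream_id`, `year`, `total_length` (mm) and
#' `migration_doy` (integer day of year).
#'
#' @param records A data frame of migration records.
#' @param min_length Smallest plausible tagging length in mm (default
#'   104, the study protocol's minimum).
#' @return The validated data frame (invisibly usable), with `stream_id`
#'   and `year` coerced to factors.
#' @export
validate_records <- function(records, min_length = 104) {
  need <- c("fish_id", "stream_id", "year", "total_length", "migration_doy")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(records[need]))
    stop("records contain missing values", call. = FALSE)
  if (any(records$total_length < min_length))
    stop("total_length below the plausible tagging minimum (", min_length,
         " mm)", call. = FALSE)
  if (any(records$migration_doy < 1 | records$migration_doy > 365))
    stop("migration_doy must lie in 1..365", call. = FALSE)
  records$stream_id <- factor(records$stream_id)
  records$year <- factor(records$year)
  records
}

#' Linear model of migration date on body size
#'
#' Ordinary least squares of migration day of year on total length with
#' stream identity and migration year as categorical fixed effects
#' (treatment coding, `lm(migration_doy ~ total_length + stream_id +
#' year)`).  Also computes, per stream, the Pearson correlation between
#' length and migration day — the signed per-population counterpart of
#' the overall size effect.
#'
#' @param records A migration-record data frame (see
#'   [validate_records()]).
#' @return An object of class `"timing_model"`: list with `size_slope`
#'   (days per mm), `size_slope_se`, `p_value_size`, `r_squared`,
#'   `intercepts` (all fitted coefficients), `per_stream_r`, `n` and the
#'   underlying `fit`.
#' @export
fit_timing_model <- function(records) {
  records <- validate_records(records)
  if (nlevels(records$stream_id) < 2L)
    stop("need records from at least 2 streams", call. = FALSE)
  if (length(unique(records$total_length)) < 2L)
    stop("need at least 2 distinct total lengths", call. = FALSE)
  fit <- stats::lm(migration_doy ~ total_length + stream_id + year,
                   data = records)
  coefs <- stats::coef(fit)
  if (anyNA(coefs))
    stop("rank-deficient design: coefficients ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "),
         " are not estimable (e.g. a stream observed in a single year ",
         "or a stream x year cell with constant size)", call. = FALSE)
  summ <- summary(fit)
  per_stream_r <- vapply(
    split(records, records$stream_id),
    function(d) {
      if (nrow(d) < 3L || stats::sd(d$total_length) == 0 ||
          stats::sd(d$migration_doy) == 0) return(NA_real_)
      stats::cor(d$total_length, d$migration_doy)
    }, 1)
  structure(
    list(size_slope = unname(coefs["total_length"]),
         size_slope_se = summ$coefficients["total_length", "Std. Error"],
         p_value_size = summ$coefficients["total_length", "Pr(>|t|)"],
         r_squared = summ$r.squared,
         intercepts = coefs,
         per_stream_r = per_stream_r,
         n = nrow(records),
         fit = fit),
    class = "timing_model"
  )
}

#' @export
print.timing_model <- function(x, ...) {
  cat("<timing_model> migration_doy ~ total_length + stream_id + year\n")
  cat(sprintf("  n = %d, r^2 = %.3f\n", x$n, x$r_squared))
  cat(sprintf("  size effect: %.3f d/mm (SE %.3f, p = %.2g)\n",
              x$size_slope, x$size_slope_se, x$p_value_size))
  r <- x$per_stream_r[!is.na(x$per_stream_r)]
  if (length(r))
    cat(sprintf("  per-stream r(size, day): mean %.2f +/- %.2f (n = %d streams)\n",
                mean(r), stats::sd(r), length(r)))
  invisible(x)
}

#' Timing summaries of a migration-record table
#'
#' Computes the median and range of migration day, the percentage of
#' migrants inside a day-of-year window (default days 91-151, i.e.
#' April-May on a non-leap calendar), and the percentile gap: the
#' difference between the mean migration day of the smallest and the
#' largest `extreme_pct` of fish ranked by total length (group size
#' `ceiling(extreme_pct * n)`, ties in length broken by input order).
#' A positive gap means the smallest fish migrate later.
#'
#' @param records A migration-record data frame.
#' @param extreme_pct Fraction defining the extreme groups (0 <
#'   `extreme_pct` < 0.5, default 0.05).
#' @param window Day-of-year window `c(lo, hi)` for `pct_in_window`
#'   (default `c(91, 151)`).
#' @return An object of class `"timing_summary"`: list with
#'   `median_doy`, `doy_range`, `pct_in_window`, `gap_days` (`NA` when
#'   the two extreme groups would overlap) and `group_stats` (a data
#'   frame with mean/SD of day and mean length for each extreme group).
#' @export
summarize_timing <- function(records, extreme_pct = 0.05,
                             window = c(91, 151)) {
  records <- validate_records(records)
  if (!is.numeric(extreme_pct) || length(extreme_pct) != 1L ||
      extreme_pct <= 0 || extreme_pct >= 0.5)
    stop("`extreme_pct` must lie in (0, 0.5)", call. = FALSE)
  n <- nrow(records)
  if (n == 0L) stop("no records", call. = FALSE)
  k <- ceiling(extreme_pct * n)
  ord <- order(records$total_length)     # stable: ties keep input order
  gap <- NA_real_
  group_stats <- NULL
  if (2L * k <= n) {
    smallest <- records[ord[seq_len(k)], ]
    largest <- records[ord[seq.int(n - k + 1L, n)], ]
    gap <- mean(smallest$migration_doy) - mean(largest$migration_doy)
    group_stats <- data.frame(
      group = c("smallest", "largest"),
      n = k,
      mean_doy = c(mean(smallest$migration_doy), mean(largest$migration_doy)),
      sd_doy = c(stats::sd(smallest$migration_doy),
                 stats::sd(largest$migration_doy)),
      mean_length = c(mean(smallest$total_length),
                      mean(largest$total_length)),
      stringsAsFactors = FALSE)
  }
  structure(
    list(median_doy = stats::median(records$migration_doy),
         doy_range = range(records$migration_doy),
         pct_in_window = 100 * mean(records$migration_doy >= window[1] &
                                      records$migration_doy <= window[2]),
         gap_days = gap,
         group_stats = group_stats,
         extreme_pct = extreme_pct,
         window = window,
         n = n),
    class = "timing_summary"
  )
}

#' @export
print.timing_summary <- function(x, ...) {
  cat("<timing_summary>\n")
  cat(sprintf("  n = %d; median doy %g, range %g-%g\n",
              x$n, x$median_doy, x$doy_range[1], x$doy_range[2]))
  cat(sprintf("  %.1f%% of migrants within days %g-%g\n",
              x$pct_in_window, x$window[1], x$window[2]))
  if (!is.na(x$gap_days))
    cat(sprintf("  smallest %g%% migrate %.1f days %s than largest %g%%\n",
                100 * x$extreme_pct, abs(x$gap_days),
                if (x$gap_days >= 0) "later" else "earlier",
                100 * x$extreme_pct))
  invisible(x)
}
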