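#!/usr/bin/env Rscript

# Reference two-size simulation: daily P/G ratio curves per habitat and the
# size-versus-timing curve under the documented default scenario (five-fold
# lake growth differential, size-selective lake predation).
#
# Writes: results/ratio_curves.csv, results/timing_curve.csv

suppressPackageStartupMessages(library(migratiming))
dir.create("results", showWarnings = FALSE)

scenario <- default_scenario(delta_g = 5)
sizes <- default_size_classes()
days <- seq.int(scenario$day_window[1], scenario$day_window[2])

ratios <- do.call(rbind, lapply(sizes, function(s) {
  do.call(rbind, lapply(c("lake", "stream"), function(hab)
    data.frame(size_class = s$label, habitat = hab, day = days,
               pg_ratio = pg_ratio(hab, s, days, scenario))))
}))
write.csv(ratios, "results/ratio_curves.csv", row.names = FALSE)

for (s in sizes) print(crossing_day(s, scenario))
gap <- crossing_day(sizes$small, scenario)$crossing_day -
  crossing_day(sizes$large, scenario)$crossing_day
message(sprintf(
  "the large class migrates %d days before the small class (empirical band: 20 +/- 10)",
  gap))

lengths <- seq(sizes$small$total_length, sizes$large$total_length,
               length.out = 25)
curve <- timing_curve(lapply(lengths, function(L)
  size_class(sprintf("%.0f mm", L), total_length = L)), scenario)
write.csv(curve, "results/timing_curve.csv", row.names = FALSE)
message(sprintf(
  "timing curve: crossing days run from %d (largest) to %d (smallest); reverse crossings appear from day %d",
  min(curve$crossing_day), max(curve$crossing_day),
  min(curve$reverse_crossing_day, na.rm = TRUE)))
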