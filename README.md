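# migratiming

Why do the largest juvenile trout leave their natal stream for the lake
weeks before the smallest ones?  `migratiming` implements a
size-structured growth–predation tradeoff model of adfluvial migration
timing, together with the simulation experiments and record-level
statistics used to confront it with PIT-tag style outmigration data.
It is written for movement ecologists and population modellers who want
to explore, refit or extend the tradeoff mechanism.

## The model

A fish of mass $M$ should migrate from stream $S$ to lake $L$ on the
first day $t$ that

$$\frac{P_L(M)}{\Delta G \, G_L(M, T_L(t))} \le \frac{P_S(M)}{G_S(M, T_S(t))}$$

where

* $P_H(M) = \alpha_H(M) \, P_{H,max}$ — predation pressure: the fraction
  of predators able to consume a fish of mass $M$ (gape-limited, so
  $\alpha$ declines with size) times the habitat's predator carrying
  capacity;
* $G_H(M, T) = c_{max} M^{-b} f(T)$ — specific growth, a
  piecewise-linear thermal response (zero at 3.6 °C, maximal at 13.1 °C,
  zero again at 19.5 °C, brown-trout defaults) scaled so smaller fish
  grow faster;
* $\Delta G$ — how much more productive the lake is than the stream at
  equal temperature;
* $T_S(t), T_L(t)$ — sinusoidal seasonal temperature regimes: a cold
  damped stream against a warm, high-amplitude, lagged lake.

As the lake warms through spring, the day the inequality first holds —
the *crossing day* — arrives earlier for larger fish, whose low
vulnerability makes the risky, productive lake pay off sooner: the model
predicts size-ordered differential migration, and later in the year a
*reverse crossing* when the lake turns unfavourable again (a
non-spawning return migration).

## Worked example

```r
library(migratiming)

sizes <- default_size_classes()       # 112.3 mm and 216.4 mm reference fish
sc <- default_scenario(delta_g = 5)   # documented defaults, 5x lake growth
crossing_day(sizes$large, sc)
#> <crossing_result> large: crossing day 83 (P/G lake 48.289, stream 50.288), reverse crossing day 194
crossing_day(sizes$small, sc)
#> <crossing_result> small: crossing day 103 (P/G lake 18.182, stream 18.512), reverse crossing day 177
```

The large reference fish is predicted to migrate on day 83 (late March)
and the small one on day 103 — a 20-day differential, inside the
empirical 20 ± 10 day band.  The printed P/G values are the
predation-to-growth ratios of each habitat on the crossing day (the lake
value has just dipped below the stream value); the reverse-crossing days
in mid-summer are when the lake overshoots the thermal optimum and the
model predicts a return to the stream.

The Monte-Carlo sweep asks how often random predator-vulnerability
draws reproduce that differential, as a function of $\Delta G$:

```r
res <- run_sweep(sweep_config(rng_seed = 20260101))
summarize_sweep(res)
#> <sweep_summary>
#>   matched band: [10, 30] days (large before small)
#>   matched fraction: 0.052
#>   matched runs peak at delta_g = 3 (107 runs)
```

Matched runs are rare when the lake is barely better than the stream,
peak at a growth differential near 3, and decay again as the lake
becomes so profitable that small fish migrate as early as large ones.

The data side works on one-row-per-fish migration records
(`fish_id, stream_id, year, total_length, migration_doy`); a seeded
generator emulates that structure for testing:

```r
recs <- generate_records(default_paperlike_config(rng_seed = 11))
fit_timing_model(recs)
#> <timing_model> migration_doy ~ total_length + stream_id + year
#>   n = 828, r^2 = 0.198
#>   size effect: -0.284 d/mm (SE 0.023, p = 2.1e-31)
#>   per-stream r(size, day): mean -0.39 +/- 0.10 (n = 12 streams)
summarize_timing(recs)
#> <timing_summary>
#>   n = 828; median doy 113, range 40-182
#>   70.2% of migrants within days 91-151
#>   smallest 5% migrate 29.6 days later than largest 5%
```

Larger fish migrate earlier (negative slope, negative per-stream
correlations), and the smallest 5% of fish trail the largest 5% by about
a month.

## Analysis workflow

The `analysis/` scripts run the full study pipeline and write their
tables under `results/`:

| script | what it does | writes |
|---|---|---|
| `01_reference_scenario.R` | daily P/G curves and the size-vs-timing curve for the default scenario | `ratio_curves.csv`, `timing_curve.csv` |
| `02_sweep.R` | the Monte-Carlo sweep: matched counts per ΔG and the crossing-point scatter | `sweep_counts.csv`, `sweep_scatter.csv` |
| `03_generate_data.R` | a synthetic 828-record migration table plus config sidecar | `synthetic_records.csv`, `synthetic_records_config.json` |
| `04_empirical_analysis.R` | timing regression and summaries of a record table | `timing_model.json` |

Run them in order with `Rscript analysis/01_reference_scenario.R` etc.;
`04` accepts an alternative record CSV as its first argument.

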