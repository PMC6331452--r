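# cytofp — cytometric fingerprinting of microbial community dynamics

`cytofp` analyzes microbial community **flow-cytometry fingerprints**: 2D
single-cell dot plots of DNA-stain fluorescence (DAPI, DNA content) against
forward scatter (FSC, cell-size related), measured repeatedly for replicated
communities under different treatments. It is aimed at microbial ecologists
who monitor community structure at high temporal resolution — e.g. wastewater
communities under toxicant exposure — where amplicon sequencing is too slow
or expensive for every sampling point.

The analysis model is gate-based. A **gate template** — a fixed, ordered set
of convex polygon gates in the log-scaled (FSC × DNA) plane, each gate
standing for a subcommunity of cells with similar optical properties — is
applied identically to every sample. Events are assigned to the first gate
containing them, giving a (treatment, replicate, day) × gate table of
relative cell abundances in percent. All downstream ecology works on that
table:

- **α-diversity** as the gate-based Hill number of order zero,
  D₀ = #{g : pₘ > τ}, the number of *dominant* gates whose relative
  abundance pₘ strictly exceeds a threshold τ (conventions: τ = 2.9 %, and
  τ = 0.71 % to match a sequencing OTU threshold);
- **intra-community β-diversity** between sampling days as the number of
  gates unique to either day's dominant set (symmetric-difference
  cardinality), by default between consecutive days within a replicate;
- **community trajectories** via Bray–Curtis dissimilarity
  d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ) and non-metric multidimensional scaling
  (Kruskal stress-1, monotone regression, random restarts);
- **per-gate responses**: OLS trend slopes *k* (percent/day, window 4–24 d,
  the day-0 inoculum excluded), Spearman's ρ of abundance against exposure
  time with strong responses at |ρ| ≥ 0.4, and marker-gate selection
  (strong positive ρ with k > 0, or strong negative ρ with k < 0 and
  non-negligible initial abundance) for downstream cell sorting.

Because real raw data are rarely at hand, the package ships a first-class
**synthetic-data generator**: Gaussian subcommunity clusters on a 4-decade
log scale, a shared inoculum with an adaptation shift at the first transfer,
treatment-dependent linear abundance trajectories, per-replicate Dirichlet
composition noise, and multinomial event sampling — so every pipeline stage
can be verified against known ground truth.

## Worked example

```r
library(cytofp)

cfg <- pipeline_config(
  output_dir    = "demo_results",
  simulate      = list(events_per_sample = 20000),
  template_path = system.file("extdata", "default_template.tsv",
                              package = "cytofp"),
  seed          = 1)
bundle <- run_pipeline(cfg)
summarize_results(bundle)
```

prints (abridged):

```
cytofp results: 120 samples, 10 gates, NMDS stress 0.055
alpha diversity (threshold 2.9%):
  EC50Ag30   d0:8.3+/-0.6 d4:5.7+/-0.6 d7:6.3+/-0.6 ... d24:7.0+/-0.0
  Neg        d0:8.0+/-0.0 d4:5.7+/-0.6 d7:5.7+/-0.6 ... d24:5.3+/-0.6
beta diversity (threshold 2.9%):
  EC50Ag30   d4:3.3 d7:0.7 d10:0.3 d14:0.3 d17:0.0 d21:0.0 d24:0.0
marker gates:
  Neg        positive: G8 | negative:
  EC50Ag30   positive: G4,G11 | negative: G3,G6,G8,G9,G10
```

Reading this: 120 samples are 5 treatments × 3 replicates × 8 sampling days.
α stays in a narrow band (5–8 dominant gates of 10), β peaks at the first
post-inoculum interval (the adaptation to batch cultivation, 3.3 unique
gates day 0→4) and then settles near zero, and under the EC50 nanoparticle
treatment the pipeline flags G4 and G11 as positive markers (rising with
exposure) and G3/G6 among the negative ones — the synthetic community's
built-in disturbance response. Per-gate statistics are available directly:

```r
gate_trend(bundle$table, "EC50Ag30", "G4")$k          # 1.685 %/day
fold_change(bundle$table, "G4", "EC50Ag30", "Neg", 24)$fold   # 14.5
```

All artifacts (abundance table, diversity series at both thresholds,
Bray–Curtis matrix, NMDS coordinates with stress, response report, marker
list, run manifest) are written as TSV/JSON under `output_dir`.

## Command line

```sh
Rscript inst/cli/cytofp.R run --config config.json --out results
Rscript inst/cli/cytofp.R summarize --results results
```

Subcommands: `simulate`, `gate`, `metrics`, `respond`, `run`, `summarize`.
Logs go to stderr; results only to files.

## Documentation

The methods vignette (`vignettes/cytometric-fingerprinting.Rmd`) documents
the generative model, every tunable parameter with units and defaults, the
numerical conventions (strict thresholds, first-match gating, stress-1
NMDS), and known limitations — including what a green synthetic-data test
does and does not establish about real cytometry data.
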