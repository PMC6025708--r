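# micop

**MIC-based oscillation prediction for time-series omics data.**

`micop` detects rhythmically oscillating molecules — proteins, metabolites,
transcripts — in short, noisy time-course matrices, including the hard
cases where the oscillation's amplitude *decays* between cycles or only a
single cycle was measured.  It is aimed at circadian studies that sample a
proteome or metabolome every 2–6 hours over one or two days, a regime where
curve-fitting and spectral rhythm detectors lose power.

## Method in brief

Each molecule's series is scored against one fixed reference sine curve by
the **maximal information coefficient**,

```
MIC(X, Y) = max_{grids: cx·cy < n^α}  I(X;Y) / log₂ min(cx, cy),
I(X;Y)    = Σ p(x,y) log₂ [ p(x,y) / (p(x)p(y)) ],
```

the maximum over 2-D grid partitions (bin product bounded by `n^0.6`) of
normalized mutual information between the reference values `X` and the
measurements `Y`.  MIC captures *any* functional association, so a
decaying oscillation — a non-linear but clean relation to the sine — keeps
a high score.  Significance is Monte-Carlo: the observed MIC is compared
with the MICs of 1000 non-oscillating random series against the same
reference (`p = k/1000`, strict exceedances), and calls are made on
Benjamini–Hochberg adjusted p-values at 0.05.  Missing points are
pairwise-deleted; the null is cached per missing-data pattern.

A seeded simulator generates the benchmark conditions (two cycles or one,
sampling every 1–8 h, Gaussian noise SD 0–0.6, optional second-cycle peak
attenuated to one third), and a benchmark harness sweeps conditions and
summarises classification quality by the Matthews correlation coefficient
(MCC).

## Worked example

Score a small simulated matrix — three decaying oscillating proteins and
two random ones, two 24-h cycles sampled every 4 h with noise SD 0.4:

```r
library(micop)

spec <- sim_spec(n_cycles = 2, interval = 4, noise_sd = 0.4, decaying = TRUE,
                 n_oscillating = 3, n_nonoscillating = 2, seed = 1)
ds  <- make_dataset(spec)
res <- micop_call(ds$x, ds$times, seed = 42)
print(res, digits = 3)
#>        id n_used   mic     p      q called
#> 1 osc_001     12 0.655 0.001 0.0025   TRUE
#> 2 osc_002     12 0.655 0.001 0.0025   TRUE
#> 3 osc_003     12 0.459 0.045 0.0750  FALSE
#> 4 ran_001     12 0.311 0.356 0.4450  FALSE
#> 5 ran_002     12 0.191 0.646 0.6460  FALSE
```

`mic` is the association with the reference sine on the 12 usable points,
`p` the fraction of 1000 random series scoring strictly higher, `q` its BH
adjustment, and `called` the oscillation call (`q < 0.05`): the two
clearly decaying rows are recovered, the third is borderline at this noise
level, and the random rows are far from significance.

A full benchmark cell — 100 decaying + 100 random series at the same
condition — reproduces the method's headline operating point:

```r
run_cell(sim_spec(interval = 4, noise_sd = 0.4, decaying = TRUE, seed = 1))
#> benchmark cell (interval 4 h, noise 0.4, decaying, seed 1): MCC = 0.696  [tp 70 fp 3 tn 97 fn 30]
```

Real matrices go through the same call: `m <- read_matrix("proteome.tsv")`
(TSV/CSV, first column molecule id, header of sampling times in hours,
`NA` for missing) then `micop_call(m$x, m$times)` and
`write_results(...)`.

## Command line

```sh
inst/cli/micop simulate  --interval 4 --noise 0.4 --decaying --n-pos 100 --n-neg 100 \
                         --seed 1 --out sim.tsv --labels labels.tsv
inst/cli/micop score     --input sim.tsv --n-draws 1000 --seed 1 --out results.tsv
inst/cli/micop benchmark --intervals 1,2,3,4 --noises 0.4 --decaying --out cells.tsv
```

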