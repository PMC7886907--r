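# loopcomp

Chromatin loops anchored by CTCF shape enhancer–promoter communication,
yet only a few percent of the CTCF site pairs lying within 1 Mb of each
other actually interact in ChIA-PET or Micro-C data. `loopcomp`
implements a quantitative loop-competition-and-extrusion (LCE) model of
why: Cohesin extrudes a loop until it is blocked at bound CTCF sites,
so the probability of a loop between sites *i* < *j* decomposes into
four interpretable ingredients,

```
p_ij = w_ij · p_i · p_j · D_ij · LC_ij
```

* **Binding occupancy** `p_i = x_i / (x_i + a)` — the chemical-equilibrium
  probability that site *i* is CTCF-bound, driven by the normalized
  ChIP-seq intensity `x_i` (signal over its genome average) and a single
  dimensionless scale `a = ⟨K_d⟩ / [CTCF]` (default 8.5). A `tanh(a·x)`
  parameterization is available as a variant.
* **Motif orientation** `w_ij ∈ {1, 1/w, 1/w²}` for convergent, tandem
  and divergent motif pairs (default `w = 3`: a convergent pair is three
  times as likely to loop as a tandem pair, nine times as a divergent
  one). A general `(w₁, w₂)` form is supported.
* **Distance decay** `D_ij = exp(−d_ij / λ)` from a constant per-bp
  Cohesin dissociation rate (λ ≈ Cohesin processivity; a power-law
  `d^−k` alternative and a distance-free model are included — on both
  real and model-generated data the distance term turns out to be
  largely redundant once competition is modeled).
* **Loop competition** `LC_ij` — an extruding Cohesin cannot pass a
  pre-formed loop, so overlapping candidate loops compete. The full
  coupled system `LC_ij = Π_{mn ∩ ij ≠ ∅} (1 − p_mn)` is solved by
  successive over-relaxation; the fast approximation
  `LC_ij = Π_{i<m<j} (1 − p_m)` (all internal sites unoccupied) ranks
  pairs nearly identically and is the default.

A Cohesin pass-through probability `s` (each competing factor becomes
`1 − (1−s)·p`) models WAPL loss, which weakens competition and grows
both the number and the length of loops.

The package is tidyverse-native: sites and candidate pairs are tibbles,
every step is pipeable, fitted objects have `tidy()` / `glance()` /
`autoplot()` methods. Readers/writers cover ENCODE narrowPeak, BEDPE
(PET counts), JASPAR PFM motifs and FASTA genomes; a synthetic
landscape generator makes the full pipeline testable without any
external download.

## Worked example

Simulate a reduced-scale genome (10 chromosomes × 5 Mb, 2,000 CTCF
sites with log-normal intensities and random orientations), draw loop
labels from the model, then evaluate, calibrate and perturb it:

```r
library(loopcomp)

cfg <- synthetic_config(seed = 1)   # true params: a = 8.5, w = 3, lambda = 3 Mb
sim <- simulate_landscape(cfg)      # $sites and labelled candidate $pairs
sim$pairs[1:3, c("chrom","pos_i","pos_j","d","ori_class","p_ij","label")]
#> # A tibble: 3 × 7
#>   chrom pos_i  pos_j      d ori_class    p_ij label
#>   <chr> <int>  <int>  <int> <chr>       <dbl> <int>
#> 1 chr1  18834  69111  50277 divergent 0.00246     0
#> 2 chr1  18834  77181  58347 tandem    0.0342      0
#> 3 chr1  18834 127822 108988 tandem    0.0506      0

evaluate_pairs(sim$pairs)
#> <lce_eval> 352 positives / 74696 negatives
#>   AUPRC = 0.1872  AUROC = 0.9768  cor(p, log2 PET) = 0.422

fit <- fit_grid(sim$pairs, lce_grid(), sites = sim$sites)
glance(fit)[, c("a", "w", "decay", "value")]
#> # A tibble: 1 × 4
#>       a     w decay       value
#>   <dbl> <dbl> <chr>       <dbl>
#> 1    10   3.5 exponential 0.189

waplko_scan(sim$sites, lce_params(), s_values = c(0, 0.4),
            call_threshold = 0.05)
#> # A tibble: 2 × 3
#>       s n_loops mean_length
#>   <dbl>   <int>       <dbl>
#> 1   0      1703      50010.
#> 2   0.4    2690      74625.
```

Reading the output: the AUPRC of 0.19 against a positive-class
fraction of 0.5% is a ~40-fold enrichment over chance, with AUROC 0.98
— labels here are Bernoulli draws from the model itself, so residual
error is label noise, and the grid fit lands one grid step from the
generating parameters (a = 10 vs 8.5, w = 3.5 vs 3). Raising the
Cohesin pass-through probability from 0 to 0.4 (a WAPL-knockout-like
regime) adds ~60% more called loops and lengthens the average loop by
~50%, the signature of weakened loop competition.

Real data enter through `read_narrowpeak()` + `normalize_signal()` +
`annotate_orientation()` (peaks, signal, motif strand), `read_loops()`
+ `label_pairs()` (ChIA-PET/Micro-C loops with PET filters), then the
same `enumerate_pairs() |> score_pairs()` pipeline. A thin command-line
wrapper with subcommands `simulate | predict | fit | evaluate |
perturb` is installed as `exec/lce`.

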