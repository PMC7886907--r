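---
title: "The loop competition and extrusion model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The loop competition and extrusion model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopcomp)
```

## The model

`loopcomp` predicts which pairs of CTCF-binding sites anchor a chromatin
loop. The underlying picture is Cohesin-mediated loop extrusion: Cohesin
loads on the fiber, translocates and enlarges a nascent loop, and stops
where it meets DNA-bound CTCF; the stable configuration is a loop with
CTCF bound at both bases. Four probabilistic ingredients multiply into
the loop probability for an ordered same-chromosome site pair $i < j$:

$$p_{ij} \;=\; w_{ij}\, p_i\, p_j\, D_{ij}\, \mathrm{LC}_{ij}.$$

**Occupancy** $p_i$. CTCF binding is a chemical equilibrium,
$p_i = [\mathrm{CTCF}]/([\mathrm{CTCF}] + K_{d,i})$. The local
dissociation constant is not observable directly, so the normalized
ChIP-seq intensity $x$ (signal divided by its genome average) stands in
for $[\mathrm{CTCF}]/K_{d,i}$ up to one dimensionless scale $a$, giving
$p_i = x_i/(x_i + a)$. The default $a = 8.5$ is the value that maximizes
agreement with deeply sequenced lymphoblastoid ChIA-PET loops; it is of
the same order as the in-vitro estimate $K_d/[\mathrm{CTCF}] =
370\,\mathrm{nM}/144\,\mathrm{nM} \approx 2.6$, as expected if chromatin
raises the effective $K_d$ relative to naked DNA. The saturating
alternative $p_i = \tanh(a x_i)$ is available (`binding = "tanh"`); we
reuse the single scale $a$ for it because calibration always refits the
scale per binding form anyway. Note $\tanh$ reaches 1.0 in double
precision around $a x \gtrsim 19$; the codomain $[0, 1)$ is
mathematical, not numerical.

**Orientation** $w_{ij}$. Loops strongly prefer convergent motifs. Each
"non-inward" motif destabilizes the CTCF–Cohesin complex by a factor
$w$: convergent pairs carry weight 1, tandem $1/w$, divergent $1/w^2$.
The default $w = 3$ means a convergent pair is three (nine) times more
likely to loop than an otherwise identical tandem (divergent) pair. The
general two-parameter form $(1, 1/w_1, 1/w_2)$ is supported in both
scoring and calibration and behaves almost identically when
$w_2 \approx w_1^2$.

**Distance** $D_{ij}$. A constant per-bp dissociation probability
$\alpha$ while translocating gives $D_{ij} = \alpha^{d} =
e^{-d_{ij}/\lambda}$, with $\lambda$ (bp) interpretable as Cohesin
processivity; the default is 3 Mb. Two variants: `decay = "none"` sets
$D \equiv 1$ — empirically the model ranks pairs slightly *better*
without the distance term, because distance is largely a proxy for loop
competition — and `decay = "powerlaw"` uses $D = \min(1, (d/10^3)^{-k})$
with $d$ in kb. The kb unit is our choice (the convention is not fixed
by the physics); the clamp keeps the term a probability below 1 kb,
where a raw power law would exceed 1.

**Loop competition** $\mathrm{LC}_{ij}$. A formed loop blocks other
Cohesins, so all candidate pairs whose open genomic intervals overlap
compete:

$$\mathrm{LC}_{ij} = \prod_{mn\,\cap\,ij \neq \emptyset} (1 - p_{mn}).$$

Because $p_{mn}$ appears inside the product and on the left-hand side of
its own equation, this is a fixed-point problem (next section). The
approximation used by default instead requires every retained site
strictly *between* the anchors to be unoccupied,

$$\mathrm{LC}_{ij} \approx \prod_{i<m<j} (1 - p_m),$$

which needs no iteration. The internal-site product deliberately runs
over all retained sites regardless of orientation: occupancy, not loop
geometry, is what stalls extrusion. Pass-through (WAPL section below)
replaces each factor $1-p$ by $1-(1-s)p$.

## Conventions and definitions

* Coordinates are 0-based half-open (BED) everywhere internally; 1-based
  formats are converted at the boundary. The site coordinate is the peak
  summit (narrowPeak offset) or interval midpoint, and all distances are
  midpoint-to-midpoint — loop anchors are ~1 kb, so midpoints are
  adequate and unambiguous.
* "Overlap" in the full competition product means intersecting *open*
  intervals $(pos_i, pos_j)$: nested loops compete; loops sharing only
  an anchor do not. This matches the approximate form, which counts
  strictly internal sites only, and resolves the endpoint ambiguity of
  the set definition in favor of non-competition.
* Candidate pairs span at most 1 Mb by default (over 96% of measured
  CTCF loops fall within this range).
* Sites whose motif orientation cannot be called unambiguously are
  excluded before pairing; measured loops whose anchor overlaps more
  than one retained peak are dropped and counted rather than guessed.
* A pair is labelled positive when each loop anchor overlaps exactly one
  retained peak (≥ 1 bp — anchors and peaks are centered on each other,
  so overlap is the natural criterion) and the PET count reaches
  `min_pet` (4 for deep libraries, 3 for shallower ones). Loops below
  the threshold keep their count but stay negative.

## The iterative solver

`solve_loops()` finds the fixed point of the full competition system by
successive over-relaxation: from the proposal
$p'_{ij} = w_{ij} p_i p_j D_{ij} \prod_{mn \cap ij}(1 - (1-s) p_{mn,k})$
the update is $p_{ij,k+1} = (p'_{ij,k+1} + b\,p_{ij,k})/(1+b)$.
Numerical choices:

* Initialization at the competition-free base term
  $w_{ij} p_i p_j D_{ij}$ (an upper bound of the solution).
* Default $b = 1$, `tol` $= 10^{-6}$ on the largest per-pair change,
  `max_iter` $= 500$; non-convergence raises a warning and a flag, never
  a silent result.
* The per-pair product over competitors is computed with
  chromosome-wide cumulative log-sums (competitors of $ij$ are all pairs
  minus those entirely left of $pos_i$, entirely right of $pos_j$, and
  $ij$ itself), so an iteration is $O(n \log n)$ in the number of pairs;
  a 500-site chromosome (~19,000 pairs) solves in well under a second.
* All products of $(1-p)$ factors, here and in the approximate term, are
  accumulated in log space via `log1p` to avoid underflow on long
  ranges; tiny positive rounding residues are clamped so the term never
  exceeds 1.

The solution is independent of $b$ over a wide range (the test suite
verifies agreement across $b \in \{0.1, 1, 10\}$ against an independent
dense, heavily damped fixed-point oracle run to $10^{-12}$ from several
initializations). One caveat: light damping ($b = 0.1$) can oscillate
indefinitely on large, strongly coupled systems (hundreds of mutually
overlapping pairs); the default $b = 1$ converges in a few dozen
iterations on every landscape we generate.

On realistic landscapes the approximate and the iterative probabilities
rank pairs almost identically (the acceptance suite requires Spearman
$\rho > 0.9$ on a 500-site chromosome and measures ~0.92); the absolute
values differ for long pairs, which face many more competing *pairs*
than internal *sites*. All evaluation defaults therefore use the
approximate term, mirroring how the model is used in practice.

## Calibration

`fit_grid()` maximizes AUPRC (average precision, step interpolation)
over an exhaustive parameter grid; `cv_by_chromosome()` repeats the fit
on chromosome-held-out folds. Design choices:

* AUPRC, not likelihood: the model's nonlinearity (the competition term
  couples all pairs) makes canonical maximum-likelihood awkward, and
  with class ratios of 1:20–1:200 average precision is the metric that
  tracks ranking quality where it matters. AUROC is available as an
  alternative objective.
* Default grids $a \in \{2, 3.5, 5, 6.5, 8, 8.5, 10, 12, 15\}$,
  $w \in \{1, 1.5, 2, 2.5, 3, 3.5, 4, 5\}$,
  $\lambda \in \{100\,\mathrm{kb}, 300\,\mathrm{kb}, 1\,\mathrm{Mb},
  3\,\mathrm{Mb}, \mathrm{none}\}$ bracket the optima reported for real
  ChIA-PET data ($a \approx 8.5$, $w \approx 3$, performance monotone in
  $\lambda$) with a broad high-performance plateau; $w = 1$ is included
  deliberately as the "no orientation effect" null even though the
  fitted value should exceed 1.
* Ties break deterministically toward the smallest parameter values,
  with the distance-free model ordered after finite $\lambda$.
* The AUPRC surface on model-generated data is shallow near the optimum
  (the closed form changes ranking only mildly between neighboring grid
  values of $a$), so recovery is asserted *within one grid step*, and
  cross-validated fold optima are compared against the full-data fit the
  same way.

## Matched-negative sampling

Distance and competition are correlated — distant anchors are more
likely to straddle a competing loop — so their individual contributions
are isolated by matching. For each positive, `matched_negatives()`
draws one negative with the same orientation class whose joint binding
term $p_i p_j$ and whose matched feature ($D_{ij}$ in distance mode,
$\mathrm{LC}_{ij}$ in competition mode) agree within a factor of two,
leaving the other feature free. Sampling is greedy, without
replacement, in seeded random order; positives without any candidate
are dropped and counted, and the constraints are re-asserted on every
emitted pair. On synthetic data the competition-aware model stays
clearly discriminative on distance-matched sets (AUROC ≈ 0.95 in the
acceptance run) while distance alone is near chance on
competition-matched sets — the qualitative signature that competition,
not distance, carries the information.

## Perturbation predictions

`perturbation()` models CRISPR-style edits: `delete` zeroes the
intensity but keeps the site row (so the competition bookkeeping stays
explicit — occupancy simply becomes 0), `invert` flips the motif strand
(touching only $w_{ij}$ unless replacement ChIP intensity is given),
`scale` multiplies the intensity. Predicted consequences follow from
the model structure: deleting a site never decreases the probability of
pairs spanning it (competition release) and leaves pairs on disjoint
intervals exactly unchanged under the approximate term; inverting one
anchor of a convergent pair divides its probability by $w$.

`crossing_outside_map()` emulates the population-genotype comparison
design for a weakened site: 40 kb bins over an 800 kb flank on each
side of the target, the ratio of summed loop probabilities
(weak/strong) for every bin pair, with bin pairs spanning the target
classified *Crossing*, one-sided pairs *Outside*, and bins overlapping
the target itself grayed out of both classes. Under the model every
Crossing ratio is ≥ 1 and Outside ratios move only through second-order
effects. The population "weak motif" genotype is represented by a
configurable scale factor (default 0.5) since SNP-level ChIP deltas are
not published per site; this is a model-side stand-in. 4C read-count
conventions are out of scope — the package outputs per-pair
before/after probabilities for the user to juxtapose.

`waplko_scan()` treats WAPL loss as a Cohesin pass-through probability
$s$: each competing factor becomes $1-(1-s)p$, so probabilities are
nondecreasing in $s$, with long, competition-suppressed pairs gaining
the most. Loops are "called" at a probability threshold (default 0.05 —
a required convention the source data do not pin down; with it, called
loop counts on the default synthetic landscape are of the same order as
the labelled positives). Called-loop count is provably nondecreasing in
$s$; mean called-loop length is asserted nondecreasing as an empirical
property on the landscapes we generate (a pathological landscape could
in principle admit a local dip when a short pair crosses the threshold
late).

## The synthetic landscape generator

Every stage of the package is testable offline against
`synthetic_config()` / `simulate_landscape()`:

* **Geometry.** 10 chromosomes × 5 Mb × 200 sites (mean geometric
  spacing 25 kb), i.i.d. forward/reverse orientations. Site positions
  are cumulative geometric gaps, redrawn if a chromosome overflows.
* **Intensities.** Log-normal raw signals (sdlog 1.25, the broad
  dynamic range typical of CTCF peak strength distributions),
  normalized by a background level set so the site-mean of $x$ equals
  `signal_to_background` (default 10 — peaks are strongly enriched over
  the genome background, so their normalized intensity averages well
  above 1; setting it to 1 reproduces the site-mean normalization
  exactly).
* **Labels.** `bernoulli_closed_form` draws labels independently as
  $\mathrm{Bernoulli}(p_{ij})$ from the approximate closed form.
  `occupancy_then_extrude` is mechanistic: occupancy is sampled per
  site, a loop candidate forms between every pair of *successive*
  occupied sites and is accepted with probability $w_{ij} D_{ij}$. The
  successive-occupied construction makes overlapping loops mutually
  exclusive by design, and its exact marginal — computable by the
  $2^n$ enumeration oracle `brute_force_pij()` — equals the approximate
  closed form analytically: $P(i, j \text{ successive occupied}) =
  p_i p_j \prod_{i<m<j}(1-p_m)$. Orientation-rejected extrusions still
  block, consistent with occupancy (not geometry) being the obstacle.
* **PET counts.** Positives receive $1 + \mathrm{Poisson}(c\,p_{ij})$
  with $c = 60$, calibrated once so the median positive count is ~6,
  which keeps the usual 3–4-PET filters meaningful.
* **Scale honesty.** At this density the positive:negative ratio is
  about 1:200 — more imbalanced than the 1:20–1:37 seen in deep
  ChIA-PET libraries, because at 25 kb spacing the competition term
  suppresses long pairs harder than at the ~60 kb spacing of a real
  genome, and the measured ratios also reflect sequencing depth. The
  ratio is configurable and treated as a reference point, not an
  invariant.

What the generator does *not* emulate: clustered/correlated site
placement and orientation (real CTCF sites cluster at TAD boundaries
and convergent pairs are enriched among strong sites), cell-to-cell
variability, mappability and peak-calling artifacts, anchor-size
heterogeneity, and any contact signal that is not a direct CTCF–CTCF
loop (intra-TAD Hi-C contacts). Passing tests therefore demonstrate
internal consistency and correct implementation of the model — recovery
of known parameters, agreement between independent computational routes
— not predictive performance on real chromatin data.

## Problem sizes and determinism

The test and acceptance runs use the default 2,000-site genome
(~75,000 candidate pairs) for calibration and cross-validation, a
500-site chromosome (~19,000 pairs) for the approximate-vs-iterative
comparison, and ≤ 12-site instances for enumeration and fixed-point
oracles; the full suite completes in about a minute on one CPU. All
stochastic steps (generation, labelling, fold shuffling, matched
sampling) are seeded through `withr::with_seed`, so every result in the
README and the acceptance JSON is exactly reproducible from its stated
seed.

## Known limitations

* Cohesin loading is assumed uniform along the genome; loading hotspots
  and compartment effects are not modeled, and no polymer dynamics are
  simulated.
* The approximate competition term ignores competitors whose anchors
  both lie outside $(i, j)$ yet overlap it; the iterative solver
  accounts for them, which is exactly where the two diverge for long
  pairs.
* The occupancy scale $a$ is degenerate with the normalization of $x$:
  only their combination is identified, so $a$ must be refit whenever
  the signal normalization convention changes (site-mean vs genome
  background).
* Orientation annotation reimplements best-PWM-hit strand calling with
  a documented threshold (80% of the maximum achievable log-odds score)
  rather than reproducing any specific motif scanner bit-exactly.
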