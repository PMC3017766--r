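---
title: "Detecting separate time scales in replicate expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting separate time scales in replicate expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftscan)
```

## The problem and the model

A time-series expression experiment measures one time scale explicitly —
minutes since release from a synchronization arrest, or position along a
developing organ. Processes synchronized to that scale produce the same
temporal pattern in every replicate. A process running on a *different*
time scale, unaffected by the synchronization, is caught by each replicate
in a different state: its pattern appears in both replicates, but displaced
in time. shiftscan detects such genes by scoring the similarity of the two
replicate series at every integer displacement and asking at which shift
the similarity is most statistically surprising.

Each gene's series of $N$ values is first converted to a rank permutation
$\pi$, with rank 1 for the highest value (so $(0.3, 0.5, 0.6, 0.2)$ becomes
$(3, 2, 1, 4)$). Ranks discard amplitude and emphasize shape, and make the
null model a uniformly random permutation for *any* i.i.d. data — the
method is distribution-free. Exact ties, rare in high-resolution data, are
broken uniformly at random under a recorded seed (`tie_seed`), and the
number of tie-broken values per gene is kept as an audit trail.

For a shift $s \ge 0$ the similarity of the two rank profiles over the
overlap window of width $W = N - |s|$ is

$$\gamma(s) = \frac{1}{N} \sum_{j=1}^{N-s} \left|\pi^1_{j+s} - \pi^2_j\right|,$$

and symmetrically for $s < 0$. Small $\gamma$ means similar shape;
$\gamma = 0$ is a perfect rank match across the window. Positive $s$ means
replicate 1's pattern occurs later than replicate 2's; the convention is
arbitrary (nothing distinguishes the replicates a priori) and swapping the
replicates flips the sign, which the test suite verifies as an exact
symmetry.

Treating each normalized rank as a continuous Uniform(0,1) variable, a
single absolute difference has mean $1/3$ and variance $1/18$; summing the
$W$ window pairs gives the Gaussian null

$$\mu = W/3, \qquad \sigma = \sqrt{W/18},$$

on the scale above. The p-value is the one-sided lower-tail probability
$P(\Gamma \le \gamma)$, meaningful only in the similarity direction
$\gamma < \mu$. Because $\mu$ and $\sigma$ both shrink with $W$, a modest
$\gamma$ in a wide window can be more significant than a smaller $\gamma$
in a narrow one — the most significant shift is deliberately *not* the
shift minimizing $\gamma$. Each gene is assigned the shift with the
smallest p-value among shifts showing similarity; exact p ties (measure
zero in real data) go to the smaller $|s|$, then the positive sign.

Note that the whole inference is invariant to jointly rescaling $\gamma$,
$\mu$ and $\sigma$ by any positive constant — only the standardized
deviate enters the p-value. The acceptance script verifies this to
machine precision, so nothing hinges on which normalization of the rank
sum one prefers.

```{r example}
sim <- generate_pair(sim_config(M_sync = 20, M_shifted = 20, M_noise = 20,
                                N = 20, s0 = 2, noise_sd = 0.25, seed = 1))
res <- classify_all(sim$pair, s_max = 6, alpha = 0.001)
res
table(truth = sim$truth$class, called = res$table$best_shift, useNA = "ifany")
```

## Tunable parameters

* `s_max` (grid steps): the scan covers $-s_{max} \dots +s_{max}$. Keep
  $s_{max} \le \lfloor N/2 \rfloor$ so the overlap window always covers at
  least half the series; `preset_yeast()` (28 samples at 8-minute spacing,
  $s_{max} = 6$, i.e. ±48 minutes) and `preset_root()` (12 sections,
  $s_{max} = 6$) encode the two benchmark designs.
* `alpha`: a raw per-gene threshold on the best p-value (0.001 for the
  dense yeast design, 0.01 for the root design). No multiple-testing
  correction is applied by default, matching how the thresholds are meant
  to be used — as class-purity controls, not family-wise guarantees; a
  Benjamini–Hochberg column over genes is emitted for users who want one.
* `tie_seed`: seed for the random tie-break; fixed by default so runs are
  reproducible byte for byte.
* Resampling: `resample_linear()` fits simple linear splines and refuses
  to extrapolate. Replicates sampled on different grids are aligned with
  `align_replicates()`, which can drop leading samples (e.g. the first of
  13 sections) and interpolates both onto a common grid (`"auto"` = the
  coarser replicate's grid restricted to the shared range).

## What the synthetic data emulates

`generate_pair()` builds two replicates with three gene classes:
*sync* genes carry the same smooth pattern at the same position in both
replicates, *shifted* genes carry it displaced by `s0` grid steps in
replicate 1, and *noise* genes are i.i.d. Gaussian. Independent Gaussian
noise of SD `noise_sd` (default 0.25 in units of the unit amplitude) is
added to every measurement.

The default pattern is a sinusoid with a period of 10 grid steps and a
random phase per gene — an oscillatory process sampled roughly ten points
per cycle, as in a cell-cycle course spanning about two cycles. The choice
matters: a rank statistic can only localize a shift if the pattern's ranks
vary informatively across the whole window. A single Gaussian bump
(`pattern = "gaussian_bump"`) has flat tails whose ranks are pure noise,
and under realistic noise its recovery of the embedded shift collapses
toward chance even though the zero-noise case is exact; it is kept as an
option precisely because it illustrates that failure mode. A strictly
monotone `"ramp"` is also available. Shifted patterns exit the window by
default (`wrap = FALSE`); wrapping is available for periodic,
cell-cycle-like signals.

The generator does *not* emulate microarray technicalities — probe
effects, normalization residue, heteroscedastic or heavy-tailed noise,
correlated genes — so passing recovery tests here demonstrates the
statistic's behaviour under its own model, not performance on any real
platform. Ranks make the method insensitive to monotone distortions, which
is the main reason the idealization is informative at all.

## Numerical choices and calibration

* The Gaussian null is validated against two oracles: exhaustive
  enumeration of all permutation pairs for $N \le 6$ (the exact discrete
  null; its mean is $W(N^2-1)/(3N^2)$, e.g. exactly $1.25$ at $N=4, s=0$
  against the continuous $\mu = 4/3$) and seeded Monte Carlo
  (`mc_null()`, `validate_gaussian()`) elsewhere. The acceptance suite
  runs both at $N = 28$ with $10^5$ draws per window.
* Empirical p-values use the add-one estimator $(1 + \#\{\gamma' \le
  \gamma\})/(R+1)$, never exactly zero and monotone in $\gamma$.
* Conservativeness is assessed at realizable lattice atoms with a
  three-standard-error Monte-Carlo slack; without the slack, a single
  extreme draw (whose add-one estimate is floored at $1/(R+1)$) would be
  flagged as a violation on sampling noise alone.
* Degenerate (constant) series are rank-randomized, flagged, and excluded
  from significance; they carry no shape information.
* Ranks are computed once on the full series and retained inside each
  window, not re-ranked per window — the null is defined for whole-series
  permutations, and re-ranking would change it.

## Known limitations

* **The Gaussian bound fails for narrow windows.** Exhaustive enumeration
  shows the Gaussian tail *underestimates* the exact p across the whole
  significant tail for $W \lesssim 8$ (at $N = 4$, $\gamma = 0$ has exact
  probability $1/24$, an order of magnitude above the Gaussian tail
  there). The often-quoted upper-bound property is a wide-window
  phenomenon; at the benchmark widths ($W \ge 22$) the Gaussian p exceeds
  the empirical p by a factor of roughly two throughout the usable tail.
  Treat results from windows narrower than ~12 points with care, or use
  `empirical_pvalue()` directly.
* **Per-gene type-I error exceeds the nominal threshold.** The
  classification takes the minimum p over $2 s_{max} + 1$ shifts with no
  multiplicity correction, so although each individual shift's test is
  conservative (rejecting at roughly 0.4× the nominal rate at $W = 28$),
  the fraction of pure-noise genes declared significant is about the sum
  of the per-shift rates — several times `alpha`, as the acceptance suite
  measures. This is inherent to the raw-threshold design; the emitted BH
  column is the remedy when gene-level error control matters.
* **CDF accuracy.** The true null SD at $s = 0$ is the Spearman-footrule
  SD, about 9–10% below $\sqrt{W/18}$ (independence ignores the
  within-permutation dependence), so the Gaussian CDF overstates the lower
  tail by up to ≈0.025 at $W = 28$ — entirely in the conservative
  direction.
* **Short series.** With $N = 12$ and shifts up to ±6, half the scanned
  windows cover fewer than 9 points and recovery of an embedded shift
  drops below 90% even at moderate noise; the recovery guarantees tested
  here use $N \ge 20$.
* Sub-grid (fractional) shifts are not modelled; a true shift of +2.5
  steps spreads its genes over the +2 and +3 classes. Resample to a finer
  grid rather than interpolating shifts.

## Problem sizes used in validation

The test and acceptance suites run entirely on synthetic data: $10^5$
Monte-Carlo null draws per window width at $N = 28$; 10,000 pure-noise
genes for the type-I measurement; 500 embedded genes at $s_0 = +2$,
$N = 20$, noise SD 0.25× amplitude for recovery; exhaustive enumeration
(all 576 permutation pairs at $N = 4$; all pairs for $N \le 6$) for the
exact oracles; 30 genes around 3 templates for module recovery. These
sizes make the full suite run in well under a minute while leaving the
Monte-Carlo standard errors an order of magnitude below every tolerance
asserted.

## Multi-replicate designs

For $m \ge 3$ replicates, pick $m - 1$ independent replicate pairs,
compute each pair's shift and p-value, and combine the p-values with
`fisher_combine()` ($-2\sum\log p$ against $\chi^2_{2k}$); the gene's
position in the $(m-1)$-dimensional shift space is its class. The volume
of that space grows quickly — beyond four replicates the classes become
too sparse to be useful. Note Fisher combination concentrates evidence
only for small p: three copies of $p = 0.6$ combine to a *larger* value,
which is correct behaviour, not a defect.
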