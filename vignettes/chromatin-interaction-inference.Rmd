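---
title: "Inferring chromatin interactions from single-cell open chromatin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromatin interactions from single-cell open chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`chromglasso` treats the accessibility of the occupied 25-kbp bins of one
chromosome as a multivariate Gaussian over cells. Peak-level counts are
merged into bins (read counts of peaks in the same bin are added) and
log-transformed, `x̄ = log(x + 1)`. With U the empirical covariance of the
binned log counts (cells as observations), the precision matrix Θ is
estimated by maximizing

$$\log\det\Theta \;-\; \mathrm{tr}(U\Theta) \;-\; \sum_{i\neq j}\rho_{ij}\,|\Theta_{ij}|,$$

a graphical lasso whose L1 weight differs per bin pair. Off-diagonal partial
correlations of Θ, $-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$, measure
co-accessibility after conditioning on every other bin and are reported as
interaction calls. The elementwise penalty is where prior knowledge enters:

$$\rho_{ij} = \frac{\delta}{h_{ij} + \varepsilon},$$

with $h_{ij}$ the enrichment between bins $i$ and $j$ averaged over Hi-C
contact maps of related cell types. Chromatin looping is substantially
conserved across cell types (CTCF-anchored loops, TAD boundaries), so a pair
supported by conserved contacts is penalized lightly and can be recovered
even when drop-out attenuates its sample covariance, while unsupported pairs
need strong evidence to survive the penalty $\delta/\varepsilon$.

## Assumptions worth stating

* Gaussianity of log counts is an approximation; it is what licenses reading
  the precision matrix as partial correlations.
* The prior helps exactly to the extent that looping is conserved between
  the cell types providing the Hi-C maps and the cell type being profiled.
  A cell-type-specific interaction without prior support is still
  recoverable when its covariance is strong, because the penalty is finite
  everywhere (that is the role of $\varepsilon$).
* Estimation is per chromosome; trans-chromosomal contacts are out of scope.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | 25000 | bp | genome bin width; Hi-C dumps must share it |
| `delta` | 1 | — | global penalty scale; the sensitivity knob: larger = fewer calls |
| `eps` | 1 | enrichment units | pseudo-count; caps the penalty at `delta/eps` where no contact is known |
| `constant_rho` | 0.01 | — | uniform penalty of the baseline mode |
| `rank` | `min(50, ⌊min(m,n)/2⌋)` | — | target rank of the MM completion |
| `a` | 1 | — | majorization step constant; must be ≥ the spectral norm of the 0/1 mask, which is 1 |
| `mm_iters`, `mm_tol` | 200, 1e-5 | — | completion stopping rule (relative cost change) |
| `tol`, `max_iter` | 1e-4, 100 | — | graphical-lasso stopping rule (relative objective change, outer sweeps) |
| `min_abs_score` | 0 | — | call threshold on the partial correlation; sparsity is meant to be driven by `delta`, not by this |

The defaults for `bin_size` (25 kbp), `constant_rho` (0.01) and the
evaluation sizes (top 60,000 pairs per chromosome; proportional allocation
with 60,000 for the longest chromosome) follow the published workflow this
package reimplements. `delta`, `eps`, the completion rank and the mask are
not published; they are surfaced as configuration with the defaults above,
and the singular-value spectrum of the input is logged to aid rank choice.

# Design decisions on genuinely open points

* **Penalty form.** The source description typesets the penalty ambiguously;
  only an inverse relation is consistent with its own prose (the
  pseudo-count "stops inflation" of penalties when no contact is found, and
  known interactions must be penalized *less*). We use
  $\rho_{ij}=\delta/(h_{ij}+\varepsilon)$, strictly decreasing in $h$.
* **Peak-to-bin assignment.** Peaks spanning a bin boundary are assigned
  whole to the bin containing their midpoint. This keeps read counts
  conserved (every read counted once), which splitting would not without
  fractional counts.
* **Logarithm base.** Natural log; the base is not stated in the source and
  only rescales the covariance, which the penalized objective absorbs;
  recorded in the output metadata.
* **What is "missing" for the completion.** Zeros in scATAC data are
  ambiguous (true absence vs drop-out). Default: all entries observed, so
  the completion acts as low-rank denoising with non-negativity; an optional
  mode (`mask = "zeros"`) treats exact zeros as unobserved. Both are exposed
  because neither reading is published.
* **Mask operator.** The observation operator is implemented as elementwise
  (Hadamard) 0/1 masking, self-adjoint, the only reading with consistent
  dimensions.
* **Diagonal penalty.** The precision diagonal is never penalized:
  penalizing it shrinks variances and fights positive definiteness at large
  $\delta$ without helping edge selection.
* **Averaging maps.** When averaging Hi-C maps, a pair absent from one map
  contributes 0 — absence of evidence gives the conservative (maximal)
  penalty.
* **Call sign.** Only positive partial correlations are calls by default
  (co-accessibility is a positive-association concept); `sign_mode = "both"`
  retains negative ones with signed scores.
* **Evaluation matching.** Bin-exact at the shared resolution (both anchors
  equal to the positive pair's bins); a `slack_bins` option exists for
  robustness studies but defaults to 0. Diagonal Hi-C entries are excluded
  from positive sets.

# Numerical choices

* Covariance uses the maximum-likelihood normalization $1/m$ (matching the
  likelihood in the objective); at hundreds of cells the difference from
  $1/(m-1)$ is immaterial.
* Singular covariances — the norm when bins outnumber cells — get a jitter
  of $10^{-6}\,\mathrm{tr}(U)/p$ on the diagonal before fitting.
* The solver is block coordinate descent (one lasso subproblem per
  row/column, per-coefficient penalties, warm starts), with the inner loop
  in compiled code. Convergence is declared on relative objective change;
  the per-sweep penalized log-likelihood trace is stored on the fit object.
* Entries of Θ below 1e-10 in absolute value are treated as exact zeros when
  counting edges.
* Completion keeps `X ≥ 0` by truncating negative entries after every
  iteration; the masked cost is checked to be non-increasing in the tests.
* Top-N positive-set ties at the cutoff are broken by (value desc, i asc,
  j asc), making evaluation deterministic.

# The synthetic world

The generator emulates the statistical structure the model assumes, with
known ground truth:

1. a sparse precision matrix with edges planted at chosen genomic distances
   (default 30% beyond 500 kbp), negative off-diagonal weights drawn from
   U(0.15, 0.35) and diagonal dominance enforcing positive definiteness —
   planted partial correlations land around 0.1–0.3, the weak-signal regime
   that makes the prior matter;
2. cells as zero-mean Gaussian draws from the implied covariance, mapped to
   counts by `max(0, round(exp(2 + z) − 1))` — the location 2 keeps the
   exponent positive for almost all draws, so `log1p` of the counts recovers
   the latent scale (verified: empirical covariance within 5% relative
   Frobenius error of the truth at 50,000 cells) — followed by independent
   dropout (default rate 0.3, a typical sparsity aggravation for scATAC);
3. a Hi-C-like prior containing each planted edge with probability 0.8
   (prior fidelity: conserved loops known from other cell types) plus 50
   decoy pairs, enrichment values lognormal around 10, written in the
   juicer-dump text dialect the loader reads.

What a green test establishes: that the prior-weighted fit recovers planted
edges better than the constant-penalty baseline (AUPRC, 5 seeds) and that
planted >500-kbp edges are recovered while a 500-kbp-capped variant finds
none there. What it does not establish: performance on real data — the
generator has no distance decay in the prior, no batch effects, no
zero-inflated count model (the latent-Gaussian choice is deliberate: it
makes ground-truth partial correlations exact and recovery quantifiable),
and one peak set per bin rather than ragged peak landscapes.

# Known limitations

* No model selection for $\delta$ (cross-validation or stability selection
  is a knob for the user, not automated).
* No FDR attached to individual calls; scores are partial correlations, not
  probabilities.
* Binary `.hic`/`.cool` files are not parsed; dump them to three-column text
  first.
* Accuracy numbers from the original study (per-cell-line evaluation against
  cell-matched Hi-C) require external accessions and are intentionally not
  asserted by the test suite.
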