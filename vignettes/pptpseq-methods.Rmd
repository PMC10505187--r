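---
title: "Methods: promoter-activity estimation and differential calling from pooled CRISPRi sort-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-activity estimation and differential calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A pooled promoter-reporter screen couples, on one plasmid, a CRISPRi
cassette that knocks down one transcription factor (TF) and a
promoter–GFP reporter that reads out one promoter's activity. Sorting the
pooled library into contiguous fluorescence gates and sequencing each
gate turns a single flow-sorting experiment into hundreds of thousands of
promoter-activity measurements, one per (sgRNA, promoter) variant. The
package takes the per-bin read counts from such an experiment and
produces per-variant activity estimates, differential
perturbation-response calls, and a signed TF-to-promoter regulatory
network, together with a simulator that generates screens with known
ground truth.

## From reads to bin occupancy

Reads are not comparable across bins: each bin is regrown, prepped and
sequenced separately. With `C_j` cells collected and `R_j` reads
sequenced in bin `j`, a variant's reads `r_ij` convert to estimated
sorted cells

    c_ij = r_ij * C_j / R_j,

valid because sorting each gate for equal time at constant flow makes
collected cells proportional to phenotypic density. The observed fraction
`f_ij = c_ij / sum_j c_ij` still contains a sorter-impurity floor: a
small fraction of cells lands in gates unrelated to their fluorescence.
The calibration removes a constant background `epsilon` per bin,

    f_adj_ij = (f_ij - epsilon) / sum_j (f_ij - epsilon),
    p_ij     = max(0, f_adj_ij) / sum_j max(0, f_adj_ij),

with `epsilon = 0.05` by default. `epsilon` must stay below `1/J` over
the `J` included bins; the configuration enforces this, and under that
guard the all-nonpositive degenerate case cannot actually occur for valid
input (the flag is retained defensively). With `epsilon = 0` the
adjustment is the identity. When a whole bin is dropped from an
experiment (the design supports per-bin `included` flags), all sums run
over the included bins only, and `epsilon` is applied per included bin —
an interpretation choice, since the correction is defined for the full
design.

## The censored log-normal fit

Single-cell fluorescence per variant is modeled as log-normal. Sorting
censors each cell to a gate, so the model's probability of bin `j` is a
difference of normal CDFs at the natural-log gate boundaries `B_j`, with
the outer gates open (`F(B_0) = 0`, `F(B_J) = 1`). The fit maximizes

    logL(mu, sigma | p) = sum_j p_ij log( F_{mu,sigma}(B_j) - F_{mu,sigma}(B_{j-1}) )

and reports the mean activity `exp(mu + sigma^2/2)` in the fluorescence
units of the boundaries. Everything internal runs on natural logs;
boundary tables in log10 are converted once (multiplied by `ln 10`).
Goodness of fit is the Kullback–Leibler divergence
`K = sum_j p_ij log p_ij - logL(mu_hat, sigma_hat | p)`, zero exactly
when the occupancy equals the model's bin probabilities
(`0 log 0 := 0` throughout).

Numerical choices, in order of consequence:

* **Optimizer.** Nelder–Mead on `(mu, log(sigma - sigma_min))`, moment
  initialization on bin midpoints (open outer bins get a pseudo-midpoint
  one interior-bin-width beyond their finite boundary), relative
  function tolerance `1e-12`, one restart from the optimum (a standard
  simplex polish) and a perturbed restart on non-convergence;
  persistent failure flags the variant rather than raising.
* **Sigma floor.** `sigma_min = 1e-3` natural-log units. Near-point-mass
  occupancies push sigma toward zero; the floor keeps the problem
  bounded.
* **Ridge resolution.** Occupancy supported on exactly two adjacent bins
  lies on a likelihood ridge: along `mu = B - sigma * qnorm(p_1)` the
  likelihood rises monotonically as sigma shrinks and flattens below
  machine precision, so any iterative optimizer stalls at an arbitrary
  ridge point. The floored maximum is analytic — `sigma = sigma_min`,
  `mu` on the ridge — and the fit returns it deterministically whenever
  it attains the simplex's likelihood.
* **Dropped bins.** The likelihood becomes the conditional multinomial
  over included bins (model bin probabilities renormalized by the
  included mass), which keeps it a proper likelihood.
* **Single-bin occupancy.** Two parameters cannot be identified from one
  occupied gate; the variant is flagged `single_bin` with no numeric
  parameters.

Four quality filters set a variant's parameters to NA: mean activity
outside the detection limits (defaults `10^1.5`–`10^5`, with a higher
ceiling appropriate for rich-media runs); estimated total sorted cells
below 1; KL divergence above 1; all cells in a single gate.

## Replicates, aggregation, and the control reference

Replicates sorted on different days differ by a smooth scale
transformation. Each replicate's log mean activities are regressed onto a
reference replicate (ordinary least squares over variants usable in both,
at least 20 required) and mapped through the fitted line. The fit uses
QC-passing variants only — the scale relation is only trustworthy where
both measurements are — which is a documented choice, not forced by the
method. Downstream calls are invariant to which replicate is named
reference, because fold changes are differences of `M` values on one
common scale.

Per variant, the rescaled log activities across replicates give a mean
`M_i`, sample standard deviation `S_i` (n−1 denominator, matching the
Z statistic's use of `n−1`), and count `n_i`. Variants with `S_i > 0.7`
are excluded as irreproducible; variants usable in fewer than two
replicates cannot enter the Z test (`S` undefined) and are excluded as
`insufficient_n`. Negative-control sgRNAs are pooled per promoter across
replicates as independent samples; outliers are removed by the
interquartile-range rule with the conventional 1.5 multiplier and
linear-interpolation quantiles (the multiplier is a convention choice),
yielding `M_i0`, `S_i0`, `n_i0`. A control sgRNA known to misbehave is
excluded by name through a user-supplied list rather than auto-detected;
no detection rule is assumed.

## Differential calls

Because mean activity is a log-normal mean, comparing knockdown and
control means uses the log-normal mean-comparison Z statistic

    Z_i = [ M_i - M_i0 + (S_i^2 - S_i0^2)/2 ] /
          sqrt( S_i^2/n_i + S_i0^2/n_i0 + (S_i^4/(n_i-1) + S_i0^4/(n_i0-1))/2 ),

whose numerator carries the variance contribution to the log-normal mean
— two samples with equal `M` but unequal spread genuinely differ in mean
activity. P-values are two-sided from the standard normal reference (the
test could be read as one-sided; two-sided is assumed and stated, since
both directions of response are reported). The FDR family is all
testable (sgRNA, promoter) pairs within one growth condition. Two
adjustments are exposed: Storey q-values (null proportion estimated on
the lambda grid 0.05–0.95 with a df-3 smoothing spline evaluated at
lambda = 0.95, clamped to (0, 1]; the default) and Benjamini–Hochberg.
Both preserve the rank order of p-values; Storey is never more
conservative than BH. Fewer than 20 tests fall back to a null proportion
of 1 (equivalent to BH) since the smoother is not estimable there.

A call additionally requires a substantial fold change — at least
1.7-fold, in the same direction — against **both** the promoter's pooled
negative-control activity and its median activity across all knockdown
conditions. The median reference guards against the minority of
promoters whose control activity is itself atypical. Calls are `up`,
`down`, `ns`, or `na` when prerequisites (usable aggregate, control with
`n >= 2`) are missing.

## Networks and binding-strength analysis

Knockdown lowers TF level, so `up` calls map to repression edges and
`down` calls to activation edges; the edge count equals the non-`ns`
call count exactly. Autoregulation is the subset of edges whose TF is
the gene driven by the edge's own promoter. Cross-condition comparison
partitions (tf, promoter, sign) tuples by membership pattern across
conditions. For in-vitro binding data, one site per (TF, promoter) is
retained (highest fold enrichment), and two normalizations are computed:
per TF (against the TF's strongest site anywhere) and per promoter
(against the strongest TF bound there); both lie in (0, 1] and are
invariant to rescaling all enrichments. Site positions are interval
midpoints relative to the transcription start site, on 0-based half-open
coordinates (BED convention; the positional convention is a choice).
Regulating and non-regulating pairs are compared per feature by the
Wilcoxon rank-sum test, BH-adjusted across features; TF concentration
enters as an optional externally measured column.

## What the simulator does and does not emulate

The generator reproduces the statistical structure of the assay: 16
contiguous log-scale gates spanning log10 fluorescence 1.5–5 with open
outer gates; per-variant log-normal fluorescence with spread drawn from
0.3–0.8 natural-log units (typical of reporter distributions);
proportional-time sorting (multinomial cells per variant over gates,
1000 cells per variant by default); a 5% uniform misallocation floor
matching the calibration's default `epsilon`; read sampling multinomial
over variants within each bin at 20 reads per sorted cell; three
replicates with 0.1 natural-log between-replicate jitter on each
variant's location plus a shared per-replicate scale offset (0.1 SD)
that the rescaling stage must undo. Effects are assigned per
(TF, promoter) pair — 10% of pairs by default, a sparse regime in line
with genome-scale screens where a few percent of pairs respond — and
realized through the sgRNA targeting that TF; 90% of effects are
upward under knockdown, reflecting the predominance of de-repression.
Controls carry fold exactly 1. All randomness flows from one integer
seed; a fixed seed reproduces the tables byte for byte.

Deliberately not modeled: PCR amplification dispersion (a gamma-weighted
read-sampling option exists but is off by default), growth-fitness
dropout of sgRNAs targeting essential genes (low per-variant depth can
be configured, but there is no fitness model), bimodal or non-log-normal
expression, and per-bin variation in sorter impurity. Because the
simulator draws truth from the same log-normal family the estimator
fits, passing recovery tests demonstrates correctness of the estimation
machinery — not adequacy of the log-normal assumption on real cytometry
data, which must be judged from fit diagnostics (the KL filter) on real
input.

## Validation problem sizes

The packaged checks run at desk scale, chosen once: parameter recovery
on 100 analytically exact occupancies (worst-case location error below
ten times the 1e-4 optimizer tolerance); agreement with a brute-force
grid search on 100 sparse occupancies within 2e-3; a null screen of
2000 TF-promoter pairs across three replicates (observed differential
call rate 0 at q <= 0.01 and 1.7-fold); and a two-fold-effect screen at
2000 cells per variant (sensitivity above 0.9, location RMSE below 0.05
natural-log units). `scripts/acceptance.R` recomputes these quantities
from scratch at any seed.

## Known limitations

Fold changes measured from plasmid reporters compress chromosomal
effect sizes; the pipeline reports what the reporter sees. CRISPRi
polarity and off-target activity can produce false-positive responses
upstream of this package's inputs; nothing in the count tables can
distinguish them. The single `epsilon` floor is a first-order model of
sorter impurity. And with only two or three replicates, `S_i` is a noisy
spread estimate — the Z statistic accounts for this through its
`S^4/(n-1)` terms, but power at small effects is correspondingly
limited.
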