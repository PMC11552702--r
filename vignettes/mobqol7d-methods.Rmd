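---
title: "Valuing MobQoL-7D health states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing MobQoL-7D health states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobqol7d)
```

This vignette explains the model the package implements, the parameters
that matter, what the synthetic-respondent generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The descriptive system and the personal utility function

The MobQoL-7D classifies mobility-related quality of life on seven
dimensions (AC, CO, PD, IN, SE, ME, AX), each with four severity levels.
A health state is a 7-digit index with one digit per dimension in that
canonical order; the state space has $4^7 = 16{,}384$ elements. The digit
order is pinned down empirically by the published single-decrement
utilities: "2111111" must reproduce $1$ minus the AC level-2 decrement,
"1112111" $1$ minus the IN level-2 decrement, and so on for every
dimension — a unit test verifies all seven.

An OPUF-style survey yields, per respondent,

* **level ratings**: VAS positions in $[0, 100]$ for levels 2 and 3 of each
  dimension, between that dimension's worst (0) and best (100) level.
  Severities rescale these to $[0, 1]$ with the best level at 0 and the
  worst at 1: $s_d(1) = 0$, $s_d(4) = 1$, $s_d(k) = 1 - \mathrm{VAS}_k/100$
  for $k \in \{2, 3\}$;
* **swing weights**: the most impactful dimension is a yardstick pinned at
  100; the rest are rated in $[0, 100]$ against it. Weights are normalised
  to sum to 1. Inputs above 100 are treated as range violations — whether
  the original elicitation tool permitted them is unknowable from the
  published material, so the package takes the conservative reading;
* **anchoring**: a choice between the worst state "4444444" and being
  dead, followed by a VAS placement. Worst-preferred: the worst state at
  $p$ on a dead(0)–full-health(100) scale gives anchor $A = p/100$.
  Dead-preferred: dead at $q$ on a worst-state(0)–full-health(100) scale.
  The published material describes the VAS layout but not the
  transformation; requiring $u(\text{dead}) = 0$ and
  $u(\text{full health}) = 1$ under an affine change of scale forces
  $A = -q/(100 - q)$, the unique projectively consistent solution. It
  reproduces the documented behaviour that some anchors fall below $-1$
  (exactly when $q > 50$) before the scale is capped at $-1$. The two
  branches agree at indifference ($p = q = 0 \Rightarrow A = 0$), and
  $q = 100$ is treated as the limiting case $A = -1$, not an error.

The personal utility function is the additive model
$u(x) = 1 - \sum_d w_d\, s_d(x_d)\,(1 - A)$, equivalently a $7 \times 4$
matrix of decrements $w_d\, s_d(l)\,(1 - A)$ with a zero level-1 column.
By construction $u(\texttt{1111111}) = 1$ and $u(\texttt{4444444}) = A$.
Capping at $-1$ is applied per respondent to the anchor *before* any
aggregation, so group statistics operate on the capped scale throughout.

## Aggregation, confidence intervals, ranking

A group value set is the arithmetic mean of the respondents' decrement
matrices; by linearity the mean of the respondents' utilities for any state
equals the utility of that state under the mean value set (a property test
checks this to $10^{-9}$). The published tables do not state the CI method
for the value sets; the package uses the percentile bootstrap over
respondents — the method the published coefficient-difference analysis
states explicitly — with 10,000 iterations by default and a seedable RNG.
Resampling is implemented as multinomial weight draws, which is
distributionally identical to index resampling and vectorises cleanly.

When the full state space is ranked, ties are broken by ascending
lexicographic state index so tables reproduce bit-for-bit. Value sets are
stored at full precision; `round_value_set()` produces the 3-decimal
publication view. The package treats the rounded published tables as the
authoritative embedded values; summing the rounded level-4 column gives
worst-state utilities of 0.129 (GP) and 0.201 (MI), consistent with the
published extreme-state table (the published running text also prints a
variant pair computed from unrounded coefficients).

## Between-sample comparisons

Coefficient differences are A-minus-B gaps in mean decrements with
independent percentile-bootstrap resampling of each sample (sizes
preserved), flagged significant at the 5% level when the 95% CI excludes
zero. The utility-difference distribution is computed by exhaustive
enumeration of all 16,384 states — never sampling — and has a closed-form
check: under uniform enumeration each level has probability $1/4$
independently across dimensions, so the mean difference equals minus the
sum over dimensions of the mean-over-levels decrement gap, and the
variance is the sum of per-dimension level variances. The SD over the
state space is the population SD (divide by $N$); at $N = 16{,}384$ the
sample/population distinction is far below reporting precision. Quartiles
use linear interpolation between order statistics; they are reported but
not asserted against the published percentile sentence, whose ordering is
internally inconsistent (it decreases with increasing percentile).

## Scoring applications

QALYs are piecewise-constant utility times duration, summed over segments;
no discounting (a deliberate scope choice — discounting belongs to the
downstream economic model). Population norms group scored utilities by
gender × age band, excluding rows with unstated demographics, and report
the group mean with a 95% $t$-interval; the published norm tables do not
state their CI method, and the $t$-interval is the standard choice for
small groups (some published groups have $n = 4$). Groups below
`min_group_size` (default 5) are flagged rather than suppressed.

## Quality control

`validate_respondent()` flags, never drops: `RANGE_VIOLATION` (any input
outside $[0, 100]$ or an unparseable state/branch), `ALL_ZERO_WEIGHTS`
(preferences undefined), `NONMONOTONE_LEVELS` (level 2 rated below level
3), and `INVERTED_GLOBAL` (the raw responses imply the best state is worse
than the worst state). Because the schema bounds all inputs, an inverted
global ordering can only arise from out-of-range raw values (e.g. a
worst-preferred anchoring VAS above 100 implying an anchor above 1), so the
flag is computed generically from the un-clamped implied utilities and
fires alongside the range flag on such rows. The default exclusion policy
(`"paper"`) removes range violations, all-zero weights and globally
inverted records — the class of inconsistency the original data cleaning
describes — while non-monotone intermediate ratings are retained, since
they are a coherent (if unusual) preference statement; `"keep-all"` retains
everything with flags attached. Invariant checks use an absolute tolerance
of $10^{-9}$; oracle-equivalence tests use $10^{-12}$.

## The synthetic-respondent generator

The generator emulates the survey's response structure: per-dimension
truncated-normal VAS positions and swing weights on $[0, 100]$, the
yardstick drawn as the argmax of the latent weights and pinned to 100, a
Bernoulli worst-preferred branch, branch-specific truncated-normal
anchoring VAS, per-dimension categorical own states and demographic
marginals. The default profiles take their level-rating and swing-weight
means/SDs, branch probabilities (66% / 72% worst-preferred) and
demographic marginals from the published sample summaries. Distribution
families are the simplest ones matching published moments: nothing in the
published material identifies shapes.

Three calibration choices were made once and not revisited:

* **own-state severity**: level probabilities (GP 0.75/0.19/0.045/0.015,
  MI 0.17/0.39/0.33/0.11 per dimension) chosen to match the reported mean
  severity scores of 9.3 and 16.7 (severity score = sum of the seven
  levels, a definition the package adopts as the natural ordinal summary;
  it is consistent with those reported means);
* **anchoring VAS**: worst-branch mean 50 (GP) / 55 (MI), SD 30; dead
  branch mean 28, SD 24 for both. These place the capped-anchor mean near
  the published 0.171 / 0.242 and give roughly
  $P(\text{dead branch}) \times P(q > 50) \approx 6\%$ of pre-cap anchors
  below $-1$, matching the published share;
* **dependence**: dimensions are drawn independently. This understates the
  reported severity-score SDs (3.2 / 4.0), which reflect correlated
  impairment across dimensions in real respondents.

**Truncated-normal sampling and calibration.** Several published mean/SD
pairs lie outside the moment set attainable by a normal truncated to
$[0, 100]$: at a given mean the SD supremum is the exponential-tail limit
(about 24.4 at mean 29.6, below the published 26.5 for one level-3 cell).
Chasing such targets pushes the latent parameters into extreme-tail
regimes where rejection sampling has acceptance probabilities near
$10^{-9}$. The generator therefore samples by the exact inverse-CDF
transform (identical distribution, no acceptance loop, computed on the
nearer tail for numerical stability), and the calibration matches the
target *mean* exactly (root-finding in the latent location, which the
truncated mean is monotone in) while minimising the SD error over the
latent scale; for infeasible cells the simulated SD saturates at the
family's supremum and the mean remains exact. Recovery tests therefore
target means, branch probabilities and the below-$-1$ share — the
generator's own parameters — not the study's unobtainable joint
distribution.

`expected_decrements()` is the oracle for parameter-recovery tests: the
expectation of the anchored decrement matrix under the profile's joint
draw. Because the normalised weights depend on all seven latent draws
(argmax pinning, shared denominator), $E[w\,s\,(1-A)]$ does not factor
into marginal means, so the oracle integrates by large-sample Monte Carlo
(200,000 joint draws by default, with per-cell standard errors attached)
through a direct matrix-form path separate from the record-level
simulator.

**What passing tests show — and don't.** Green recovery tests demonstrate
that the pipeline is an unbiased, deterministic implementation of the
stated model under the generator's assumptions (independence, truncated
normality, no response error correlation). They do not certify behaviour
on real survey data, which exhibits digit preference, correlated
dimensions and respondent inconsistency beyond the flags modelled here.

## Problem sizes and determinism

The test suite uses 5,000 simulated respondents for value-set parameter
recovery (checked within 3 combined Monte-Carlo standard errors per
coefficient), 500 replications of two 50-respondent null samples at 1,000
bootstrap iterations for the significance-rate calibration (nominal 5%,
accepted 3–8%), and the full 16,384-state enumeration wherever the state
space is involved — sizes at which every statistical check is stable under
reruns with different seeds. Every stochastic routine takes an explicit
seed, restores the caller's RNG state, and writes identical bytes on
identical inputs; the command-line layer records its configuration in a
`provenance.json` next to each output.

## Known limitations

* The additive PUF has no interaction terms by construction; states
  differing only in how severity is distributed across equally weighted
  dimensions can tie.
* The generator's independence assumption makes its severity-score SDs
  narrower than the published samples'; a common severity factor would be
  the natural extension.
* Norm tables computed under both value sets emit one CI per value set;
  the published layout (one CI column against two means) is ambiguous and
  is not replicated verbatim.
* The embedded value sets are the published 3-decimal tables; quantities
  derived from unrounded study coefficients can differ in the third
  decimal.
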