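---
title: "Copy-number marker calling for gliomas: models and design choices"
author: "gliomacnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number marker calling for gliomas: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomacnv)
```

## The problem

The WHO CNS5 classification of diffuse gliomas leans heavily on a small set
of copy-number markers: complete codeletion of chromosome arms 1p and 19q
defines oligodendroglioma; its absence in an IDH-mutant diffuse glioma
points to astrocytoma; the +7/−10 signature (whole-chromosome 7 gain with
chromosome 10 loss) and EGFR amplification are molecular hallmarks of
glioblastoma in IDH-wildtype tumors; and homozygous — but not hemizygous —
deletion of CDKN2A/B supports WHO grade 4. Low-pass whole-genome long-read
sequencing resolves all of these from a single cheap run, but two
obstacles stand between raw read counts and a defensible call: technical
bias (GC content, mappability, pericentromeric noise) and tumor purity.
At tumor fraction $t$, every copy-number deviation is attenuated toward
the diploid baseline, and — critically — a homozygous deletion in an
impure sample looks exactly like a hemizygous deletion in a purer one.
`gliomacnv` implements the full chain from alignments (or binned counts)
to a structured report, with tumor fraction modeled explicitly at every
step.

## Binning and bias correction

Reads are counted in fixed 500-kb windows (the default; configurable down
to 10 kb) by the leftmost aligned base, after dropping unmapped,
secondary/supplementary, and MAPQ < 20 records. Counting by the leftmost
base rather than the midpoint keeps the assignment deterministic for long
reads spanning window boundaries.

Bias correction is two-stage. First a smooth curve of count versus GC is
estimated from the data itself: bins are stratified into GC strata (at
most 50, never fewer than ~10 data bins per stratum so a genuine CNV
cannot dominate a stratum), the stratum medians are fitted with a
tricube-weighted local quadratic spanning 30% of the observed GC range,
and each count is divided by its fitted value. Medians make the curve
robust to altered segments; the local polynomial tracks curved bias that
a moving median would flatten incompletely. Second, counts are divided by
mappability where a track is supplied, and bins below the mappability
threshold (default 0.75) are dropped. Log2 ratios are taken against the
median of valid **autosomal** bins — sex chromosomes never enter the
centering, so an XY sample does not drag the diploid baseline down.
Pericentromeric bins are excluded with one flanking bin of padding on each
side (configurable); bins with zero counts or missing GC are invalid and
stay invalid through every later stage.

An optional panel of normals subtracts the per-bin **median** log2 ratio
across the panel (robust to one aberrant normal); bins invalid in at least
half the panel are invalidated.

## The segmentation model

Valid bins are decoded into integer copy states $c \in \{0,\dots,5\}$
(state 5 absorbs higher amplifications) with a hidden Markov model decoded
by the Viterbi algorithm per chromosome. The emission center for state $c$
at tumor fraction $t$ is the standard admixture expectation

$$\mu(c, t) = \log_2\!\frac{t\,c + 2(1-t)}{2},$$

zero at $c = 2$ for any purity and attenuated toward zero as $t \to 0$.
Emissions are Gaussian with a standard deviation estimated robustly from
the data as $\mathrm{mad}(\Delta x)/\sqrt{2}$ — the scaled median absolute
deviation of first differences, which is insensitive to segment structure.
Transitions are homogeneous with a small switch probability ($10^{-4}$ by
default) shared across all state changes; chromosomes are decoded
independently, and invalid bins are bridged by a single transition without
emitting.

**The scaling degeneracy and the state prior.** The admixture expectation
has an exact symmetry: a profile decoded as states $\{1, 3\}$ at fraction
$t$ has identical emission centers to one decoded as $\{0, 4\}$ at $t/2$
($\mu(1,t) = \mu(0,t/2)$ and $\mu(3,t) = \mu(4,t/2)$). Under a uniform
state prior the two readings are exactly equally likely and tumor fraction
is unidentifiable from arm-level events alone. We resolve this the way
tumor-fraction CNV callers conventionally do, with a soft per-bin state
prior $\propto \exp(-\alpha\,|c - 2|)$ (default $\alpha = 0.3$,
config-exposed) that prefers the less extreme interpretation — a
hemizygous arm loss over a whole-arm homozygous deletion. The prior is
weak: a genuine homozygous deletion at any practical purity carries an
emission advantage of several nats per bin, orders beyond $\alpha$.

Tumor fraction is estimated by decoding at every $t$ on a grid (0.05 to
1.00 in steps of 0.01) and keeping the maximum-likelihood decode, with
ties broken toward smaller $t$. A profile whose best decode is entirely
diploid carries no purity information; it is reported at the grid floor
and flagged `non_informative`. Grid search was chosen over EM
deliberately: it is deterministic, exhaustively testable, and 0.01
resolution is far below the biological noise floor.

The decoder is verified against brute-force path enumeration (every
$K^n$ path scored by direct density composition) on hundreds of random
small instances; the enumeration oracle includes the same state prior,
because it checks decoding optimality, not model choice.

## The CDKN2A/B deletion baseline

Distinguishing homozygous from hemizygous CDKN2A/B deletion is the grade-4
question, and it is exactly where purity bites: at tumor fraction $t$ the
expected copy value at the locus is $2 - 2t$ under homozygous deletion and
$2 - t$ under hemizygous deletion, so the margin between them is only
$t/2$ wide and vanishes in impure samples.

The baseline is calibrated by in-silico admixture: a diploid normal and a
pure tumor carrying the homozygous deletion are depth-normalized to a
common **diploid (median) bin depth** and mixed per bin as
$t \cdot \text{tumor} + (1-t) \cdot \text{normal}$ over fractions 0.1 to
0.9. Median-depth rather than total-count normalization matters: the
deleted tumor genome has less mass, so total-count scaling inflates its
per-cell depth and biases the mixture algebra; with median scaling the
noiseless series reproduces $\text{copy}(t) = 2 - 2t$ to float precision.
Each mixture runs through the full correction pipeline, the copy value at
the marker bins is extracted as the mean of $2 \cdot 2^{\log_2 r}$, and
ordinary least squares of copy value on true fraction yields the baseline
(slope $\approx -2$, intercept $\approx 2$). A packaged default baseline
fitted on a noiseless synthetic series ships with the package (clearly
labeled synthetic in its provenance) and can be regenerated or refitted
from user data with `simulate_admixture_series()` + `fit_baseline()`.

An observed deletion is typed by nearest expectation — fitted homozygous
baseline, analytic hemizygous $2 - t$, neutral 2 — with cuts at the
midpoints. The hemizygous expectation is analytic rather than fitted
because only the homozygous case needs empirical calibration. A fitted
slope above $-0.1$ marks the baseline unusable (a flat series carries no
deletion signal; floating-point noise around zero must not pass a
`slope < 0` check).

Deletion typing is attempted only when the tumor-fraction estimate is
informative. At the grid floor the three expectations collapse to within
per-bin noise and any call would be noise; such samples report CDKN2A/B
as neutral with an explanatory note. Conversely, typing does **not**
require the Viterbi decode to show the deletion: a 2-bin focal event at
moderate purity cannot repay the transition penalty
$2\log(\text{switch}/(K-1)) \approx -22$ nats, yet its copy value
discriminates cleanly — the segmentation answers "how pure, what
landscape", the baseline answers "what zygosity".

## Marker calls and classification

Arm and whole-chromosome markers are called complete when at least 80% of
valid bins share the altered direction; partial alterations (20% to the
threshold) are surfaced in an evidence note but deliberately not called,
matching the diagnostic requirement of *complete* codeletion. EGFR is
called amplified at the capped top state (≥ 5 copies), gained at 3–4.
Arm/chromosome calls need at least 5 valid bins; focal calls need at
least 1. All thresholds are config-exposed.

The classification engine is a deterministic, total rule set over the
marker composites. In order: codeletion → oligodendroglioma; the +7/−10
signature or EGFR amplification with IDH wildtype-or-unknown → molecular
glioblastoma (taking precedence over the astrocytoma rule, since +7/−10
is the stronger signature — the precedence is recorded in the fired
rules); no codeletion with IDH mutant-or-unknown and any CNV evidence →
astrocytoma; CDKN2A/B homozygous loss → grade-4 support regardless of
entity. Indeterminate composites propagate — no definite rule fires on
missing data. IDH status is advisory only (copy number cannot determine
it) and the output is phrased "CNV-consistent-with", with a fixed
disclaimer that this is decision support, not a diagnosis. Every output
cites its fired rules with stable ids; the engine is exhaustively
enumerated over the full status × IDH product in the test suite.

## The simulator: what it emulates, what it does not

The simulator generates per-bin counts as negative binomial with mean
$\lambda \cdot b(\mathrm{gc}) \cdot (t c + 2(1-t))/2$: configurable depth
(default 100 reads/bin, typical of low-pass runs at 500-kb windows),
overdispersion (default size 20 — low-pass nanopore depth is clearly
overdispersed relative to Poisson), a smooth polynomial GC bias over a
fixed genome-like GC landscape, planted arm-level and focal events at a
known tumor fraction, and a mandatory seed. A profile-level generator
(Gaussian log2 noise around the admixture expectation) isolates the
segmentation model from count-level correction; segmentation-recovery
results are characterized at per-bin log2 noise 0.1.

Four named presets cover the canonical genotypes (neutral;
1p/19q-codeleted; +7/−10 with EGFR at 8 copies; CDKN2A/B homozygous
deletion). Presets use depth 400 and dispersion 600 — per-bin log2 noise
about 0.09, the ≤ 0.1 regime deletion typing is designed for. The
grade-4 preset plants chr13 and chr18 single-copy background losses along
with the focal deletion: real high-grade astrocytomas are aneuploid, and a
genome whose only event is one focal homozygous deletion leaves tumor
fraction unidentifiable at low purity (the ratio $2-2t$ is exactly a
hemizygous deletion at $2t$, and the state prior then prefers the wrong
reading). The same background is used in the deletion-typing validation.

What the simulator does **not** emulate: read-level error profiles,
mappability structure (tracks are unit by default), replication-timing or
fragment-length bias, subclonal heterogeneity, and genuine inter-sample
GC variability. Passing tests therefore demonstrate correctness of the
*model chain* under its stated assumptions, not performance on real
nanopore data — the calibration hooks (panel of normals, refittable
baseline, config-exposed thresholds) are where real-data adaptation
happens.

## Numerical choices and degenerate inputs

* Emission centers are clamped at $-8$ log2 units so $c=0, t=1$ stays
  finite; ratios below that are indistinguishable from zero coverage.
* Likelihood ties across the tumor-fraction grid break toward smaller
  $t$ (reported conservatively); the all-diploid tie is additionally
  flagged non-informative.
* Bias correction refuses to run with fewer than 50 valid bins or GC
  annotation on fewer than 80% of non-excluded bins; a degenerate
  (constant) GC track skips the GC stage with a recorded warning rather
  than dividing by a flat fit.
* Strata for the GC fit shrink with the data (never fewer than ~10 bins
  per stratum) so toy genomes do not overfit the bias curve into real
  CNVs.
* WIG I/O is 1-based fixed-step on disk, 0-based half-open in memory;
  integer counts round-trip bit-exactly.
* The classification decision cut placed exactly on a midpoint resolves
  to the less severe class.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data
at desk scale: enumeration-oracle instances of up to 8 bins and 4 states
(hundreds of random cases), whole-genome recovery at ~6,200 bins (hg38 at
500 kb) with 20 replicates per condition, 20-seed batches per scenario
preset, and admixture series of 6–9 fractions. These sizes were chosen so
the complete validation runs in minutes on one core while keeping every
statistical check at its stated tolerance.

## Known limitations

* 500-kb windows cannot resolve events much smaller than a bin; CDKN2A/B
  and EGFR are each assessed from 1–2 bins on the shipped builds.
* Ploidy is fixed at 2. Whole-genome doubling will shift every call; the
  markers here are defined relative to diploid and no ploidy search is
  attempted.
* No subclonal modeling: tumor fraction is a single global parameter.
* The default deletion baseline is synthetic; for clinical-grade use it
  should be refitted from an in-house admixture of real samples via the
  provided fitting entry points.
* IDH, ATRX, TERT, MGMT and histone-variant status are out of scope; the
  engine covers the copy-number portion of CNS5 only.
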