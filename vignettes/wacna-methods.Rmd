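---
title: "Joint transcript-metabolite correlation network analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint transcript-metabolite correlation network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wacna)
```

## The problem and the model

Weighted gene co-expression network analysis (WGCNA) summarises a single
expression matrix as a weighted correlation network: the soft-thresholded
adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (unsigned, the
default here; the signed variant $((1+\mathrm{cor})/2)^\beta$ is
available), the topological overlap similarity

$$\mathrm{TOM}_{ij} =
  \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
       {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  k_i = \sum_{u \neq i} a_{iu},$$

and average-linkage clustering of the dissimilarity $1 - \mathrm{TOM}$
into modules, each summarised by its *eigengene* — the first principal
component of the module's analyte-by-sample submatrix.

`wacna` generalises this from genes to *analytes*: transcripts and
untargeted LC-MS metabolite features (m/z-retention-time pairs) measured
on the same biological samples are filtered, imputed, reduced to the
most variable fraction per dataset, row-concatenated, z-scaled, and
analysed as one network. Modules may therefore mix transcripts and
metabolites, and module-eigengene associations with a two-factor design
(diet: CON vs high-fat; exercise: pre vs 3 h post) identify modules of
interest — the analogue of a module-by-condition eigengene display.

The pipeline order is fixed and matters: metabolomics feature QC →
k-nearest-neighbour imputation (k = 3) → univariate statistics → top-20%
variance selection per dataset → combine, centre, z-scale → network →
modules → eigengenes → design association. Imputation precedes variance
selection, and selection precedes scaling.

## Upstream metabolomics stage

**Feature QC.** Pooled-QC injections (a mixture of all biological
extracts injected repeatedly through the run) measure per-feature
technical reproducibility. A feature is removed when its QC relative
standard deviation ($100 \cdot \mathrm{SD}/\mathrm{mean}$ over
non-missing QC values) exceeds 20%, or when it is detected in fewer than
70% of biological samples. The source sentence for this rule is
grammatically ambiguous between OR-removal and AND-removal; we default
to two independent removal criteria (the standard practice: either
defect alone makes a feature unusable) and expose
`rule = "conjunctive"` for the literal conjunctive reading. Features
never observed in any QC injection are removed with reason `rsd`, since
their reproducibility cannot be established. The detection denominator
uses biological samples only by default (`include_qc` switches this).

**Imputation.** Missing metabolome entries are imputed in analyte space,
the classical expression-matrix KNNimpute convention: neighbours of an
analyte are other analytes, ranked by Euclidean distance normalised to
the co-observed sample count; for a missing entry the k = 3 nearest
neighbours observed at that sample contribute the unweighted mean of
their values. Fewer than k eligible neighbours fall back to all eligible
ones; none at all falls back to the analyte's observed mean (both warn).
Observed values are never altered.

**Statistics.** Group comparisons use the two-sided
Wilcoxon–Mann–Whitney test: the exact null distribution when the
combined n is at most 12 and the analyte has no ties, otherwise the
midrank normal approximation with tie-corrected variance and continuity
correction. Multiplicity is handled by Benjamini–Hochberg step-up
adjustment. Fold changes are ratios of group means on the raw intensity
scale, reported on the symmetric signed scale (ratios below 1 as the
negative reciprocal, so a halving is −2); no log transform is applied
anywhere because the upstream method operates on raw peak areas. The
95% confidence limits come from a seeded percentile bootstrap of the
mean ratio (2000 resamples by default) — the method for the limits is
not prescribed upstream, and the distribution-free bootstrap matches the
non-parametric testing choice. The signed-scale transform is monotone on
$(0,\infty)$, so percentile limits transfer directly.

## Network stage: numerical choices

**Soft power.** `pick_soft_power()` implements the scale-free topology
criterion: for each candidate $\beta$ it bins connectivities, regresses
$\log_{10}$ frequency on $\log_{10}$ mean bin connectivity, and returns
the smallest $\beta$ whose signed fit $-\mathrm{sign}(slope) \cdot R^2$
reaches 0.80 (argmax with a warning otherwise; degenerate constant
connectivity returns the conventional default 6). The *pipeline default*
however is a fixed $\beta = 6$, the canonical unsigned-network default:
module-structured data is not scale-free, and on such data the first
$R^2 \geq 0.8$ crossing routinely lands at $\beta = 2\text{–}4$, too low
to suppress background correlation ($\mathbb{E}|r|$ for unrelated
analytes at 24 samples is ≈ 0.16; $0.16^6 \approx 2\times10^{-5}$ kills
it, $0.16^3 \approx 4\times10^{-3}$ does not). `beta = "auto"` restores
the criterion.

**Module detection.** Average linkage is monotone, so every dendrogram
branch's internal cohesion equals its own merge height. The branch cut
declares a branch a module when (a) it has at least `min_module_size`
(20) members, (b) its height is at most `cut_height` (0.99), and (c) it
is *separated*: the height at which it joins the rest exceeds its own
height by a gap set via `deep_split` (0–4 → 0.05, 0.03, 0.02, 0.01,
0.005; default 2 → 0.02). A qualifying branch is accepted only if
neither child qualifies on its own, so nested separated structure splits
as deeply as the gap supports; chains of mutually unrelated analytes
accrue height in tiny increments, never open a gap, and stay grey
(unassigned). This is a simplified dynamic tree cut — the reference
hybrid branch-shape algorithm is intentionally not reimplemented; the
simplified cut satisfies the same contracts (perfect block recovery,
all-grey on structureless input, planted-module recovery) and its
sibling over-splits are healed by the next stage.

**Merging and refinement.** Modules whose eigengenes correlate above
$1 - \texttt{merge\_cut\_height}$ (default 0.25 → cor 0.75) are merged
iteratively. Then a module-membership (kME) refinement reassigns every
analyte to the module whose eigengene it best correlates with in
absolute value, provided $|\mathrm{kME}| \geq$ `kme_min` (0.5), else
grey, iterated to a fixed point (≤ 3 rounds). The 0.5 threshold sits
above the null 97.5% bound for 24 samples (≈ 0.42) while genuine module
members in data of this kind sit at ≥ ≈ 0.75. Modules are labelled by
the conventional colour sequence in decreasing size order (ties break by
smallest member id); `grey` is reserved for unassigned analytes.

**Eigengenes.** The eigengene is the sample-score vector of the leading
singular direction of the row-standardised member submatrix, unit norm,
oriented to correlate positively with the module's mean analyte profile
(the singular vector's sign is otherwise arbitrary, and a fixed
convention is required for reproducible outputs). Variance explained is
$d_1^2/\sum d_k^2$.

**Design association.** Each eigengene is correlated with the diet
indicator and the exercise indicator (Pearson, with correlation-test
p-values), and a two-factor fixed-effects model supplies an interaction
p-value; BH adjustment runs across modules within each factor, and a
module is flagged of interest when any factor's q-value is below
`alpha` = 0.05. The upstream work selected its modules of interest from
an eigengene display without naming a test; a formal indicator
correlation + two-factor decomposition is the smallest testable
replacement. Over-representation of module members in user-supplied GMT
sets uses the upper-tail hypergeometric p with BH across sets — a
generic stand-in for proprietary pathway tooling, which is out of scope.

## The synthetic cohort: what it emulates

`simulate_cohort()` states the world the pipeline is tested in:

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 6 | biological samples per diet × exercise cell (four groups) |
| `n_qc` | 16 | pooled-QC injections: 10 lead-in + 1 per 6 biological + 2 closing |
| `n_transcripts` | 2000 | transcriptome size |
| `n_metabolites_pos`/`_neg` | 600/600 | features per ionisation mode |
| `n_modules` | 6 | planted modules spanning all three datasets |
| `module_size_range` | (25, 35) | analytes per module per dataset |
| `diet_effect` | 2 | latent activity shift in HFD for the diet module |
| `exercise_effect` | 1.5 | latent shift post-exercise for the exercise module |
| `loading_range` | (0.6, 1) | absolute analyte loadings, sign random |
| `noise_sd` | 0.5 | analyte-level residual SD, latent scale |
| `qc_rsd_range` | (2, 30)% | per-feature target technical RSD |
| `detection_quantile` | 0.05 | left-censoring quantile, metabolome only |
| `mcar_rate` | 0.02 | additional random missingness, metabolome only |

Module activities are per-sample latent variables:
$\mathrm{act}_{ms} = \delta_d \cdot [\mathrm{HFD}] + \delta_e \cdot
[\mathrm{post}] + \varepsilon_{ms}$, $\varepsilon \sim N(0,1)$, with
the shift applied only to the responsive module for that factor. The
first module is diet-responsive and the second exercise-responsive;
the remainder are neutral. (Two modules sharing a trait would share
their shift and be observationally confounded — the design mirrors the
one-diet-module / one-exercise-module structure the method is meant to
expose.) Analyte latents are
$\ell \cdot \mathrm{act} + N(0, \texttt{noise\_sd})$ with signed
loadings $\ell$.

Intensities are lognormal: per-analyte base magnitudes are drawn around
dataset-typical levels (spread 0.5 natural-log units — a deliberate
compression of real assays' dynamic range, without which raw-intensity
variance ranking would be dominated by abundance rather than biology),
and the latent value enters through a global gain of 0.4 log units per
latent unit. The gain puts analyte CVs at a realistic 20–70%; mapping
latent units 1:1 into log-intensity would imply CVs of several hundred
percent, and the exponential transform would then distort Pearson
correlations badly enough to break module recovery on the raw-intensity
scale the method prescribes. The gain changes no latent correlation, no
rank statistic, and no QC/censoring behaviour.

Pooled-QC columns are the per-feature biological mean perturbed by
multiplicative noise whose log-SD is calibrated so the realized RSD
targets a per-feature draw from `qc_rsd_range`; with the 20% filter
threshold inside that range, roughly a third of features fail QC, which
is the attrition the module sizes are dimensioned against: planted
modules must still exceed `min_module_size` = 20 after QC (~36% loss)
and top-20% variance selection (~40–50% loss), which (25, 35) per
dataset guarantees with margin (measured post-attrition sizes 29–62).
Missingness is metabolome-only and censoring-dominant: values below the
per-feature `detection_quantile` of biological intensities are removed
(a detection-limit mechanism), then `mcar_rate` entries at random.

Ground truth (partition, traits, latent activities, QC targets) is
written to sidecar files that no analysis stage reads. Each dataset
draws from its own random stream derived from the master seed, so
resizing one dataset leaves the others bit-identical.

**What the generator does not emulate:** chromatographic drift and batch
effects, correlated (structured) missingness, adduct/isotope redundancy
among features, count-like sampling noise in RNA-seq, and real assays'
full dynamic range. A green recovery test therefore establishes that the
pipeline recovers planted co-variation structure under realistic noise,
censoring and technical-replicate behaviour — not that it is robust to
acquisition artefacts the generator does not model.

## Evaluation

Recovery is scored by: adjusted Rand index between detected and planted
labels over analytes assigned by both (planted background and grey are
excluded, since background analytes have no module identity — including
them would conflate structure detection with noise rejection, which is
reported separately as the *background rejection* rate); per-module
purity; eigengene fidelity (best absolute correlation between each
detected eigengene and any planted activity); and trait-assignment
accuracy (flagged factor vs the flagged module's dominant planted
trait).

## Known limitations

* The branch-cut gap is an absolute dissimilarity difference; extremely
  shallow dendrograms (all heights within the gap) yield all-grey
  partitions by design.
* Percentile-bootstrap limits with n = 6 per group are coarse (at most
  $\binom{11}{6}$ distinct resample means); they are honest about
  sampling noise but should not be over-read.
* The exact Wilcoxon path refuses ties entirely; heavily tied data
  always takes the corrected approximation.
* Unsigned networks conflate correlated and anti-correlated members by
  construction; `network_sign = "signed"` is available but not the
  default, matching the method being generalised.
* With 24 samples, eigengene-design correlations have sampling SD ≈ 0.1;
  realized flags for moderate effects vary across cohort draws even
  when detection is perfect.
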