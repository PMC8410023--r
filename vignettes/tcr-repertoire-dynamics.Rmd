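---
title: "Models and methods behind tcrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdyn)
```

`tcrdyn` quantifies T-cell receptor β-chain repertoire dynamics in
hematopoietic-cell-transplant cohorts. This vignette explains the
statistical model behind each stage, the tunable parameters and their
defaults, what the bundled synthetic-cohort generator does and does not
emulate, and the numerical and design choices a maintainer should know
about.

## Clonotypes and depth

The unit of observation is the *genomic template*: one sequenced DNA
molecule carrying a V(D)J rearrangement. A *clonotype* is the set of
templates sharing a CDR3 amino-acid sequence. Keying clonotypes at the
amino-acid level (rather than nucleotide, or amino-acid plus V gene) is
a deliberate choice: specificity annotation operates on amino-acid
CDR3s, and convergent recombination — distinct nucleotide
rearrangements encoding the same CDR3 — is biologically one specificity,
so their template counts are summed. The aggregation functions accept
`key = "aa_vgene"` for sensitivity analyses; nucleotide-level identity
is not offered because every downstream statistic here is defined on
amino-acid tags.

Only *productive* rearrangements enter clonotype tables: in frame and
free of stop codons. Out-of-frame and stop-containing rearrangements
are real sequencing observations but not expressed receptors.

Every diversity statistic depends strongly on sequencing depth, so
cross-sample comparisons are made at a *common depth*: the minimum
total template count among samples passing a floor (`min_acceptable`,
default 5420 templates, a conventional lower bound for this assay
family below which richness estimates degrade). Each retained sample is
subsampled **without replacement** to that depth — the multivariate
hypergeometric law — because reducing depth is physically a subsampling
of molecules; multinomial resampling would allow a clonotype to exceed
its observed count. Each sample's draw is seeded by hashing
`(master_seed, sample_id)`, so adding or removing a sample from a
cohort never changes any other sample's normalized table. One draw per
sample is the default; averaging metrics across replicate draws is
available wherever the extra variance estimate is worth the compute.

## Expansion threshold

"Expanded" is unambiguous (more than one template), but *pathological*
expansion needs a reference. The threshold τ is derived from a healthy
reference cohort (donors plus healthy controls at the common depth):
for each reference sample, take the mean size of its expanded
clonotypes; across samples, form the t-based confidence interval of the
mean of those means; then

τ = ⌊ mean + t₍₁₋α/2, n−1₎ · SE ⌋,

with clonotypes of size strictly greater than τ called pathologically
expanded. The t construction is exact under across-sample normality and
remains safe for small reference cohorts, where a normal approximation
would be anticonservative; at reference sizes in the hundreds the two
are numerically indistinguishable. Samples with no expanded clonotype
carry no information about expansion size and are excluded with a
warning. A previously derived cutoff can be fixed with
`fixed_threshold()` instead. Hyperexpansion uses an absolute default
cutoff of 100 templates, configurable.

Clonal space occupancy partitions template space (not clonotype counts)
into nonexpanded / normally expanded / pathological fractions summing
to one. Both mean and median pathological expansion sizes are exported,
since skewed clone-size distributions make them diverge.

## Overlap and the public background

Two repertoires are compared by their shared clonotype keys. Two
coefficients are reported side by side: the classical overlap
coefficient |A∩B| / min(|A|, |B|) on clonotype sets, and an
abundance-weighted form Σ min(p_A, p_B) over shared clonotypes, which
down-weights sharing of rare clones. Both are symmetric and bounded by
[0, 1]; the count form is primary and the weighted form is reported
alongside because set-based sharing alone ignores the relative
abundance of what is shared.

Donor–recipient sharing must be corrected for *public* clonotypes —
sequences frequent enough in the population that unrelated individuals
share them. The background is estimated from all unordered pairs of
unrelated reference samples at the common depth: for each size class
(all / expanded / pathological), background = mean pairwise shared
count divided by mean per-sample richness in that class. The
denominator choice makes the statistic interpretable as a fraction of a
repertoire: an identical cohort yields exactly 1, a pairwise-disjoint
one exactly 0. Related pairs can be excluded via an explicit pair list.
The adjusted donor-derived fraction is

max(0, shared/richness_recipient − background),

floored at zero with the raw (unfloored) difference retained, so
negative sampling noise is visible but never reported as negative
sharing. The remainder of the recipient repertoire is *de novo at the
analyzed depth* — a clonotype absent from 5420 donor templates may
still exist in the donor.

## Specificity annotation

Annotation is exact string matching of CDR3 amino-acid sequences
against an aggregated reference (VDJdb/McPAS-style schemas are mapped
onto a canonical six-column form). Fuzzy matching is deliberately not
offered: edit-distance neighborhoods change counts in ways that cannot
be validated against the reference databases themselves. A clonotype
may match entries in several disease categories and is then counted in
each of them — category summaries are a per-category view, not a
partition, and the double counting is documented in the output. CMV
clonotype tracking defaults to non-normalized tables so that rare
anti-CMV clonotypes are not lost to downsampling; a flag restores
normalized-mode comparisons. Annotated fractions are
reference-version-dependent and should be read qualitatively.

## HLA evolutionary divergence

HED summarizes how different an individual's two HLA alleles are at the
peptide-binding domain, as a proxy for the breadth of the presented
immunopeptidome. For each class I locus the divergence is the mean
per-site Grantham chemical distance between the two aligned allele
sequences (gap columns excluded from numerator and denominator);
`mean_class1` averages loci A, B and C. Normalizing by aligned length
follows the convention of the method this predictor derives from; a
raw-sum mode exists behind a flag. Inputs are pre-aligned exon 2–3
protein FASTA plus a genotype table; this module does not align.
Alleles are resolved at two-field precision, and an unresolvable allele
is an error rather than a nearest-neighbor fallback — silently
substituting alleles would bias divergences unpredictably. The
Grantham distance matrix is embedded from the published 1974 table
(composition/polarity/volume composite scaled to mean 100); the test
suite asserts symmetry, zero diagonal and published spot values. The
FASTA shipped under `inst/extdata/` is a synthetic stand-in for
demonstration, not IMGT sequences.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated
against known ground truth. Its defaults describe a transplant cohort:
131 healthy controls and 14 donor–recipient pairs (a reference set of
145), per-sample depths uniform on 5420–100000 templates, and four
recipient timepoints (pre, day +30, +100, +180).

**Clone sizes** follow a truncated discrete power law
P(k) ∝ k^(−α), k = 1..max_size, the simplest heavy-tailed law in which
most clonotypes carry one template while a minority expand. Defaults
α = 3 and max_size = 100: the truncation sits at the hyperexpansion
boundary because hyperexpanded clones are a post-transplant/GVHD
feature in this design (injected via `gvhd_mode`), not a property of
healthy baselines. With α = 3 a sample's richness is ≈ 0.73 × depth and
the mean expanded-clone size ≈ 3.2, so synthetic cohorts derive τ ≈ 3.
A single power law cannot simultaneously reproduce the richness ratio
(≈ 0.9), expanded fraction (≈ 3%) and expanded-clone mean (≈ 4.7)
reported for real normalized healthy repertoires — real clone-size
distributions are closer to a singleton-inflated mixture — and α = 3 is
the chosen compromise; consequences are listed under *Limitations*.

A repertoire draws `richness` i.i.d. sizes from this law, then
reconciles the total to the target depth exactly: surplus templates are
removed uniformly from the above-singleton excess (hypergeometric, so
every clonotype survives), deficits are added proportionally to current
size. Keys are random CDR3-like strings (C…F, length 8–20, keyspace
large enough that accidental collisions are below 10⁻⁶ per cohort).

**Public sharing.** A cohort-wide pool of `public_pool_size` keys is
shared by construction. `public_rate` (default 0.009) is defined as the
*expected pairwise shared fraction between unrelated samples at the
analysis depth*; the per-sample pool-inclusion probability is
calibrated as q = √(rate · richness / (pool · s)), where s is the
analytic probability that a clonotype survives downsampling to the
analysis depth. Defining the parameter at the analysis depth keeps it
identifiable after normalization regardless of raw sample depth.

**Carry-over.** Each recipient timepoint inherits
`carryover_fraction` (default 0.025) of its clonotypes from the donor's
non-public keys (inflated by 1/s_donor for sampling loss), with
recipient sizes rank-correlated to donor sizes through a Gaussian
copula (default ρ = 0.5). Drawing carry-over from non-public donor
clones keeps the graft and public channels statistically independent,
so ground truth is identifiable: expected measured sharing decomposes
as carryover + public, and background subtraction recovers the
carry-over fraction. The pre-transplant sample is the recipient's own
immune system: no carry-over, no spikes.

**Post-transplant course.** Timepoint effects default to richness
multipliers 1 / 0.9 / 0.85 / 0.8 and 0 / 20 / 30 / 50 injected
pathological expansion spikes (sizes uniform on 8–40 templates at
analysis scale) for pre / d30 / d100 / d180. Spike sizes are a
construction guarantee: their templates are budgeted first and the
baseline repertoire is fitted into the remainder, so spikes are never
eroded by the depth constraint. `gvhd_mode` adds hyperexpanded clones
(150–600 templates). Specificity labels are applied per key at
per-category rates (defaults: pathogen 4% with 40% of those CMV, cancer
1%, autoimmune 0.8%, allergy 0.4%), and the synthetic reference holds
exactly the labeled keys plus decoys absent from every sample.

All randomness flows from one `master_seed` through per-purpose hashed
seeds, so cohorts are byte-reproducible and insensitive to the order in
which samples are generated.

**What the generator does not emulate:** V/J gene usage and generation
probability; nucleotide-level convergence; longitudinal persistence of
individual de novo clones between timepoints (each timepoint's de novo
compartment is drawn fresh); age, CMV-serostatus or conditioning
effects on diversity; HLA-linked repertoire biases. Tests passing on
synthetic cohorts therefore validate the *estimators* (that the
pipeline recovers the parameters the data were built with), not the
biological realism of any particular parameter value.

## Numerical choices and degenerate inputs

- Clonotype tables are stored sorted by decreasing size with ties
  broken lexicographically by key, so rank-based statistics and all
  on-disk outputs are deterministic.
- Downsampling refuses to upsample; depth equal to the sample depth is
  the identity.
- ISI is undefined on empty tables (error, not NA); a monoclonal sample
  gives exactly 1.
- Threshold derivation needs at least two usable reference samples;
  zero across-sample variance collapses the CI to the mean.
- Spearman size correlation needs ≥ 3 shared clonotypes and returns NA
  with a warning when either margin is fully tied.
- Fold changes against a zero reference count are NA with a warning,
  never Inf.
- Sequence divergence errors on length mismatch and on all-gap overlap.
- RNG is pinned to Mersenne-Twister with rejection sampling inside all
  seeded operations, and the caller's `.Random.seed` is always
  restored.

## Validation scale

The test suite and `scripts/acceptance.R` exercise the pipeline on
scaled cohorts chosen to keep a full run in minutes on one CPU: unit
fixtures of tens of clonotypes with brute-force oracles; statistical
checks at depth 3000 per sample (50 pairs per carry-over value for
recovery, 100 seeded runs for the post-transplant trajectory); and an
acceptance cohort of 40 healthy controls plus 14 pairs at depths
5420–20000 normalized to 5420. The same code paths run unchanged at
full cohort scale.

## Limitations

- The power-law compromise above means synthetic cohorts derive τ ≈ 3
  rather than the ≈ 5 typical of real normalized cohorts, and their
  pathological occupancy fractions are correspondingly higher; the
  threshold *rule* is validated exactly, the *value* is
  distribution-dependent.
- The public background model treats pool membership as independent
  across samples; real publicity is graded (generation-probability
  driven) and age-structured.
- Specificity annotation is exact-match only, and annotated fractions
  inherit every bias of the reference databases.
- HED is only as good as the allele alignment provided; the package
  ships no IMGT data.
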