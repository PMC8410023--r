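# tcrdyn

Quantitative analysis of TCRβ CDR3 clonotype repertoires around
allogeneic hematopoietic cell transplantation (allo-HCT).

After allo-HCT the recipient's T-cell compartment is rebuilt from the
graft. Tracking how diverse the new repertoire is, how much of it is
clonally expanded, and how much of it is actually donor-derived requires
a chain of carefully normalized comparisons: repertoires sequenced at
different depths are not directly comparable, clonotype sharing between
*any* two people is non-zero ("public" clonotypes), and "expanded" needs
a data-derived definition. `tcrdyn` implements that chain for analysts
working with ImmunoSEQ- or AIRR-style rearrangement tables:

- **Ingestion** — productive-only filtering (in-frame, no stop codon),
  aggregation of convergent rearrangements into amino-acid CDR3
  clonotypes with template counts.
- **Depth normalization** — every sample subsampled without replacement
  (multivariate hypergeometric) to the cohort's lowest acceptable depth,
  with per-sample seeds derived from one master seed.
- **Diversity and expansion metrics** — richness, Inverse Simpson Index
  `ISI = 1 / Σᵢ pᵢ²`, expanded (> 1 template), pathologically expanded
  (> τ), and hyperexpanded (> 100) clonotype counts, and clonal space
  occupancy. The cutoff τ is derived from a healthy reference cohort as
  the floor of the upper 95% t-CI of the across-sample mean size of
  expanded clonotypes.
- **Donor–recipient overlap** — shared clonotypes, the overlap
  coefficient `|A∩B| / min(|A|,|B|)` and its abundance-weighted form
  `Σ min(p_A, p_B)`, and the recipient shared fraction corrected by the
  public background estimated from all unrelated reference pairs.
- **Specificity annotation** — exact CDR3 matching against aggregated
  VDJdb/McPAS-style references, per-pathology summaries, longitudinal
  tracking (CMV tracking conventionally on non-normalized tables).
- **HLA evolutionary divergence (HED)** — per-locus mean Grantham
  distance between the two class I allele peptide-binding domains and
  the individual's mean class I HED.
- **Synthetic cohorts** — a generator for healthy-control, donor and
  longitudinal recipient repertoires with known ground truth (carry-over
  keys, public pool, expansion spikes, specificity labels), used
  throughout the test suite.

## Worked example

```r
library(tcrdyn)

cfg <- cohort_config(n_hc = 10, n_pairs = 3, depth_law = c(5420L, 12000L),
                     master_seed = 42L)
cohort <- generate_cohort(cfg)
tables <- c(cohort$hc, unlist(lapply(cohort$pairs, function(p)
  c(list(p$donor), unname(p$recipient))), recursive = FALSE))

depth <- determine_common_depth(tables, min_acceptable = 5420)
norm  <- downsample_cohort(tables, depth, master_seed = 1)
refset <- Filter(function(t) t$group %in% c("healthy_control", "donor"),
                 norm$tables)

(th <- derive_threshold(refset))
#> <expansion_threshold> tau = 3 (upper 95% CI of mean expanded-clone
#> size: 3.059; reference mean 2.958 over 13 samples)

(bg <- public_background(refset, th))
#> <public_background> over 78 unrelated pairs: all 0.0087,
#> expanded 0.0013, pathological 0.0003

donor_recipient_overlap(norm$tables[["R_01_d30"]], norm$tables[["D_01"]],
                        bg, th)
#> <overlap_result> R_01_d30 vs donor D_01: 140 shared clonotypes,
#> OC(count) 0.0349, OC(weighted) 0.0248,
#>   recipient shared fraction 0.0349 (adjusted for public background:
#>   0.0262)
```

Reading: a month after transplant, 3.49% of this recipient's clonotypes
are also found in the donor; 0.87% would be expected between two
unrelated individuals at this depth, so ~2.6% of the repertoire is
attributable to the graft (this cohort was simulated with a 2.5%
carry-over fraction). Per-sample metrics come from `compute_metrics()`:

```r
compute_metrics(norm$tables[["R_01_d30"]], th)
#> richness 4016, n_expanded 612, n_path_expanded 124, isi 1190.4,
#> occ_pathological 0.206
```

`run_pipeline()` chains all stages (ingest/simulate → normalize →
threshold → metrics → overlap → annotate → HED) and writes one TSV per
stage plus a deterministic run manifest; see `?run_pipeline` and the
vignette in `vignettes/` for the underlying model and parameter choices.

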