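---
title: "Models and methods behind cranioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cranioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(cranioscan)
```

cranioscan maps quantitative trait loci (QTLs) for skull shape in dog breeds
and prioritizes candidate causal variants inside the mapped intervals. This
vignette explains the statistical models behind each stage, the tunable
parameters and their defaults, the numerical conventions, and what the
bundled synthetic-data generator does and does not emulate. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The study design in brief

Breed standards make purebred dogs phenotypically uniform: a handful of
skulls can stand in for a breed's skull shape, and a genotyped dog can carry
its breed-sex average phenotype ("breed-stereotype" mapping). The pipeline
therefore runs:

1. landmark morphometrics → allometry-corrected shape principal components
   → breed-sex averages;
2. a kinship-corrected mixed-model genome scan of those averages over
   individual dogs;
3. selection scans (observed heterozygosity and F~ST~ in ten-SNP windows)
   contrasting brachycephalic against dolichocephalic breeds;
4. haplotype-sharing critical intervals, refined by two-genome allelic
   agreement;
5. multi-criteria variant filtering plus codon-consequence annotation in
   the refined interval.

## Morphometrics

**Merging dual views.** Dorsal and ventral landmark sets are digitized
separately on the same physical skull. `merge_views()` fits the
least-squares rigid transform (rotation + translation, *no scaling*, since
scale is shared by construction) on the landmarks present in both views
(defaults: ids 1, 2, 28, 29) and maps the ventral configuration into the
dorsal frame; shared landmarks take the average position and the RMS
discrepancy is reported. Fewer than three shared landmarks, or a
(near-)collinear shared set, leaves the transform unidentified and is an
error.

**Superimposition.** `gpa()` performs full generalized Procrustes analysis:
configurations are centred, scaled to unit centroid size, rotated to the
current consensus, and the consensus is re-estimated until its change is
below `1e-10` (at most 100 iterations). Centroid sizes — and neurocranium
centroid sizes over a user-supplied landmark subset — are recorded before
scaling. Because a Procrustes fit is only defined up to a global rotation,
the consensus is put into a canonical orientation (principal axes, with
signs fixed by a landmark-index-weighted functional chosen for stability
under small perturbations); this makes the fit invariant, to numerical
tolerance, to arbitrarily rotating, translating, or rescaling any input.
Specimens with missing landmarks are excluded with a warning rather than
imputed, since no imputation rule is defensible for museum material of this
kind. The anatomical membership of the neurocranium subset is a
configuration input, not a package constant: the generator defines its own
subset, and real analyses must supply theirs.

**Allometric correction.** Shape varies with size. The allometric component
is estimated by *pooled within-group* regression of the superimposed
coordinates on log neurocranium centroid size: breed-sex group means are
removed from both sides, a common slope vector is estimated from the
within-group variation, and significance comes from permuting size within
groups (default 10,000 permutations; the `(b + 1)/(n_perm + 1)` estimator
keeps p away from zero). Residuals retain between-group shape differences:
`residual = (shape − grand mean) − slope · (size − grand mean size)`. When
every breed-sex cell is a singleton there is no within-group variation; the
implementation falls back to pooling by breed, with a warning.

**Shape space.** `shape_pca()` eigendecomposes the specimen-level
covariance of the residuals. Whether the original analysis weighted
breeds in the covariance is unknowable from the text; specimen-level is
implemented, which weights well-sampled breeds more. Loading signs follow a
fixed convention (the largest-magnitude entry positive) for
reproducibility. `morph_along_pc()` reconstructs `mean + c · loading` for
display, and `breed_sex_average()` collapses scores to the mapping
phenotype, passing single-specimen cells through unchanged.

## Association

**Design.** Each genotyped dog carries its breed-sex average PC score and
log size covariate (`assign_phenotypes()`). The unit of analysis stays the
individual dog, mirroring the original pairing of genotype panels with
breed-average phenotypes. When a dog's own sex has no phenotype row the
default is to drop the dog; an opposite-sex fallback exists but is off by
default, since how the original analysis handled one-sex breeds is not
stated. Sex is not a covariate — the phenotype is already sex-averaged.

**Marker QC.** Strict thresholds: missingness `< 0.10`, minor allele
frequency `> 0.01`.

**Linear scan.** Per-marker OLS with a two-sided Wald *t* test; dogs
missing a call are dropped marker-wise; a constant phenotype yields p = 1
and a constant marker is undefined.

**Mixed model.** `lmm_assoc()` fits `y = Wα + xβ + u + ε` with
`u ~ (0, σ²_g K)` and `K = ZZ'/m` the centred genomic relationship matrix
(missing dosages mean-imputed inside `K` only). `K` is eigendecomposed
once; the restricted likelihood is profiled over the variance ratio
`σ²_g/σ²_e` by bounded 1-D search (log10 ratio in `[−5, 5]`, tolerance
`1e-6`) under the covariate-only model, and each marker is then Wald-tested
by GLS at that ratio. REML rather than ML is used (standard for variance
components; the original tool's setting is unstated), and re-profiling per
marker is available via `per_marker = TRUE`. Markers with missing calls are
tested on the called subset through a Cholesky factor of the corresponding
submatrix of the marginal covariance, honouring marker-wise dropping
without re-eigendecomposition. X-chromosome dosage is treated like an
autosome — a documented limitation, matching how the mapped X hits were
reported without a special model.

**Thresholds and strata.** `bonferroni_threshold(alpha, m) = −log10(α/m)`.
Note one arithmetic subtlety: at the published "~36,685 markers" the value
is 5.8655, which the source prints truncated as 5.86. `stratify()`
implements the three published sensitivity designs: keep breed-sex rows
strictly below the median log size; drop a named breed list; or drop
"extreme brachycephalic" breeds, defined as breeds whose breed-sex PC1
averages all exceed 0.15.

## Selection scans

`obs_het()` is the fraction of heterozygous calls among non-missing calls
per marker within a breed population. `log_h_ratio()` contrasts
dolichocephalic over brachycephalic H~O~ on a log10 scale (the base is a
package choice — the source says only "log" — and is configurable); the
default pseudocount is 0, with zero denominators flagged undefined rather
than papered over. `fst()` defaults to the Hudson two-population estimator
computed from sample allele frequencies and allele counts, chosen for its
robustness to unequal sample sizes (the source names no estimator); a
Nei-type estimator is available. Values are clipped to `[0, 1]` and
markers monomorphic in both populations are undefined. Whether the
original F~ST~ contrast was brachy-versus-rest or brachy-versus-dolicho is
ambiguous; both are supported — the pipeline stage uses the brachy
subpopulation against all remaining dogs.

`sliding_windows()` averages defined values over ten-marker windows
(step 1, both configurable), never spanning chromosomes and flagging
windows with more than 20% undefined markers. `percentile_flags()` ranks
windows by mid-rank against the genome-wide distribution of their
statistic and flags a tail fraction counted from the relevant end; with
`n` windows and fraction `f` exactly the `f·n` most extreme distinct
values flag, and an all-tied distribution flags nothing. The published
flags are the top 5% for F~ST~ and the lowest 0.2% for the H~O~ ratio.

## Haplotype intervals

`em_phase()` estimates haplotype frequencies per breed by
expectation–maximization over the full `2^m` haplotype space of a small
marker window (cap 12 markers; convergence when the largest frequency
change is below `1e-8`, at most 500 iterations; haplotypes below `1e-6`
pruned). This deliberately does *not* re-implement the original
cluster-based phasing engine: the scientific contribution downstream is the
interval logic, and the EM phaser (or externally phased input) feeds it
equivalently. The test suite checks the EM solution against direct numeric
maximization of the marginal likelihood.

`shared_interval()` takes each target breed's common haplotypes (default
within-breed frequency ≥ 0.2, so that low-frequency phasing noise cannot
break the shared run) and reports the maximal run of consecutive markers
at which all contributing haplotypes agree, as the positions of its first
and last marker, leftmost on ties. `refine_breakpoint()` scans two genomes
across the interval in ascending position and truncates at the last
agreeing genotype before the first disagreement — heterozygous versus
homozygous counts as disagreement, missing calls are skipped. One
convention had to be pinned: the source describes disagreement "downstream
of" one coordinate while its refined interval ends one base later; the
implementation reports the last agreeing *marker position* as the
endpoint. Intervals are 1-based inclusive internally; BED export converts
to 0-based half-open. `confirm_breakpoint()` is a pure tabulation of a
genotyping panel's support for the interval haplotype.

## Variant filtering

The filters mirror the published criteria, each with its boundary
convention made explicit because the source is internally inconsistent:

* `mask_gq()`: per-sample genotypes with quality strictly below 8 become
  missing (the methods text says "below 8", one table says "≤ 8"; strict
  is the default and the boundary is configurable).
* `variant_assoc()`: additive OLS of a per-genome phenotype on dosage over
  the small panel, omitting listed outlier samples; the `associated` flag
  marks p-values in the smallest 5% by mid-rank, with the denominator
  being the variants evaluable after masking (the source does not state
  its denominator).
* `conservation_filter()`: conservation score ≥ 0.7 (the figure legend's
  "≥" is followed where the methods text says "above"); absent scores are
  never flagged.
* `gene_context_filter()`: exonic means inside any exon, inclusive
  endpoints, UTRs count; splice-adjacent means 1–20 bases from an
  *internal* exon boundary on the intronic side — outer gene edges are not
  splice junctions.
* `combine_filters()`: a variant is of interest when it lies inside the
  active interval AND meets at least one criterion; counts per criterion
  are reported. The count is monotone non-increasing as any threshold
  tightens.

`annotate_codon_change()` maps a genomic position through the exon model
(respecting strand), substitutes the alternate base, and translates both
codons with the standard genetic code, reporting e.g. `F452L` /
`Phe452Leu`, synonymous, or stop gain.

## The synthetic-data generator

No genotype or landmark data are deposited with the source study, so the
generator builds datasets with the statistical structure the analysis
assumes; its defaults are the study conditions, not tuning knobs.

* **Breeds and drift.** 60 breeds × 8 dogs (close to the 62 breeds / 576
  dogs genotyped), 10 chromosomes × 150 markers, Balding–Nichols drift
  with `F = 0.2` per breed around uniform ancestral frequencies; an
  optional two-level hierarchy creates breed clades.
* **Trait-selected QTLs.** Five QTLs, one per chromosome. The mapped system
  is breeds under strong artificial selection on skull shape, with sweeps
  and near-fixation at the QTLs; the generator reproduces this by giving a
  "selected" group (10 breeds, mirroring the ten-breed brachycephalic
  contrast set) QTL allele frequencies concentrated near 0.9 while all
  other breeds drift around an ancestral 0.2. This trait-correlated
  differentiation is what makes breed-average mapping able to reach
  genome-wide significance at ~60 breeds at all; with independent
  per-breed drift at five equal QTLs, each QTL's share of breed-level
  variance is bounded near 20% and no threshold crossing could be
  expected.
* **Trait.** Breed trait = Σ effect × breed mean QTL dosage (+ breed
  effect, sd 0.3; + noise, sd 0.05); both sexes share the value.
* **Landmarks.** A deterministic bilaterally symmetric 51-landmark
  template (17 midline, 17 left/right pairs); specimens are the template
  plus trait × a rostrum-shortening/palate-widening deformation axis
  (0.5 mm per trait unit), an allometric dorsoventral axis scaled by the
  specimen's log-size deviation, and isotropic 0.2 mm digitizing noise,
  all scaled to the specimen's size. Log size varies 8% between breeds,
  6% within breed-sex cells (individual adult variation — also what makes
  the pooled within-group slope identifiable), runs slightly smaller in
  high-trait (brachycephalic) breeds to emulate the size confound, and
  males run 5% larger. Deformation is linear in the trait; nonlinear
  growth is out of scope.
* **Sweep.** Within ±5 markers of the first QTL, each selected-breed
  chromosome is replaced by the derived haplotype with probability 0.95,
  otherwise re-drawn from the breed's pre-sweep frequencies.
* **Resequencing panel.** 452 variants over the published 85.7 kb
  interval coordinates for 11 genomes (4 brachycephalic including
  Pekingese and Bulldog, a dolichocephalic outlier, 6 others); exactly 8%
  of genotype calls get qualities below the masking threshold; ~15% of
  positions are conserved at ≥ 0.7; a two-gene exon model with one gene
  fully inside the interval; and one planted causal variant — a C→A at
  the third base of the TTC codon 452 of the interior gene, conservation
  0.95, carried homozygous only by the brachycephalic members and the
  outlier (whose carrier status is exactly why the published analysis
  excluded it from the association filter).

Everything is drawn from integer-offset seeds of one master seed, so
identical config + seed is bit-reproducible and each stage is individually
reproducible.

**What passing tests do and do not show.** The generator has no linkage
disequilibrium decay, no recombination map, no ascertainment bias in the
marker panel, no measurement error structure beyond isotropic noise, and
its QTL architecture is planted rather than inferred. Tests on it
demonstrate that the estimators are implemented correctly and behave as
designed under the assumed structure — not that the pipeline would recover
this biology from arbitrary real data.

## Orchestration

`run_pipeline()` executes simulate → morpho → gwas → sweep → interval →
filter with plain-file handoff (CSV/TSV/PED/VCF/GFF3/bedGraph) in a working
directory, so every stage is independently re-runnable and inspectable;
completed stages are skipped on re-run, a missing upstream file fails
naming the stage, and a manifest records the config hash, seed, package
version, and outputs. The package is a library: the exported functions are
the command surface (one function per stage), and `scripts/acceptance.R`
shows fully scripted use.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
properties sharp while keeping a full run around a minute on one core:
morphometric recovery on 240 specimens × 51 landmarks; mixed-model
calibration on 480 dogs × 2,000 markers (type-I error within
[0.035, 0.065] at nominal 0.05); five-QTL recovery and sweep detection
over 20 seeded replicates each at full generator defaults; permutation-p
uniformity over 500 null datasets at 99 permutations; EM phasing against a
direct likelihood-maximization oracle on 2–4 marker windows; and the
single-QTL top-marker experiment over 12 seeded replicates.

## Known limitations

* The mixed model fixes the variance ratio at its null-model REML estimate
  per scan (per-marker re-profiling is optional and slower).
* Genotype dosage on X is modelled like an autosome.
* The EM phaser is exponential in window width (capped at 12 markers); it
  is a window-local tool, not a genome-wide phaser.
* The generator's within-cell allometric signal is weak relative to
  digitizing noise, as in small museum series; the allometric slope is
  then noisy, which the downstream PCA tolerates (the recovery property
  is tested) but single-dataset allometry tests on generator output are
  underpowered.
* Indel consequences, PolyPhen/PSSM scoring, read alignment, and variant
  calling are out of scope; the filters consume variant tables and
  precomputed annotations.
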