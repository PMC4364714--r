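---
title: "Models and methods behind gutcrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gutcrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcrest)
```

gutcrest analyses a transgenic insertional mouse model of male-biased
aganglionic megacolon: a concatemer of two co-injected transgenes landed in
a chromosome-10 gene desert, flanked by a target-site duplication, and the
homozygous animals show incompletely penetrant, strongly male-biased
intestinal obstruction caused by slowed enteric neural crest cell (eNCC)
migration. This vignette documents the models the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was open.

## Insertion architecture from paired-end reads

### The generative model

`build_insertion_allele()` constructs a mutant allele as

```
host[1 .. s+d-1] + array + host[s .. L]
```

where the duplicated segment `host[s .. s+d-1]` (default d = 26 kb) appears
once on each side of the array — the hallmark of a target-site duplication.
The array interleaves the transgene units (equimolar co-injection), by
default two 7 kb units at 50 copies each, i.e. 700 kb per allele. All
coordinates in the package are 1-based and inclusive, the R/Bioconductor
convention; nothing needs shifting when SAM is written.

`simulate_paired_reads()` samples fragments uniformly from the allele
copies (two mutant copies for a homozygote; mutant plus reference for a
heterozygote). Fragment lengths are Gaussian with mean 400 bp and sd 35 bp
— the middle of a 300–500 bp library — truncated by redraw to
[2·read length, 2·mean]. The pair count is
`coverage × total length / (4 × read length)`, and each fragment emits a
forward read at its start and a reverse read at its end. Reads are
assigned their truth alignment from the allele's segment map: a read fully
inside a host segment (including either duplication copy) maps to the host
chromosome, a read fully inside one array unit maps to that unit's contig,
and a read straddling a segment junction is emitted unmapped while its
mate keeps its assignment. Junction evidence is therefore purely
pair-level (host–transgene chimeric pairs); soft-clipped, base-exact
breakpoints are deliberately out of scope, as the inference downstream
uses pair mapping only.

The generator does **not** emulate sequencing-quality structure (qualities
are uniform), indel or chimeric-library artefacts, GC-coverage bias,
mappability variation, or a real aligner's mismapping around repeats.
Passing tests therefore demonstrate the *inference arithmetic* on clean
pair-level evidence, not robustness to alignment noise; externally aligned
SAM can be supplied to the same functions via `read_sam()`.

### Inference

* `compute_depth()` counts mapped read starts in fixed windows (default
  1 kb) and normalizes by the median count over host windows — a baseline
  robust to the duplication itself occupying a small fraction of the host.
  Because both mates of a pair start within a fragment length of each
  other, window counts have roughly twice-Poisson variance; at 30× the
  per-window noise is a few percent.
* `detect_duplication()` reports maximal runs of windows with normalized
  depth inside [1.3, 2.7] and length ≥ 10 kb (both configurable; the
  minimum-length default sits well below the 26 kb signal and well above
  single-window noise). Zygosity follows diploid copy arithmetic: depth
  ≥ 1.75 → duplicated on both alleles (4/2 copies), otherwise → one
  (3/2). Calls snap to window boundaries, so the duplication length is
  resolved to ± one window.
* `call_junctions()` clusters host-side mates of chimeric pairs by strand:
  forward-strand host reads face the array from the left, reverse-strand
  ones from the right. The breakpoint estimate extends the innermost host
  coordinate of a cluster by half the mean inner gap,
  `(insert mean − 2·read length)/2`. With dense support the innermost
  coordinate already abuts the breakpoint, so the offset over-extends by
  up to ~100 bp; the bias is well inside the reported ±2·insert-sd
  uncertainty and the one-insert-length tolerance the recovery tests use.
  Junction calls need at least 5 supporting pairs per side (at 30× the
  expectation is ~30).
* `estimate_copies_and_size()` converts transgene-contig depth into copies
  per allele (`depth × 2 / carrier alleles`). Reads crossing the boundary
  between adjacent array copies are unmapped in the truth model, so depth
  is computed over the `length − read length + 1` mappable start positions
  of a unit rather than its full length; without this correction a 7 kb
  unit would be underestimated by ~1.4%. Copy estimates are reported raw
  and rounded (ties half-up); the total size sums copies × unit length.

The study's printed outcome for this architecture — a 26 kb duplication at
twofold depth and "about 700 kb" of insertion — does not state how the
total was computed; the copy-number arithmetic above is this package's
choice, and the recovery tests hold it to within 10%.

## The megacolon tipping point

The phenotype axis is the ganglionic fraction *g*: the percentage of colon
length (from the cecum) covered by myenteric ganglia. The model is a hard
threshold: obstruction occurs systematically when *g* < *T*, with
*T* = 80% as default, and `simulate_cohort()` implements megacolon as this
deterministic rule on truncated-Gaussian fractions. Consequently
`predict_penetrance(mu, sigma, T)` is the Gaussian lower tail
Φ((T − µ)/σ): with the weaning-age defaults — males µ = 79, females
µ = 89 — males straddle the tipping point (penetrance ≈ 0.58 at σ = 5)
while females lie beyond it (≈ 0.036), reproducing a strong male bias from
a purely quantitative, sex-independent threshold. Neonate defaults are
74/90. The per-animal spread is not reported in the source material; σ = 5
percentage points was chosen once as a realistic within-sex spread
(consistent with the published scatter) and is an explicit argument.

`critical_region()` is defined exactly as the worked example's two
extremes — the longest ganglionic zone among affected animals and the
shortest among non-affected — with no smoothing or model fit. In real data
these overlap (83.6 vs 77.1); under the deterministic simulator the
affected maximum sits just below *T* and the unaffected minimum just above
it, so the interval between the two bounds always brackets *T*. Group
comparisons use `welch_t()`, the unequal-variance form of the t-test — a
robust superset of the Student's test used in the original
quantifications — with the conventions p = 1 for identical constant
groups and p = 0 for constant groups at different means.

## Migration tracks and explants

`simulate_tracks()` draws per-step headings from a von Mises distribution
(sampled with the Best–Fisher rejection algorithm, switching to the
wrapped-normal limit above κ = 500) centred on the mesentery reference
axis, and step magnitudes as folded Gaussians with the control default
speed of 0.58 µm/min (~35 µm/h). Defaults of 5-minute sampling over
3 hours and κ = 4 were fixed once as typical of directed eNCC
front-cell imaging; no distribution is named in the source, so the
concentration parameter is declared, not inferred. Tracks are consumed as
given — no re-linking of identities is attempted when leader cells
leapfrog.

"Directionality" is not formula-defined in the source figures, so
`track_direction()` reports both candidates: circular statistics of the
per-step deviations from the reference axis (circular mean and resultant
length R, computed by unit-vector averaging with zero-length steps
skipped) and the straightness index (net displacement over path length).
The circular deviation feeds the group test, matching the source's use of
a circular ANOVA: `watson_williams()` implements the Watson–Williams F
with the `1 + 3/(8κ̂)` correction, κ̂ estimated from the pooled
within-group resultant length by the standard piecewise inverse of
A₁(κ). The test assumes reasonably concentrated samples; it warns below
R̄ = 0.45 and, in the small-angle limit, its p-value converges to a
linear one-way ANOVA (verified in the tests to 5% relative).

`feret_diameter()` is the maximum caliper width — the exact maximum
pairwise distance, via the convex hull for large sets — and
`explant_summary()` applies the active-migration rule: spread strictly
greater than 200 µm, the average diameter of the intestinal slices used in
the assay. The boundary case (exactly 200 µm) is not active.

## The expression screen

The original screen ran two published NB testers and kept genes both
called at adjusted p < 0.001 with at least a 2-fold difference. This
package implements two NB schemes of its own and applies the same
consensus rule — a methodological stand-in with the study's thresholds as
defaults (2-fold genome-wide, 4-fold for the short list). Where the
running text says "p < 0.001" and the methods say "adjusted p-value
< 0.001", the methods wording wins: both schemes are Benjamini–Hochberg
adjusted.

* Size factors are DESeq-style medians of ratios to the per-gene geometric
  mean, rescaled by their median so the typical sample is exactly 1.
* **Exact scheme**: per-gene method-of-moments dispersions are moderated
  toward the common dispersion with 10 prior degrees of freedom; group
  sums of normalized counts are compared conditionally on their total
  (sums of n i.i.d. NB(µ, φ) variables being NB(nµ, φ/n)), with the
  p-value summing all split probabilities not exceeding the observed one.
  The enumeration is windowed to ±60 conditional standard deviations, so
  very highly expressed genes stay cheap.
* **LRT scheme**: per-gene dispersions are shrunk halfway toward a lowess
  mean–dispersion trend, group means are quasi-MLEs with size-factor
  offsets, and twice the log-likelihood ratio is referred to χ²₁.
* Fold change is the ratio of normalized group means; ratios below 1 are
  displayed as negative reciprocals (−1/f), matching the tables' signed
  entries. Fold changes in the packaged tables are kept verbatim — they
  are not recomputable from the printed mean raw counts because the
  original normalization factors are unpublished — and the pipeline never
  recomputes them from fixture counts.

On null simulations at the 2 + 2 design the consensus false-call rate
stays below the nominal 0.001 (the exact scheme is slightly conservative,
the LRT slightly liberal at raw level, and the intersection with the fold
filter is strict); planted 5-fold genes at mean ≥ 200 are detected at
≥ 80% power. Both properties are asserted in the test suite at 2,000–3,000
genes per replicate.

Downstream, `sex_linked_screen()` partitions a DE set into X-linked
downregulated and Y-linked upregulated genes, and
`rank_insertion_candidates()` ranks upregulated genes on the insertion
chromosome by distance to the insertion position — supplied by the user,
because the screen's published coordinate is the distance itself: the
packaged demonstration uses position 47,985,420, derived as the top
candidate's start minus the printed ~3.6 Mb, and labelled as derived.
`hypergeom_enrichment()` doubles the smaller hypergeometric tail (capped
at 1) and selects terms at ≥2-fold enrichment or depletion with BH-adjusted
p < 0.01.

### Fixture integrity

The packaged transcription of the 4-fold table is validated against the
printed tallies (41 down, 188 up, 229 total). Two upregulated entries were
lost from the available transcription of that table (its "Miscellaneous"
row is truncated mid-list); they are reinstated as placeholder rows with
`reconstructed = TRUE` and names `reconstructed_up_1/2` so the tallies are
exact while the stand-ins remain unmistakable. Genes whose printed fold is
inflated by a zero count in one sample carry `null_count_flag`. The
loaders parse the tables' decimal-comma, space-thousands dialect and
re-check row counts on every load.

## Problem sizes and limits

The test suite and the acceptance script run the insertion chain on a
2 Mb host with the full 26 kb + 700 kb architecture at 30× (~409,000
pairs, a few seconds per seed), with a 300 kb miniature used for
multi-seed property tests; cohorts use 500–10,000 animals per sex; DE
calibration uses 2,000–3,000 genes per replicate. These sizes were chosen
so the whole suite runs in about a minute while keeping every statistical
tolerance derivable from first principles.

Known limitations: the mapper assumes a single insertion locus and does
not phase the two duplication copies (reads from them are
indistinguishable; the interval is reported once); the array's internal
unit order is not assembled; penetrance inference is simulation-based (the
incidence table of the source is a figure, not machine-readable); and the
genome-wide 1,243-gene list is not reproducible at desk scale because the
raw libraries are not deposited — the screen's behaviour is instead
characterized on synthetic data with known truth.
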