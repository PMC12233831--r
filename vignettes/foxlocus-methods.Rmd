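---
title: "Models and methods behind foxlocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foxlocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(foxlocus)
```

`foxlocus` quantifies the transcriptional output of a two-promoter gene locus
(modelled on human *FOXP3*) from three data modalities: aligned direct-RNA
long reads, short-read coverage, and single-molecule RNA-FISH images. This
vignette records the models, the tunable parameters and their defaults, the
design choices made where the design was genuinely open, and what the
synthetic-data generators do and do not emulate. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates

All internal coordinates are 0-based half-open; a position `p` is inside
`[start, end)` iff `start <= p < end`. BED input is native; GTF features and
printed spans like `chrX:49264670-49264735` are 1-based inclusive and
converted on ingestion (`parse_span()`). All upstream/downstream logic runs
through a transcription coordinate (`tx_pos()`: identity on the plus strand,
negation on the minus strand), and every piece of coordinate logic is
property-tested for invariance under coordinate reflection plus strand flip
(`mirror_locus()`). The default locus is minus-strand, like *FOXP3*, with the
alternative promoter at higher genomic coordinates than the canonical one.

## Regions of probable transcription initiation

Direct RNA sequencing reads native molecules 3′→5′ and misses the last
5–15 nt of the 5′ end, and RNA decays 5′→3′, so a read's 5′ end cannot be
equated with a TSS. Following the published construction, each CAGE peak
summit is broadened by `broaden_factor` (default 5) times its positional
standard deviation on each side — asymmetric SDs are accepted as a pair —
and the interval is then translated `tech_shift_nt` (default 10, the middle
of the 5–15 nt loss range) in the direction of transcription. Reads whose 5′
end falls outside all regions are interpreted as decay products or aborted
sequencing and excluded.

Per-peak SDs are not published; when a peak carries no `sigma`, the default
is cluster width / 4 (the cluster treated as ±2σ). The two published regions
(canonical peak 1, alternative peak 1) are therefore shipped verbatim as
fixtures (`foxp3_initiation_regions()`) rather than reconstructed, and the
builder is exercised on synthetic peaks with known σ.

## Read filtering and classification

Filters apply in order, the first violated rule being recorded:
(i) 5′ end in the neighbouring gene's promoter; (ii) 5′ end outside all
initiation regions; (iii) 3′ end stopping strictly more than `utr3_min_nt`
(default 50) nt transcription-upstream of the PAS — implemented as a single
threshold position, identical semantics to the printed absolute coordinate;
(iv) retained introns or junctions not matching the annotation under an
allowed exon-skip signature (∅, Δ2, Δ7, Δ2+7; junction slack configurable,
default 0 nt because the synthetic data are exact). Alternative-promoter
reads whose 3′ end stops before the first coding exon are the *short
upstream transcript* class and are exempt from (iii)/(iv) — they terminate
early by definition, and without the exemption the class could never survive
filtering. Reads on the wrong strand are excluded as aberrant.

Classification: alternative-promoter reads reaching the terminal exon are
longFOXP3 (full-length / Δ2 / minor by skip signature); canonical-promoter
reads are canonical (fl/Δ2 by exon-2 status) unless their 5′ block matches an
alternative first-exon structure by at least 50% of the block (configurable),
which makes them *novel canonical*. Canonical reads with allowed minor skips
(Δ7, Δ2+7) collapse onto the fl/Δ2 labels by exon-2 status, since the class
set has no canonical-minor label. The abundance report uses canonical
(fl + Δ2) as the numerator of the per-replicate ratios — whether the novel
canonical transcripts belong in that numerator is not stated in the source
material; we exclude them there but include them in the pooled promoter
output ratio, which the published equation defines explicitly as
(canonical + novel) / (longFOXP3 + short upstream). Medians across an even
number of replicates are the mean of the central pair.

## Dual-modality estimator

Poly(A)-selected long reads see only adenylated molecules; rRNA-depleted
short reads see everything. Coverage over the canonical initiation region in
either modality comes from canonical transcripts plus longFOXP3 molecules
(intact or 5′-degraded) spanning it, and the long-read data count each
contribution directly:

`f = n_intact_longFOXP3 / (n_canonical_output + n_intact + n_degraded)`

"Degraded longFOXP3" is operationalized as reads excluded by filter (ii)
whose 5′ end lies between the alternative regions and the canonical region
while their alignment fully spans the canonical initiation region — exactly
the excluded reads that still contribute coverage over it. `f · C_canon`
then predicts the short-read coverage that adenylated alternative-promoter
output alone would produce over the alternative initiation region, and the
excess is attributed to non-adenylated species:

`R = (C_alt − f·C_canon) / (f·C_canon)`

Promoter-region coverage uses the mean; the cross-technology terminal-exon
anchor uses the max (the published figure quotes a coverage range). A
negative `R` is reported with a warning flag (no detectable non-adenylated
excess), never silently. The source prints the alternative-region coverage
as 272 in prose but uses 279 in the equation; the fixture stores both and
the estimator follows the equation.

On synthetic data the coverage is measured over *anchor* regions
(`synthetic_anchor_regions()`) placed ≥150 nt (one fragment length)
downstream of each promoter's TSS cluster: within the fragment-length ramp
at a transcript 5′ end, mean coverage underestimates copy number and the
estimator's read-count/coverage correspondence breaks down. The estimator
also assumes adenylated alternative output ≈ longFOXP3 (in the source data
poly(A)+ short upstream reads were 3 of 133); the recovery test therefore
plants poly(A)+ short upstream transcripts at a comparably small weight.
Under those stated conditions the estimator recovers planted ratios
ρ ∈ {1, 2, 4} within ±30% at ≥200× coverage (property-tested).

## Coding potential

ORF discovery follows the microprotein-prediction rules: AUG and CUG starts,
first in-frame stop, minimum total length 150 nt including the stop. The
Kozak scorer is an internal position-weight model over the flanking
positions −6…−1 and +4 (the start codon itself is not scored, so AUG and CUG
contexts are comparable): the vertebrate consensus `gccRccAUGG` scores 1.0,
an all-N context 0.0, with −3 (purine) and +4 (G) carrying triple weight.
Published Kozak scores for this locus come from an external web predictor
whose weights are not reproducible; they are treated as reference
annotations, not targets. Molecular weights use average (not monoisotopic)
residue masses plus one water, in kDa, matching gel-scale comparisons; the
initiator codon — including near-cognate CUG — is translated as methionine.
Proteoform categories: the main ORF; N-terminally extended proteoforms
(upstream in-frame AUG/CUG sharing the main stop); and uORFs, whose start
codon must lie in the 5′ UTR but which may overlap the main ORF.

## RNA-FISH quantification

Nuclei are primary objects: Otsu threshold on the DAPI channel, hole
filling, 8-connected labelling, watershed splitting on the exact Euclidean
distance transform (seed plateaus merged over half the minimum nucleus
diameter), and an equivalent-diameter size filter (default 10–80 px). Cells
are nuclei expanded isotropically by 3 µm — 29 px at the 104 nm pixel size —
with collisions resolved by nearest nucleus (exact Euclidean, deterministic
tie-break); cytoplasm = cell − nucleus.

Spots are enhanced by a white top-hat (structuring radius ≈ expected spot
radius, default 4 px) and thresholded at the *maximum* of the Otsu value and
a robust-background floor (median + 4 MAD of the enhanced image). The floor
is a deliberate deviation from a pure Otsu design: with diffraction-limited
spots occupying well under 1% of pixels, two-class Otsu demonstrably splits
the background mode instead of separating spots from it; on high-contrast
images the floor is inactive. Each 8-connected component above threshold is
one spot — agglomerates are deliberately counted once. A UPA spot
co-localizes when ≥ 0.3 of *its own* area is overlapped by the union of mRNA
spots (the MaskObjects convention; normalization by the mRNA spot is a
config option). Compartments are assigned by centroid-in-nucleus on the 2-D
projection, which overestimates nuclear localization — compartment fractions
are semi-quantitative by construction. Spots outside every cell are dropped.
Because the per-cell-median versus pooled convention for the co-localization
percentage is ambiguous in the source, the culture summary emits both.

## Prevalence statistics

Speckle presence is compared between two cell types with
`glm(present ~ cell_type + donor, family = binomial)` — donors enter as
reference-coded fixed effects, matching the published covariate language; no
random effects. The reported p-value is the Wald test of the cell-type
coefficient (likelihood-ratio optional). Complete or quasi-separation is
flagged, not silently reported. Pairwise tests across cell types are
Bonferroni-corrected (multiply by the number of tests, clip at 1). Rank-sum
comparisons use the exact distribution for combined n ≤ 20 without ties and
the tie-corrected normal approximation otherwise. The reporter-normalized
fold change is the printed double ratio
`(target_cond/target_ref) / (reporter_cond/reporter_ref)`.

## The synthetic world

The generators' defaults state one world and are not tuned per test:

* **Locus** — minus strand, 12 exons numbered −1 and 1…11, PAS 8 nt inside
  the terminal exon, canonical promoter with two CAGE peaks (scores
  18671 : 315, the published 59× ratio), alternative promoter with four
  peaks ~1.6 kb upstream, a neighbouring promoter beyond them, and one
  alternative first-exon structure. Exon 2 is 105 nt (35 codons, in-frame
  skippable, as for FOXP3).
* **Transcript sequences** — the background is generated T-free (A/C/G
  only), so every start and stop codon is planted explicitly and the planted
  ORF inventory is provably exact: the 5′-extended transcript carries
  exactly 5 uORFs (four in the extension, one starting in the canonical UTR
  and overlapping the main start in a different frame), 2 in-frame upstream
  starts sharing the main stop, and the main ORF. This sacrifices realistic
  base composition for exact ground truth; the ORF scanner is additionally
  oracle-tested on unconstrained random ACGU sequences.
* **Reads** — class mixture 6 : 1 : 1.5 : 0.35 (canonical : novel :
  longFOXP3 : short upstream, reproducing the published median ratios;
  canonical split 45 : 55 fl : Δ2, longFOXP3 split 37 : 56 : 7), TSS jitter
  N(0, σ_peak), uniform 5–15 nt terminal loss, PAS jitter uniform on
  {−2…+2}, log-normal poly(A) tails with modes 89 nt (FOXP3-like classes)
  and 53 nt (background), 30% of reads 5′-decayed by a geometric law (mean
  400 nt — memoryless decay; the source states no law, the parameter is
  exposed).
* **Coverage** — uniform fragment sampling (150 nt) along each species,
  projected through its exon chain; non-adenylated upstream species span the
  alternative promoter down to just above the canonical region at
  `nonadenylated_ratio` (default 4) times the adenylated upstream copies.
* **Images** — nuclei as noisy disks of radius 22–28 px (2.3–2.9 µm at
  104 nm pixels, T-cell-scale) on a jittered grid spaced so expansions
  cannot collide; Gaussian spots (σ 1.5 px ≈ a diffraction-limited PSF) with
  Gaussian noise at SNR 8 (amplitude/SD); negative-binomial mRNA counts
  (μ 6); UPA positivity 0.88 per cell with 1 + Poisson(2) spots;
  co-localized fraction 0.22 planted as coincident spot pairs in both
  channels (the two probes detect the same molecule); UPA-only spots kept
  ≥6 px from mRNA spots so the planted label is unambiguous ground truth;
  nuclear fraction 0.85. The generator does not emulate real cell
  morphology, 3-D structure, autofluorescence, or intensity variation
  between transcripts — a green recovery test establishes that segmentation,
  detection, assignment and overlap logic are correct at realistic density
  and SNR, not that the pipeline is robust to every imaging artefact.
* **Presence tables** — Bernoulli draws from a logistic model with cell-type
  base probabilities (0.06/0.11/0.18/0.88, the published per-type medians)
  and N(0, 0.3) donor effects.

All generators are deterministic per seed (integer sub-seeds derived from
the master seed; no time-based seeding) and emit truth tables sufficient to
score every downstream operation.

## Numerical choices and degenerate inputs

Ratios with zero denominators are `NA` with an undefined flag, never
infinities. The poly(A) mode is the most frequent integer-rounded length,
ties toward the smallest. Otsu on a constant image returns `+Inf` (no
objects). Blank images yield zero nuclei/spots without error. Expansion
collisions and nearest-label ties are resolved deterministically by scan
order. Logistic fits run to tolerance 1e−10 with a separation flag at
boundary fitted probabilities or |coefficient| > 15. The recovery test for
per-cell positivity judges the pipeline against the *realized* planted
Bernoulli draw (cell-for-cell concordance), since the nominal probability is
a property of the generator, not of the images actually produced.

## Known limitations

BAM input is a thin convenience (primary alignments, no poly(A) estimates —
those come from the basecaller); the tested interchange format is the
documented TSV. Images are in-memory matrices with a plain-text PGM
interchange (no TIFF reader is available in this installation). Junction
matching is exact by default and has no model of alignment softclips.
The Kozak scores, as noted, are internally normalized and not comparable to
the external predictor's absolute values. Nuclear/cytoplasmic fractions
inherit the 2-D projection bias of the imaging protocol.
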