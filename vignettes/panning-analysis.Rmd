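---
title: "Methods: panning-screen analysis and aggregation kinetics in panscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panning-screen analysis and aggregation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panscreen)
```

This vignette documents the models and numerical choices behind the
package, the parameters that matter, and what its synthetic-data generator
does and does not establish.

## Library model

A library is a `scaffold_template`: a constant amino-acid context with
placeholder (`X`) positions, an alphabet allowed at those positions, and
two DNA flank markers. The two built-ins mirror the calbindin-D9k-based
display libraries this package targets: a "side" library with three
randomized residue pairs on the first EF-hand (6 positions) and a "loop"
library with a 13-residue insert — three glycines, seven randomized
residues, three glycines — between the EF-hands (7 positions). The
alphabet excludes cysteine (19 letters): surface cysteines promote
dimerization. Theoretical diversity is `|alphabet|^k`, i.e. 19^6 ≈ 5e7 and
19^7 ≈ 9e8.

The default codon design assigns each amino acid one common *E. coli*
codon, omits TAA and TGA entirely, and keeps TAG as a second glutamine
codon, because the amber codon is read as Gln in the suppressor host used
for phage production. The published library's exact codon table is not
public; since only three properties of it are load-bearing downstream (no
Cys codon, no TAA/TGA, TAG→Q), a single-codon design with those properties
is the default and the whole table is user-replaceable. Constant-region
DNA is always rendered deterministically; only variable-region codons are
ever sampled. This matters: a synthesised library has one fixed constant
sequence, and the constant-region filters below rely on it.

Randomized positions are 1-based indices, as is idiomatic in R.

## Read QC cascade

Filters run in the order used by the screens this reimplements, in which
the stop-codon and quality criteria came first and removed the large
majority of discarded reads:

1. `contains_N` — any undetermined base, anywhere in the read;
2. `low_quality` — any base with Phred < 21 (error probability ≥ 1%),
   applied to the whole read, not only the insert;
3. `in_frame_stop` — TAA or TGA in the coding frame. The frame is anchored
   on the 5' DNA flank of whichever strand carries it. If neither strand
   anchors the flank the scan is skipped and the read falls through to
   `unoriented`: scanning all six frames of an unalignable read would
   misattribute random junk to the stop filter. (TAG is *not* a stop here;
   it translates to Q.)
4. `unoriented` — flank markers on neither strand, or ambiguously on both.
   Antisense reads are reverse-complemented in silico, qualities reversed.
5. flank / constant checks — for a contiguous variable region (loop
   library) both flanks must match exactly and bracket exactly 3k
   nucleotides (`flank_mismatch` otherwise); for an interspersed design
   (side library) every constant nucleotide between the anchoring flanks
   must equal the expected construct (`constant_mismatch`). Matching is
   exact: the screens specified expected sequences, with no stated
   tolerance.
6. translation with TAG→Q; a residual in-frame stop in the extracted
   codons fails the read.

Each read receives exactly one fate; the QC report's counts sum to the
total. `run_qc()` is a vectorized implementation of this cascade; the
exported single-read operations (`orient_read()`, `quality_filter()`,
`frame_and_constant_check()`, `translate_variable_region()`) are the
reference semantics, and the test suite asserts the two paths agree on a
mixed fixture.

## Enrichment statistics

Frequencies are computed over *retained* (QC-passed) reads — the screen's
published tables do not state the denominator, and retained reads are the
only defensible choice for a pipeline whose statistics follow its own
filters. Ranking is by read count descending with lexicographic
tie-breaking, so all outputs are reproducible to the byte; the original
analysis is silent on ties. Per-selection summaries report the top
sequence's frequency (percent) and the number of sequences with ≥ 100
reads; overlaps between 2–4 selections are exact string-identity Venn
region counts (regions are exclusive and sum to the union size). Naive
library QC reports the fraction of reads whose peptide occurs once (≈ 80%
at real depths), at most twice (> 99.9%), and the read-weighted
per-position amino-acid frequency matrix.

## Similarity scoring, clusters, logos

Peptides of one library have equal length, so alignment is ungapped: the
score of a pair is the sum of per-position matrix entries. The published
screens used an unpublished 0–9 matrix; the default here preserves its
stated structure — identity 9, and a physicochemical-group model for the
rest: within-group 6 (aliphatic ILVM, aromatic FWY, polar STNQ, positive
KRH, negative DE, small AG, P alone), related groups 3
(aromatic–aliphatic, polar–charged), otherwise 0. This reproduces the
loop-library identity score 63 = 7 × 9. The side library's published
identity score of 56 is *not* reproducible by any per-position-uniform
matrix over six positions (56 is not 6 × 9); the original matrix evidently
scored some residues or positions differently, and the package treats the
matrix as configuration, recording its checksum in every cluster result.

Clusters are seed-centric ("star") clusters: all top-list peptides scoring
at least the cutoff (30 for 7-mers, 27 for 6-mers in the original screens)
against a chosen seed, not transitive single-linkage — matching how hits
are actually reported ("all sequences with a score of at least 30 versus
the hit").

Logo matrices follow the WebLogo convention: position information
R = log2(A) − H (Shannon entropy, log2), letter bar = frequency × R. The
alphabet size defaults to A = 19 because cysteine is excluded by design;
with A = 20 every column would carry a constant extra log2(20/19) ≈ 0.074
bits. Members are weighted equally by default (each unique sequence once);
read-count weighting is available but makes the logo an abundance plot
rather than a motif summary.

## Synthetic panning generator

The generator produces the statistical structure the analysis assumes,
with all randomness flowing from one seed:

- naive pools drawn uniformly over `alphabet^k`;
- selection rounds that resample `n_reads` reads multinomially with weight
  `count × fitness`, where fitness is
  `background + Σ_f weight_f · exp(stringency · score_f)` over motif
  families given as position-weight tables — a softmax sharpening with
  `stringency` as the single selection-strength knob, not a phage-titer
  model;
- FASTQ rendering with sampled variable-region codons (this is where amber
  TAG codons enter), clamped Gaussian Phred scores, substitution errors
  with lowered qualities, N calls, and a configurable antisense fraction.

The frozen defaults are: 2e5 reads per round (a 1/25 desk-scale stand-in
for the ~5e6 reads of a real selection — large enough that the top-500
list is dominated by genuine motif-family members), 3 rounds, stringency
1.0, background 0.05, error rate 1e-3, N rate 1e-4, antisense fraction
0.5, Phred ~ N(35, 4) clamped to [2, 40]. Under these defaults the
round-3 pools show single-percent top frequencies (1–3%), a few dozen
mutually similar sequences above the cluster cutoff, and logo information
concentrated at the binder model's fixed positions — the qualitative
structure real selections of this kind report. The default loop binder
model conserves hydrophobic residues (L/I preferred) at positions 2, 4, 6
and spreads its score over eight polar letters at positions 1, 3, 5;
position 7 is mixed. An early draft gave the polar positions only three
scoring letters, which made them as conserved as the "fixed" ones; varied
positions must be genuinely broad for the fixed/varied contrast to be the
planted signal.

What the generator does **not** emulate: PCR chimeras and amplification
bias, phage growth-rate differences, paired-end merging artifacts,
position-correlated motifs (fitness is additive over positions), and
quality-score correlation along reads. A green end-to-end test therefore
establishes that the pipeline recovers planted enrichment structure from
realistic read-level noise — not that it would be robust to amplification
pathologies.

## Aggregation kinetics

The two-moment model is integrated as written:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M,\qquad
  \frac{dM}{dt} = 2 k_+ m P,\qquad \frac{dm}{dt} = -2 k_+ m P,$$

with concentrations in µM and time in hours. Defaults are typical of
recombinant Aβ42 at low-µM concentration: k₊ = 1.08e4 µM⁻¹h⁻¹ (3e6
M⁻¹s⁻¹), kₙ = 3.6e-7 µM⁻¹h⁻¹, k₂ = 3.6e-5 µM⁻²h⁻¹, n_c = n₂ = 2 — giving
half-times of 1–2 h at 3 µM. Seeds are specified by mass fraction; the
seed *number* concentration divides that mass by a mean seed length
(default 500 monomers, typical of sonicated fibril preparations) unless
given explicitly. Whether reported seed percentages are mass or number
fractions is ambiguous in most assay descriptions; mass fraction is
assumed here.

Numerics: classical RK4 with 4000 uniform steps to the last requested
time, dense output by linear interpolation within a step. The monomer is
integrated as an explicit third state rather than eliminated via
m = m_tot − M, so mass conservation is a genuine consistency check: every
trace verifies max |m + M − m_tot| ≤ 1e-6·m_tot and errors out rather than
returning a drifting solution. Sub-zero monomer overshoot (possible at
the plateau at coarse steps) is clamped with the complementary correction
applied to M, preserving the invariant exactly. The elongation-only case
has the closed form m(t) = m₀·exp(−2k₊P₀t) and is kept as an independent
oracle in the tests, as is the secondary-dominated half-time scaling
t₅₀ ∝ m₀^(−(n₂+1)/2).

Inhibition fitting follows the "selective reduction" scheme: all traces
share one parameter set; only the rate constant named by the mode is
multiplied by a free factor in (0, 1] per nonzero inhibitor concentration
(factor ≡ 1 at zero inhibitor; a Hill-type tie across concentrations is
deliberately not imposed). Normalized traces constrain only the products
k₊kₙ and k₊k₂, so k₊ is anchored at its starting value during fits; the
factors are identifiable under every mode regardless of the anchoring
(under elongation mode the factor rescales both products at once, which
is exactly its observable signature). Optimisation is Nelder–Mead on
log10 rate constants and logit factors from a small deterministic
multi-start grid; `select_mode()` fits all three hypotheses and ranks
them by the mean over traces of the RMS residual of the normalized
signal. The fitted rate constants themselves should be read as effective
values conditional on the anchored k₊; the mode ranking and factors are
the scientific output. Model selection is by residual alone (no
complexity penalty) because all three hypotheses have identical parameter
counts.

Half-times are the linearly interpolated first upward crossing of half
plateau; a trace that never crosses is an error, not NA, so downstream
ratios cannot silently propagate.

## Spectroscopy arithmetic

FRET efficiency is E = (I₀ − I)/I₀ on background-subtracted donor
intensities; values below zero (donor enhancement artifacts) are passed
through with a warning flag rather than clipped, since clipping would
bias time-course averages. The hydrodynamic-radius-to-mass conversion
uses the globular scaling MW ∝ R_h³; for non-globular species this is an
upper-bound heuristic, which is why the monomer-count calculator takes
explicit masses and an assumed binder stoichiometry instead of hardcoding
a bound.

## Degenerate inputs and tie rules

- Empty FASTQ → empty peptide table, total 0, no error.
- Empty peptide stream → empty variant table with a warning; summaries of
  empty tables error.
- Ranking ties → lexicographic; cluster-member ties → score, then count,
  then peptide.
- All-zero selection weights → error (degenerate pool).
- Flat kinetic traces → normalization error for raw traces; half-time
  error when the level is never crossed.

## Known limitations

- Criterion-level reproduction of the original screens' Table-1 numbers
  requires their deposited reads (network download) and is not part of
  the offline test surface.
- The default similarity matrix is a documented stand-in with the stated
  0–9 structure, not the unpublished original; side-library identity 56
  is knowingly not reproduced (see above).
- The kinetics module fits the unfragmented two-moment model only; no
  fragmentation, saturating elongation, or oligomer intermediates.
- The CLI is a thin convenience wrapper; the R API is the interface of
  record.
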