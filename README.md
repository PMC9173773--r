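# panscreen

Analysis toolkit for phage-display panning screens of small scaffold-protein
libraries against amyloid-β (Aβ) species, and for characterising the binders
such screens produce.

## The problem

Directed-evolution screens against aggregating targets generate two kinds of
data that need careful, reproducible computation:

1. **Selection sequencing.** Libraries built on the calbindin D9k (S100G)
   scaffold carry either a six-residue randomized surface patch ("side"
   library, diversity 19⁶ ≈ 5·10⁷) or a seven-residue randomized loop
   between the two EF-hands ("loop" library, 19⁷ ≈ 9·10⁸); cysteine is
   excluded, and the amber codon TAG encodes Gln in the suppressor host.
   After three rounds of selection the eluates are amplified with primers in
   the constant region and sequenced. Turning those FASTQ reads into ranked
   binder candidates requires orientation, filtering (N bases, Phred < 21,
   in-frame stops, flank/constant-region mismatches), translation,
   counting, and cross-selection comparison.

2. **Binder characterisation.** Aβ42 aggregation follows the two-moment
   kinetics

   dP/dt = kₙ mⁿᶜ + k₂ mⁿ² M,  dM/dt = 2 k₊ m P

   (P fibril number, M fibril mass, m free monomer). An inhibitor that
   selectively reduces kₙ (primary nucleation), k₂ (secondary nucleation on
   the fibril surface — the dominant source of toxic oligomers) or k₊
   (elongation) reshapes ThT traces in distinct ways; fitting all three
   hypotheses globally and ranking them by residual identifies the
   microscopic target. Seeded assays give an orthogonal check: 1 % seed
   isolates secondary nucleation, 30 % seed isolates elongation. Simple
   binding readouts round this out: FRET efficiency E = (I₀ − I)/I₀ and the
   globular scaling MW ∝ R_h³.

Because raw screen sequencing is rarely redistributable, the package
includes a seeded synthetic panning simulator (uniform naive libraries,
softmax affinity selection, sequencing errors, mixed read orientation) so
every pipeline stage is testable end-to-end from code alone.

## Worked example

```r
library(panscreen)

tpl <- built_in_template("loop")
theoretical_diversity(tpl)
#> [1] 893871739            # 19^7

## synthetic three-round panning with a planted YLTIRLM-like motif family
sim <- simulate_panning(tpl, binder_model_loop_default(),
                        sim_config(n_reads = 2e5, seed = 1))
tab <- count_variants(rep(sim$final$peptide, sim$final$count), "round3")
selection_summary(tab)
#> $top_freq_percent : 1.42   # most abundant sequence, % of retained reads
#> $n_seq_min_reads  : 327    # sequences seen at least 100 times

## cluster the top hit against the top-500 list, default matrix, cutoff 30
top <- tab[1:500, ]
cl  <- cluster_by_cutoff(top$peptide[1], top, cutoff = 30)
cl
#> cluster around QININLI (cutoff 30): 67 members

round(logo_matrices(cl$members$peptide)$information, 2)
#> [1] 1.02 1.92 1.06 2.21 1.03 3.14 1.00
```

The information content (bits) peaks at positions 2, 4 and 6 — the
hydrophobic positions the planted motif family conserves — while the polar
positions 1, 3 and 5 stay varied, the alternating pattern such screens
recover for real Aβ-binding loops.

```r
## kinetics: which rate constant does an inhibitor reduce?
p <- kinetic_params()          # Aβ42-like defaults, 3 uM monomer
traces <- simulate_inhibition_dataset(p, "secondary", c(0, 1, 3),
                                      c(1, 0.5, 0.2),
                                      seq(0.05, 6, length.out = 60),
                                      noise_sd = 0.01)
select_mode(traces, params0 = p)
#>         mode mean_residual_error
#> 1  secondary          0.0102     # best fit: the generating mode
#> 2 elongation          0.0149
#> 3    primary          0.0321

fret_efficiency(I = 72, I0 = 100)  #> 0.28
mw_ratio_from_rh(3)                #> 27
```

A mean residual error at the noise floor (1 % here) for exactly one mode is
the signature of selective inhibition; the 0.28 FRET efficiency and the
cube-law 27× mass ratio are the arithmetic behind oligomer-binding
readouts.

## Layout

- `R/` — templates & codon designs, read QC, enrichment, alignment/logos,
  synthetic panning, kinetics, spectroscopy, CLI (`panscreen_cli()`).
- `src/` — Rcpp RK4 integrator for the two-moment aggregation model.
- `inst/extdata/templates.json` — shipped library definitions.
- `vignettes/panning-analysis.Rmd` — models, parameter choices, what the
  synthetic generator does and does not emulate, known limitations.
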