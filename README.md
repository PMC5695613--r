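# mir140sim

Stochastic and deterministic kinetic models of the regulatory network
motifs through which the chondrocyte microRNA **miR-140** acts in
osteoarthritis (OA), plus the companion bioinformatics step that motivates
them: hypergeometric enrichment ranking of miRNAs by their share of
OA-associated target genes.

The package is aimed at systems biologists and cartilage researchers who
want to simulate how miR-140 shapes anabolic (TGF-β/SMAD3, IGF-1) and
catabolic (IL-1, TNF-α) signalling in chondrocytes, to test *in silico*
interventions (miRNA knockdown, overexpression, NF-κB inhibition, anti-miR
dosing), and to explore how the combined network changes the response to an
inflammatory stimulus from sustained matrix degradation to a transient
pulse.

## What is inside

**Models.** All models are explicit mass-action reaction networks over
integer molecule counts — no Michaelis–Menten or Hill terms:

* five single-pathway models: TGF-β/SMAD3/SMAD7/miR-140 (positive
  feedback), SOX9/miR-140/HDAC4/RUNX2/MMP13 (incoherent feedforward),
  IL-1/miR-140/ADAMTS5 (coherent feedforward), IL-1/NF-κB/miR-140/MMP13
  (incoherent feedforward), TNF-α/NF-κB/JNK/AKT/miR-140/IGFBP5/IGF-1/ACAN;
* an integrated cartilage-degradation model joining the five over shared
  miR-140 and NF-κB pools, with ADAMTS-5/MMP-13 protein, aggrecan and
  collagen-II fragment readouts and anti-miR-140 titration;
* four generic TF/miRNA/target motif models (bistable positive feedback,
  ringing negative feedback, coherent and incoherent feedforward loops).

**Engines.** An exact Gillespie direct-method simulator (compiled inner
loop, bit-reproducible from a seed) with ensemble summaries (mean and
Student-t 95% CI per species per time point), and an LSODA deterministic
integrator (relative tolerance 1e-6, absolute tolerance 1e-13). A
propensity of a reaction with rate constant *k* and reactant counts *x*,
*y* is *k*, *k·x*, *k·x·y*, or *k·x·(x−1)/2* for a self-interaction.

**Experiments.** Fold changes, smoothed peak times, return-to-basal times,
the IL-1 × TGF-β × anti-miR dose–response scan, and `reproduceFigure()`
runners for the documented simulation panels (tidy CSV + plot +
provenance).

**Enrichment.** For each miRNA with more than one disease-associated
target, the probability that a random target set of the same size contains
at least the observed number of disease genes is the upper hypergeometric
tail P(X ≥ k), X ~ Hypergeom(N, K, n) over the target-gene universe;
p-values are Benjamini–Hochberg corrected and miRNAs ranked. A synthetic
generator plants truly enriched miRNAs at a controlled enrichment ratio so
the pipeline's recovery behaviour is testable end to end.

**Exchange.** SBML Level 3 Version 1 export/import for the supported
mass-action model class (Level 2 Version 4 writer available).

## Worked example

```r
library(mir140sim)

m <- getModel("il1_mmp13", "with_miR140")
m
#> KineticModel: il1_mmp13
#>   4 species, 7 reactions, 7 rate constants
#>   nonzero initials: IL1=500
#>   notes: IL-1/NF-kB/miR-140/MMP13 incoherent feedforward loop

es <- runEnsemble(m, nReps = 100, duration = 48 * 3600, baseSeed = 1)
pk <- peakTime(es, "MMP13")
sprintf("MMP13 mRNA peaks at %.1f h (ensemble mean %.0f molecules)",
        pk$time / 3600, pk$value)
#> "MMP13 mRNA peaks at 9.7 h (ensemble mean 7317 molecules)"

inh <- runEnsemble(getModel("il1_mmp13", "miR140_inhibition"),
                   nReps = 100, duration = 48 * 3600, baseSeed = 1)
sprintf("50%% miR-140 inhibition raises the peak to %.0f molecules",
        peakTime(inh, "MMP13")$value)
#> "50% miR-140 inhibition raises the peak to 9560 molecules"
```

A transient IL-1 stimulus (half-life ~45 min, gone by 2–3 h) activates
NF-κB, which transcribes both *MMP13* and miR-140; because miR-140 removes
*MMP13* mRNA, the incoherent loop turns the response into a pulse peaking
within about 10–12 hours instead of a sustained 48-hour rise. Halving
miR-140 synthesis (the `k_synmiR140 = 0.0009` s⁻¹ preset) raises the pulse
by roughly 30%.

The enrichment side, on a synthetic table with five planted OA-enriched
miRNAs (200 miRNAs, 2000-gene universe, 100 disease genes):

```r
g <- generateTargetTable(plantedEnrichmentDesign(seed = 1))
r <- rankMirnas(g$table, g$diseaseGenes)
head(r[, c("mirna", "n_targets", "n_disease_targets",
           "enrichment_ratio", "p_adjusted", "rank")], 3)
#>     mirna n_targets n_disease_targets enrichment_ratio   p_adjusted rank
#> 1 miR-005       223                41         3.677130 3.546603e-13    1
#> 2 miR-004       250                34         2.720000 7.628525e-07    2
#> 3 miR-002       177                26         2.937853 1.067570e-05    3
```

`enrichment_ratio` is observed over expected disease-target count; the
planted miRNAs (miR-001 … miR-005) occupy the top ranks, as the truth
record in `g$truth` confirms.

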