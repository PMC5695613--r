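---
title: "Kinetic models of miR-140 regulatory motifs in cartilage"
author: "mir140sim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of miR-140 regulatory motifs in cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(mir140sim)
```

## The modelling problem

Chondrocytes, the only cell type of articular cartilage, balance anabolic
signalling (TGF-beta, IGF-1) against catabolic signalling (IL-1, TNF-alpha)
that drives expression of the matrix-degrading enzymes MMP-13 (cleaves type
II collagen) and ADAMTS-5 (cleaves aggrecan). The chondrocyte microRNA
miR-140 sits inside several small regulatory circuits — feedback and
feedforward loops — on both sides of that balance, which is why reports of
its role in osteoarthritis appear contradictory when each circuit is studied
in isolation. `mir140sim` implements those circuits as explicit mass-action
reaction networks so that their individual and combined dynamics can be
simulated stochastically (every reaction event) or deterministically, and
provides the companion bioinformatics step: a hypergeometric enrichment
ranking of miRNAs by their share of disease-associated targets.

## Model formalism

A model is a list of species with integer copy numbers and a list of
reactions with at most two reactant molecules. Reaction propensities follow
stochastic mass action: a zeroth-order reaction fires at rate $k$; a
first-order reaction at $k x$; a bimolecular reaction at $k x y$, or
$k x (x - 1)/2$ for a self-interaction. The stochastic engine is the exact
direct-method simulation algorithm: waiting times are exponential with rate
equal to the total propensity and the firing reaction is chosen with
probability proportional to its propensity. The deterministic engine
integrates the matching rate equations (self-interaction term $k x^2 / 2$)
with the LSODA stiff/non-stiff switching solver at relative tolerance
$10^{-6}$, absolute tolerance $10^{-13}$, and at most 10000 internal steps.
Counts are molecules, time is seconds; 1000 reporting intervals is the
default output grid. No Michaelis–Menten or Hill terms are used anywhere:
regulation is encoded only through the reactions themselves.

Three recurring encodings deserve explanation, because they determine how
"inhibition" behaves quantitatively:

* **Translation inhibition by sequestration.** Where the evidence says the
  miRNA blocks translation without changing mRNA levels (SMAD3, HDAC4), the
  miRNA binds the mRNA into a complex. The complexed mRNA still turns over
  at its own rate (recycling the miRNA) and the miRNA still turns over at
  its own rate (releasing the mRNA), so neither total pool is distorted by
  complexation — only the translationally active free mRNA is.
* **miRNA-directed mRNA destruction.** Where the evidence says the miRNA
  degrades the message (ADAMTS5, MMP13, IGFBP5), removal is catalytic in
  the miRNA (directly, or through a short-lived complex destroyed ten-fold
  faster than free mRNA, for the IGFBP5 arm where total mRNA pools are the
  observable).
* **Transcriptional repression by promoter binding.** Repressors
  (phospho-SMAD3 on the miR-140 gene, HDAC4 on the RUNX2 gene) bind a
  two-copy gene species; transcription fires only from free gene copies.
  Two copies reflect a diploid genome.

Stimuli (IL-1, TNF-alpha, active TGF-beta) are initial amounts, not events;
their decay constants set how transient the signal is (IL-1 half-life ~45
minutes, so less than 10% remains at 3 hours). NF-kB activation is encoded
first-order in the stimulus — production of active NF-kB from a non-limiting
inactive pool at rate $k_\mathrm{actNFkB} \cdot \mathrm{IL1}$ — because the
documented inhibition intervention is expressed as a change in a rate
constant with units of s$^{-1}$, which is only dimensionally consistent with
that encoding (a bimolecular variant also saturates the inactive pool within
seconds at either rate value, making an 80% inhibition a no-op).

## Parameter calibration

Most rate constants in this field are not measurable directly, so the
package follows a half-life-first recipe: degradation constants are chosen
to give physiologically sensible half-lives (hours for mRNAs and proteins,
about a day for the miRNA), synthesis constants are then set so pools sit at
their chosen basal steady states (`steadyStateSynthesisRate`,
`halfLifeToRate`), and the few remaining constants are tuned so the
deterministic dynamics satisfy documented behavioural constraints. Values
printed in the source figure legends are taken verbatim and never tuned:
`k_synmiR140 = 0.0018` s$^{-1}$ with 500 initial miR-140 copies, the NF-kB
activation pair `5e-4`/`1e-4` s$^{-1}$, the intervention presets
`0.0009`/`0.0036` s$^{-1}$, the three chronic miR-140 presets (30/`6e-5`/
`1.5e-4`, 200/`4e-4`/`1e-3`, 900/`1.8e-3`/`4.5e-3`), and the chronic
TNF-alpha decay `1e-5` s$^{-1}$. Notably the three presets are mutually
consistent with a single miR-140 turnover rate of `2e-6` s$^{-1}$
(initial = synthesis/turnover in every preset), which the TNF-alpha model
therefore adopts.

The behavioural constraints used for tuning, all asserted in the test
suite, are: phospho-SMAD3 peaks 30–45 minutes after TGF-beta activation and
is largely de-phosphorylated (below 25% of peak) though still above basal at
8 hours; total miR-140 dips after TGF-beta stimulation and re-enters a
±10% band around basal within 48 hours; MMP13 mRNA pulses with an interior
peak at roughly 10–12 hours under transient IL-1 and keeps rising for 48
hours when miR-140 is absent; an acute TNF-alpha = 500 stimulus yields
approximately a 3-fold increase in total IGFBP5 mRNA and a 1.5-fold increase
in total miR-140 at 20 hours; and under chronic TNF-alpha with low initial
miR-140 the IGFBP-5 protein peaks near 2.5 days before declining. Each
model ships its frozen post-calibration parameter set, so none of this
tuning re-runs at build or test time. `calibrateModel()` exposes the same
machinery programmatically (log-uniform sampling plus local refinement
against ODE statistics) for users who want to re-fit constants to their own
constraints.

One structural constant is worth flagging: in the TGF-beta/SMAD3 model the
miR-140 gene carries two copies each transcribing at the printed
`k_synmiR140`, giving total basal synthesis `0.0036` s$^{-1}$ and hence a
turnover of `7.2e-6` s$^{-1}$ (half-life about 27 h) at the printed basal
level of 500. With half that turnover the documented return to basal within
48 hours is unreachable from any dip deeper than about 12%, so the
two-copy reading is the one consistent with the stated dynamics.

## The model library

Five single-pathway models (`buildTgfbSmad3Model`, `buildSox9Runx2Model`,
`buildIl1Adamts5Model`, `buildIl1Mmp13Model`, `buildTnfaIgfbp5Model`), four
generic motif models (`buildGenericMotif`), and the integrated model
(`buildIntegratedModel`) are constructed in code and addressable through
`getModel(name, variant)`. Intervention presets (miR-140 null, 50%
inhibition, overexpression, NF-kB inhibition, anti-miR doses) are applied
through the same `applyIntervention()` mechanism available to users, so a
preset differs from its base model only in the printed initial counts and
rate constants.

```{r}
m <- getModel("il1_mmp13", "with_miR140")
m
tr <- simulateSSA(m, duration = 48 * 3600, seed = 1)
plot(gridTimes(tr) / 3600, observableTrace(tr, "MMP13"), type = "l",
     xlab = "time (h)", ylab = "MMP13 mRNA (molecules)")
```

### The integrated model

The integrated model merges the five networks over one miR-140 pool and one
NF-kB pool and adds the coupling reactions to the matrix readouts:
translation of ADAMTS5 and MMP13 mRNAs, enzyme-catalysed conversion of
finite Aggrecan and Collagen2 pools (10000 copies each — a configurable
bookkeeping scale, since only relative fragment levels are interpreted) to
AggFrag and ColFrag, and irreversible binding of an anti-miR-140
oligonucleotide into an inert complex. Combining networks calibrated in
isolation forces a handful of shared constants to be re-balanced; these are
the integrated model's own calibration, documented here:

* NF-kB is a low-copy active pool (tens of molecules) feeding both the
  miR-140 and MMP13 promoters, so the printed per-NF-kB transcription
  constants remain usable in the combined network.
* SMAD7-mediated TGF-beta inactivation is slowed so the TGF-beta signal
  persists for days in a dose-dependent way on the week-long horizon of the
  combined experiments, rather than hours as in the isolated model.
* TGF-beta protection of collagen is carried by SMAD3 signalling
  antagonising RUNX2 (phospho-SMAD3-promoted RUNX2 turnover, a
  well-established antagonism between TGF-beta/SMAD3 signalling and
  chondrocyte hypertrophy), with only weak phospho-SMAD3 repression of the
  miR-140 gene. The alternative — routing the TGF-beta effect through
  strong miR-140 repression — makes TGF-beta *increase* collagen
  degradation (less miR-140 means less MMP13 mRNA removal), contradicting
  the documented dose-response geometry; the combined network's behaviour,
  not the isolated models', constrains this choice.
* RUNX2 is the dominant sustained MMP13 source, NF-kB the dominant pulsed
  one; miR-140-directed removal dominates both, which is why sequestering
  miR-140 with anti-miR raises MMP-13 and collagen fragments even though it
  also shuts the RUNX2 route down via restored HDAC4.

With these choices the combined model reproduces the documented geometry:
at zero anti-miR dose, matrix degradation is small and TGF-beta reduces
collagen (not aggrecan) fragments; a moderate dose (500) is overwhelmed
within days by stimulus-driven miR-140 synthesis; a high dose (3000) keeps
the enzymes high for the whole week. Aggrecan degradation is insensitive to
TGF-beta because the ADAMTS5 pulse happens in the first day, before the
slow TGF-beta-driven miR-140 decline can matter — a timescale-separation
argument rather than a structural one.

### Generic motifs

The four generic motifs use deliberately simple parameter sets chosen for
unambiguous qualitative behaviour: the double-negative positive feedback
loop adds stoichiometric miRNA/mRNA mutual destruction (molecular
titration), which together with promoter binding provides the
ultrasensitivity that makes the loop genuinely bistable — with catalytic
removal alone the deterministic loop gain is bounded below one and the
circuit is monostable. The negative feedback loop is a three-stage cascade
whose deterministic response rings (damped oscillations); sustained
deterministic oscillation is not reachable in this reaction class for the
same gain-bound reason, and the ringing (at least three alternating
extrema) is what the tests assert. The coherent feedforward loop shows its
sign-sensitive delay as prolonged target expression relative to a control
whose miRNA is not repressed by the signal; the incoherent loop shows the
classic pulse.

## Stochastic engine details

Per-replicate seeds are `baseSeed + replicate - 1`; the generator is R's
default Mersenne Twister seeded through `set.seed()`, so every trajectory,
ensemble and scan is bit-reproducible from its base seed. Ensembles report
the per-time-point mean and the Student-t 95% confidence interval of the
mean. The event loop is compiled (C++), recomputing all propensities after
each event — networks here have at most ~70 reactions, so sparse updating
would add complexity without measurable benefit. An all-zero propensity
state is absorbing: the remaining grid is filled with the frozen state.
Negative ODE concentrations beyond the absolute tolerance trigger a
warning; reported values are clipped at zero.

Exactness of the engine is tested against closed forms: the stationary law
of the birth–death process (chi-square goodness of fit to the Poisson law
on 10^4 independent samples), exponential-decay means, conservation of
conversion-only totals, and agreement of the ensemble mean with the ODE
solution within three CI half-widths when all copy numbers are scaled
100-fold (bimolecular constants scaled down accordingly).

## Summary statistics and experiment runners

`foldChangeAt`, `peakTime` (moving-average smoothing, default 11 grid
points ≈ 1% of a standard trace — wide enough to suppress shot noise,
narrow enough to shift a peak by at most one window) and
`returnToBasalTime` (earliest time after the largest excursion at which the
trace is inside the band *and stays there*) operate on trajectories and
ensembles alike; `"total:"` observables sum a free pool with its mRNA
complexes while excluding gene-state and anti-miR-sequestered species.
`runDoseResponseScan` crosses IL-1 (0–1000, ten even levels) with TGF-beta
(1–1000, three log-spaced levels: 1, 31.6, 1000) and anti-miR doses, with
deterministic per-cell seed derivation; its default end time is 7 days,
matching the horizon over which the combined model's fragment dynamics
play out. `reproduceFigure` runs any documented simulation panel and
writes tidy CSV, a plot, and a provenance record.

## Enrichment pipeline

`rankMirnas` implements the prioritisation pipeline: the gene universe
defaults to all distinct target genes in the interaction table (an explicit
universe can be supplied); miRNAs with fewer than two disease-associated
targets are removed; each remaining miRNA's disease-target count is tested
with the upper-tail hypergeometric probability (computed in log space);
p-values are corrected by Benjamini–Hochberg (Bonferroni optional — which
correction a given ranking used is often unrecorded, so the default is
the field's standard FDR control); rows are ranked by adjusted p-value
with ties broken by enrichment ratio then identifier. Both strong and weak
evidence interactions are included by default, with a `supportFilter`
option. File readers accept the hsa_MTI-style tab/comma layouts and plain
one-gene-per-row lists.

The synthetic generator (`plantedEnrichmentDesign`, `generateTargetTable`)
emulates those downloads with planted structure: planted miRNAs draw
disease genes with probability inflated to `ratio * K/N` (binomially, so
hypergeometric assumptions stay honest; an exact-count mode exists for
deterministic tests), background miRNAs draw uniformly. The default design
(200 miRNAs, 2000 genes, 100 disease genes, 150–250 targets per miRNA, 5
planted at ratio 3) is sized so that planted and background disease-target
counts separate reliably; the recovery property — all five planted miRNAs
in the top ten ranks in at least 95% of 100 seeded replicates — is part of
the test suite. What passing these tests does *not* show: real interaction
tables have heavy-tailed target-set sizes, correlated target sharing
between miRNA family members, and annotation biases, none of which the
generator mimics; results on real downloads therefore need the usual
caution, and any real-database ranking is database-version dependent, so
no specific real-data ranks or p-values are asserted anywhere.

## SBML exchange

`exportSBML`/`importSBML` round-trip the supported model class (mass
action, order ≤ 2) through SBML Level 3 Version 1, writing counts as
`initialAmount` with `hasOnlySubstanceUnits="true"` so stochastic semantics
are unambiguous; a Level 2 Version 4 writer flag exists for older tools.
Import rejects constructs outside the class (rules, events, function
definitions, reversible reactions, non-mass-action laws) with a named
diagnostic. Validation is structural (required elements, referential
integrity); no network access or schema files are assumed.

## Problem sizes and reproducibility

The shipped experiments use 100 stochastic replicates for ensemble
statistics (the documented replication), 1000 reporting intervals, and the
durations their scenarios imply (20 h acute TNF-alpha, 48 h IL-1 panels,
72 h TGF-beta, 7 days chronic/integrated). The test suite exercises the
same code paths at reduced replication for the broad property checks
(e.g. scans at 8 replicates on a 3x3 stimulus grid), chosen as the smallest
ensembles at which the asserted orderings are decisive; the full-scale
numbers are recomputed by `scripts/acceptance.R`. Every stochastic result
in the package is a pure function of (model, duration, seed).

## Known limitations

* Mass action only: no explicit receptor/kinase cascades, no saturation;
  "activation" constants lump multi-step signalling.
* The integrated model's cross-pathway constants are a calibration of this
  package, constrained by the documented qualitative geometry rather than
  by data; absolute fragment counts have no physical units.
* Anti-miR binding is irreversible; real oligonucleotide chemistry shows
  measurable off-rates.
* The enrichment stage treats target sets as fixed truth; it does not model
  annotation uncertainty.
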