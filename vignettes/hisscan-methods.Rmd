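---
title: "Methods: histidine-scanning library design and screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histidine-scanning library design and screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hisscan)
```

## The problem

Protein A affinity chromatography elutes bound IgG with harsh acid (pH ~3),
which can aggregate or denature the product. A ligand whose IgG binding
switches off at *mildly* acidic pH would allow gentler elution. Histidine is
the natural pH switch: its side chain protonates between pH 5 and 7, so a
His placed against a positively charged residue of the partner creates
electrostatic repulsion that appears only on acidification. `hisscan`
implements the computational side of a workflow that finds such His
positions in the protein A B domain (PAB): structure-guided candidate
selection, a combinatorial "wild-type-or-His" library, selection-round
frequency analysis, and the biophysical assays used to characterize the
winners.

## Structure-guided site selection

Candidate positions are residues of the ligand chain that are (a) close to
positively charged residues (His, Lys, Arg — His counts as charged only in
the acidic-condition screen) of the target chain and (b) solvent exposed.

* `distance_profile()` computes, for every ligand residue, the minimum
  over the charged set of the all-atom minimum distance — the convention of
  crystallographic contact programs, which matches the few-Angstrom
  magnitudes expected at an interface. Cβ–Cβ or centroid metrics were
  rejected because they systematically overestimate contact distances for
  long charged side chains.
* `compute_fsasa()` computes fractional solvent accessibility by the
  Shrake–Rupley quadrature: each atom is inflated by the probe radius
  (default 1.4 Å, water), covered with a deterministic golden-spiral grid
  (default 960 points), and scored by the fraction of grid points outside
  all neighbouring inflated spheres. Per-residue SASA of the isolated chain
  is divided by a Gly-Xaa-Gly extended-tripeptide reference modelling the
  denatured state. We ship the published theoretical Gly-X-Gly maxima (Tien
  et al. 2013) as the default reference rather than regenerating tripeptide
  coordinates internally: building idealized all-atom side-chain geometry
  is a large component in its own right, the reference is a convention in
  any case, and the table is fully overridable via the `reference`
  argument. Consequences of the quadrature: totals are invariant under
  rigid motion to ~0.1–0.2% at 960 points, and doubling the point count
  moves well-exposed residues by <1%. fSASA values slightly above 1 are
  possible for extended termini; values are *not* clipped.

Parsing goes through `read_structure()` (bio3d underneath) with a strict
single-conformer policy: first MODEL only, HETATM and waters excluded,
alternate locations resolved to the highest occupancy (ties to the first
record). Chain roles are always user-supplied; which chain is the ligand in
a deposited complex is an external fact the software should not guess.

## Mixed-codon library design

At each selected position the gene carries a *mixed codon*: a degenerate
codon synthesized as a nucleotide mixture that encodes at least the
wild-type residue and histidine. `design_mixed_codon()` constructs it as
the positionwise IUPAC union of the wild-type codon with the His codon CAT
(e.g. TTT ∪ CAT = YWT; GAT ∪ CAT = SAT; CTG ∪ CAT = CWK). Because the
mixture expands as a Cartesian product, some positions pick up one or two
bystander residues (YWT also encodes Tyr and Leu); the reference design
accepts these rather than optimizing them away. We deliberately did *not*
adopt a "fewest expanded codons" objective: it is not what the published
design does (it would emit MAT where the design uses MAY, and CRT where it
uses CRY), and the union rule reproduces the reference design exactly from
a wild-type codon table. The default table (`default_wt_codons()`) uses the
scanned gene's codons for the residues that occur in it and common E. coli
codons elsewhere; pass `wt_codon` explicitly when the gene is known.

Two hard constraints are enforced: the expansion must contain the wild type
and His, and must contain no stop codon. For tryptophan no stop-free
covering codon exists at all — any degenerate codon containing TGG and a
His codon necessarily expands to TAG — so `design_mixed_codon("W")` errors;
this is a mathematical property of the genetic code, verified exhaustively
in the test suite.

`library_diversity()` reports exact integer products at both levels: the
17-position reference design (`pab_library_design()`) encodes
4·2·2·2·2·4·2·4·3·4·4·2·2·4·2·4·2 = 25,165,824 ≈ 2.5 × 10⁷ distinct
proteins from 5.4 × 10⁸ distinct genes. The protein-level number is the one
to compare against library titers.

## Panning simulation (synthetic data)

No sequencing data are deposited for the reference screen, so the
enrichment analyzer is exercised against a stochastic stand-in,
`run_panning()`. The model is deliberately the simplest mechanism that
reproduces the two observed phenomena — enrichment of high-affinity
variants and collapse of sequence diversity:

1. **Capture.** Each phage is captured independently with probability
   proportional to `exp(beta * log_affinity)`, scaled so the expected
   number of captures equals the round's capacity. Decreasing capacities
   (default: 20% of the pool, halving each round) model offering less
   immobilized antibody each round.
2. **Wash.** Non-captured phages leak into the eluate with probability
   `wash_survival` (default 10⁻³, a typical background-binding level).
3. **Amplification.** The eluate is resampled to a fixed pool size
   (default 10⁵) with per-variant lognormal bias (default sd 0.3) modelling
   growth-rate differences.
4. **Sequencing.** A fixed number of clones is drawn without replacement;
   defaults follow the reference screen's depths (84, 50, 84, 58, 88, 93
   including the unselected library).

Variant fitness is additive over positions (`log_affinity` = sum of
per-position contributions), which encodes no epistasis; the planted effect
model (`pab_effect_model()`) gives His a +3 bonus at the five known
effective sites and penalizes non-wild-type residues by 3 at the five known
essential interface sites. Real panning adds phenomena this stand-in omits:
avidity of multivalent display, PCR sequence bias, phage growth genetics,
and epistasis between positions. Passing the closure tests therefore shows
the *analyzer* recovers planted truth through the full stochastic pipeline
— not that the simulator predicts real screens.

Everything is driven by one integer seed; a fixed seed yields byte-identical
round FASTA files. Pool extinction (possible at very small capacities) is
flagged on the result, not raised as an error.

## Enrichment analysis and site calling

`position_frequencies()` tallies wild-type / His / other fractions per
position, by default over *unique* sequences — the denominator used in the
reference analysis, which prevents a single clone that took over the pool
from dominating every position. At a position whose wild type is His, the
His count folds into the wild-type category so the three categories
partition. Residues outside a position's encoded set are counted as
"other" with a warning (sequencing error in real data).

`call_sites()` applies strict thresholds: His frequency > 0.70 calls an
*effective* His site (the screen tolerates — indeed favours — His there);
< 0.20 calls an *essential* site (wild type required for binding); exactly
0.70 or 0.20 is neutral, since the defining phrases are "more than" and
"less than". Unique-sequence ratios are reported under two rounding
conventions (`percent`, half-up; `percent_trunc`, truncated) because
published values have used either.

## Two-state thermal unfolding

CD melting curves are fit to the standard Gibbs–Helmholtz two-state model

ΔG_U(T) = ΔH_m (1 − T/T_m) − ΔC_p (T_m − T + T ln(T/T_m)),
f_U = 1 / (1 + e^{ΔG_U/RT}),

with the observed signal a f_U-weighted mixture of two linear baselines.
ΔC_p is held fixed during fitting (default 2.643 kJ/(mol·K), the value
used for all variants of the reference study; a single scan cannot
determine it) and `delta_cp_from_mw()` scales it by molecular weight, with
the default slope calibrated so a 6.7 kDa domain reproduces that anchor.
Starting values are data-driven and deterministic: baselines from the
terminal 10% of points, T_m from the apparent-fraction 0.5 crossing, ΔH_m
from a van 't Hoff slope of logit(f_U). A curve whose signal range is
within 6× the point-to-point noise estimate is rejected as having no
transition. Heating-rate (kinetic) effects are not modelled; the fit
assumes equilibrium at every temperature.

Monte-Carlo behaviour, measured by the test suite on the package's own
synthetic curves (T_m 346.4 K, ΔH_m 230 kJ/mol, 96 points over 278–373 K,
noise 2% of signal range): the T_m estimator is unbiased to <0.05 K, its
sampling sd equals its asymptotic standard error (~0.3 K), and ~88% of
replicates land within 0.5 K. That 88% is an information floor of these
curve conditions, not an optimizer artifact — restarting the fit at the
true parameters gives an identical spread.

## 1:1 binding kinetics

Sensorgrams follow the Langmuir 1:1 closed form (association
R(t) = R_eq (1 − e^{−(k_a C + k_d) t}) with
R_eq = k_a C R_max / (k_a C + k_d); exponential dissociation), verified in
the tests against independent numerical ODE integration. `fit_one_to_one()`
fits one global (k_a, k_d, R_max) across all concentrations — the standard
identifiable parameterization — by least squares on log-parameters, and
reports K_D = k_d/k_a with a delta-method standard error. Censoring mirrors
the "ND" (not determinable) convention of binding tables: a result is ND
when the fit fails, when fitted K_D exceeds 10× the highest analyte
concentration, or when the relative standard error of K_D exceeds 100%.
K_D ratios versus a reference are rendered at 2 significant figures, "-"
when either side is ND. The synthetic series used in the recovery studies
(concentrations 0.3–10 × K_D, 600 s phases) were chosen to be
well-conditioned: contact times much shorter than the slowest relaxation
time (~1/(k_a C + k_d)) leave K_D weakly identified, and the recovery rate
degrades accordingly. Mass-transport limitation and multivalent (avidity)
models are out of scope.

## pH-gradient elution

`simulate_elution()` models the column as a logistic release law in pH —
cumulative released fraction 1/(1 + e^{s (pH − pH_1/2)}) — mapped through a
linear descending gradient (default pH 7.0 → 2.5) and broadened by a
Gaussian band; total absorbance integrates to the load (mass
conservation, verified to 1%). `detect_peak_ph()` smooths with a fixed
5-sample moving average, subtracts a 10th-percentile baseline, takes the
earliest maximum, and reads the peak pH by linear interpolation of the pH
trace at the peak volume — the way a dual-axis chromatogram is read.
Guards: a maximum that does not rise 3 noise SDs above baseline, or that
sits at the trace boundary (a truncated rising edge, as when the release
midpoint lies below the gradient's end), is flagged "no elution" rather
than reported. ΔpH, the figure of merit for mild elution, is the variant
column's peak pH minus the wild type's, at 1 decimal. Detector dead volume
between the UV cell and pH meter is assumed zero (traces aligned);
stepwise elution is supported through piecewise-constant pH traces with
per-step recovery reporting.

## What is preset and what is computed

The wet-lab observables of the reference study — variant elution-peak pH
values, T_m values, K_D tables, per-round sequencing depths, stepwise
recovery percentages — enter the package only as *presets*
(`pab_variants()`, `pab_round_depths()`, `paz_step_recoveries()`): they
parameterize the synthetic generators and the report layout and cannot be
recomputed from sequence. Everything downstream of them — diversity
products, frequency tables, site calls, fitted parameters, detected peak
pH, all ratio and difference columns — is computed by the package at run
time, and `run_pipeline()` demonstrates the full loop by simulating each
assay at its preset value and recovering it by fitting.

## Problem sizes and determinism

Default analysis sizes were chosen for interactive use: synthetic libraries
of 2 × 10⁴ variants over a 10⁵-phage pool (the 2.5 × 10⁷-variant design is
never enumerated), 960 quadrature points per atom, 96-point melting curves,
3–4-concentration sensorgram series, 0.02 mL chromatogram sampling. The
Monte-Carlo studies in the test suite use 200 replicates for the two curve
fits and 100 seeded screens for the panning closure. Every stochastic
function takes an explicit integer seed and is exactly reproducible; no
global RNG state is consumed implicitly.

## Known limitations

* The panning model is a stand-in: no avidity, epistasis, PCR bias, or
  bead-transport physics; its parameters are tunable but not calibrated to
  any real screen.
* SASA values depend on the radii set and reference table; agreement with
  other programs is expected only to a few percent, so fractional SASA
  should be read as a band, not a point value.
* The two-state fit cannot detect intermediates; strongly sloped baselines
  with a shallow transition inflate T_m uncertainty (see the Monte-Carlo
  numbers above).
* The 1:1 kinetic fit assumes a clean monophasic interaction; heterogeneous
  or bivalent data will fit poorly rather than fail loudly.
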