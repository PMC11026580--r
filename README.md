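# igaflex

Solution-scattering analysis of antibody Fab–Fc flexibility, exercised
end to end on synthetic data with known ground truth.

Monomeric IgA2-class antibodies are three-domain molecules — two Fab
arms and an Fc joined by a short hinge — that populate a range of
conformations in solution, from compact ("closed", Rg ≈ 43–46 Å) to
splayed ("open", 52–54 Å, and further for deglycosylated variants).
Small-angle X-ray scattering (SAXS) measures the ensemble average
I(q); resolving the underlying states requires model-free reductions
plus explicit conformational modeling. `igaflex` implements the whole
chain in R:

* **Synthetic data with ground truth** — a coarse-grained builder for
  glycosylated IgA2-like antibodies (one bead per residue or
  monosaccharide, five N-glycan sites per heavy chain, flexible hinge
  228–235 and tailpiece 449–466), closed/open/extended conformers,
  noisy two-state mixture profiles, SEC-SAXS frame stacks, single-cycle
  SPR sensorgrams, and thermal melt curves.
* **Theoretical scattering** — the Debye formula
  `I(q) = Σᵢⱼ fᵢfⱼ sin(q rᵢⱼ)/(q rᵢⱼ)` with an accelerated
  distance-binned path (within 0.2% of the exact double sum) and
  `I(0) = (Σf)²` exactly.
* **Model-free reductions** — Guinier fit with a self-consistent
  `q·Rg < 1.5` window; pair distribution `p(r)` by regularized
  non-negative indirect Fourier transform with automatic
  regularization and a Dmax scan; exact model histograms; the
  dimensionless Kratky curve `(qRg)² I/I(0)` with peak/shoulder
  detection; buffer subtraction and elution-peak frame merging.
* **Conformational sampling** — rigid-body pivot moves over hinges,
  tails and glycans with steric rejection and Rg-stratified coverage
  of the compact-to-splayed range.
* **Multistate fitting** — non-negative least-squares weights for
  k-state models, exhaustive/beam-search model selection (beam verified
  against exhaustive enumeration), and state counting from the Rg
  distribution of the top fits.
* **Auxiliary fits** — 1:1 Langmuir SPR kinetics (K_D = kd/ka) and
  melting temperatures from the first-derivative extremum.

## Worked example

```r
library(igaflex)

res <- run_pipeline(run_config(seed = 1, n_conformers = 60))
print(res)
```

which prints (abridged):

```
# two-state antibody SAXS analysis report
seed: 1
truth: weights = 0.5/0.5, noise = 0.020

## model-free reductions
Guinier Rg: 48.61 A (I0 = 2.224e+06, qRg_max = 1.49, 8 pts)
Dmax: 160 A (scan)
P(r) Rg: 49.06 A; features: peak at 40.49
Kratky features (qRg): peak at 2.01; peak at 9.30

## ensemble
conformers: 63, Rg 46.0-67.8 A

## multistate fit
k = 1: best chi2 = 3.0272
k = 2: best chi2 = 1.0233
k = 3: best chi2 = 1.0162
selected k: 2 (improvement rule > 15%)
estimated states: 2
  state at Rg 46.0 A (mass 0.57)
  state at Rg 54.4 A (mass 0.43)
```

Reading it: the synthetic experiment was generated from an equal
mixture of the closed (Rg ≈ 45.9 Å) and open (≈ 53.8 Å) conformers
with 2% noise. The Guinier radius of the mixture (48.6 Å) and its
maximal dimension (160 Å) match what such a two-state antibody
measures; the one-state fit is poor (χ² 3.0), two states drop it to
~1.0, a third state adds under 15% and is rejected; and the Rg
distribution of the top two-state fits localizes two states within
~1 Å of the truth with roughly equal populations.

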