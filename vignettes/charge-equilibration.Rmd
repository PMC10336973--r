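---
title: "Neural-network atomic charges and charge equilibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network atomic charges and charge equilibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aimcharge)
```

## The problem

Real-space atomic charges partition a molecule's electron density into
atomic basins: the charge of atom $A$ is $q_A = Z_A - N_A$, with $N_A$ the
electron population of its basin, and the molecular charge is the exact sum
$Q = \sum_A q_A$. Neural-network surrogates predict each $q_A$
independently, so the sum rule breaks: the residual
$\Delta Q = \sum_A q_A^{\mathrm{pred}} - Q$ is nonzero and grows wherever
the model extrapolates (strained geometries, transition states). A charge
set that does not reproduce $Q$ is unusable for anything downstream that
relies on neutrality — electrostatics, charge transfer along a reaction
coordinate, per-residue aggregation.

`aimcharge` implements the full surrogate pipeline (descriptors, per-element
networks, training, persistence) and, at its core, a family of *charge
equilibration* schemes that remove $\Delta Q$ exactly. These are rescaling
methods applied after prediction; they are deliberately distinct from
electronegativity-equalization methods that *compute* charges from scratch.

## The correction rule

All deterministic schemes share one linear rule:

$$\eta_A = w_A\,\Delta Q, \qquad q_A^{\mathrm{corr}} = q_A^{\mathrm{pred}} - \eta_A,
\qquad \sum_A w_A = 1 .$$

Normalizing the weights makes conservation an identity:
$\sum_A q_A^{\mathrm{corr}} = \sum_A q_A^{\mathrm{pred}} - \Delta Q = Q$.
This is the unique linear rule with that property, which is why the package
adopts it as the concrete form of the per-atom correction. Conservation in
floating point is verified to $10^{-10}\cdot\max(1, N)$ by property tests;
in practice residuals land at machine epsilon.

The eleven weight kernels (`CEQ` ids 1–11) assign $w_A$ proportional to:

| id | weight proportional to | parameters used |
|----|------------------------|-----------------|
| 1  | $1$ (uniform)          | — |
| 2  | $|q_A^{\mathrm{pred}}|$ | predicted charges |
| 3  | $Z_A - q_A^{\mathrm{pred}}$ (electron count) | $Z$ |
| 4  | $\chi_A^S$ (Sanderson electronegativity) | $\chi^S$ |
| 5  | $\chi_A^P$ (Pauling electronegativity) | $\chi^P$ |
| 6  | $\sigma_A$ (error spread of the element's model) | $\sigma$ |
| 7  | $|\mu_A|$ (mean error magnitude) | $\mu$ |
| 8  | $|\mu_A|\,\sigma_A$ | $\mu, \sigma$ |
| 9  | $|\mu_A|\,(Z_A - q_A^{\mathrm{pred}})/r_A$ | $\mu, Z, r$ |
| 10 | $|\mu_A|\,(Z_A - q_A^{\mathrm{pred}})$ | $\mu, Z$ |
| 11 | $|\mu_A|\,\sigma_A\,(Z_A - q_A^{\mathrm{pred}})/r_A$ | $\mu, \sigma, Z, r$ |

The statistical kernels rest on a simple argument: an element whose network
shows a broad validation-error distribution is likelier to have caused the
residual, so it should absorb more of the correction. The shipped defaults
for $(\mu_e, \sigma_e)$ — see `default_error_stats()` — are normal-fit
parameters of per-element validation errors of the reference CHON charge
models (in electrons); users training tailor-made models should override
them with their own validation fits (`read_error_stats()`), which is also
why they are stored in an editable data file rather than hard-coded.

Element constants: $\chi^S$, $\chi^P$ and the covalent radius $r$ enter only
as *ratios within one molecule*, so any single consistent tabulation works.
The package ships the standard Sanderson and Pauling scales and Cordero
covalent radii in `inst/extdata/element_data.tsv`, with sources noted in the
file; the table is extensible beyond CHON.

### Degenerate inputs

Two situations would produce undefined or negative weights, and the package
resolves both by falling back to uniform weights with a warning: (i) a weight
sum at or below $10^{-15}$ (e.g. scheme 2 with all-zero predictions); (ii) a
nonpositive electron count $Z_A - q_A^{\mathrm{pred}}$ in schemes 3/9/10/11,
which cannot occur for physically plausible charges but can for corrupted
input. Uniform is the only parameter-free fallback, and a warning (not an
error) keeps batch pipelines running.

### Iterative variants

Schemes 12 and 13 implement the stochastic alternative: repeatedly draw
per-atom corrections from each element's error distribution
$\mathcal{N}(\mu_e, (\texttt{Sigma}\cdot\sigma_e)^2)$, accept a proposal
only if it strictly reduces $|\Delta Q|$, and stop once
$|\Delta Q| \le \texttt{Qtoler}$ or after `max_iter` proposals. Scheme 12
draws independently per atom; scheme 13 draws one shared standard-normal
deviate per iteration, scaled by each element's $\texttt{Sigma}\cdot\sigma_e$
around $\mu_e$ (atoms of one element move coherently). After the loop, any
remaining residual is removed by a uniform redistribution, so the final
charges satisfy the same conservation contract as the deterministic
kernels. The accept-if-decreasing loop with a uniform cleanup is this
package's documented interpretation of the iterative approach; the draws
are fully seed-reproducible. Defaults: `Sigma = 1` (draws at the models' own
error scale), `Qtoler = 1e-4` e (well below chemical significance),
`max_iter = 10000`.

Custom kernels plug in via `CEQ = -1`: an R file defining
`assign_custom_weights(symbols, q_pred, stats, elements)`. Its output is
validated on every call (length, nonnegativity, unit sum), so a buggy
plug-in fails loudly rather than silently breaking conservation.

## Descriptors

The featurizer computes the canonical atom-centered symmetry functions with
the cosine cutoff $f_c(r) = \tfrac12[\cos(\pi r/R_c) + 1]$ for $r \le R_c$
(exactly zero beyond), Gaussian radial functions
$\sum_j e^{-\eta (R_{ij}-R_s)^2} f_c(R_{ij})$ resolved per neighbor
element, and narrow/wide angular functions

$$2^{1-\zeta}\sum_{j<k} (1 + \lambda\cos\theta_{jik})^\zeta\,
e^{-\eta(R_{ij}^2 + R_{ik}^2 [+ R_{jk}^2])}\,
f_c(R_{ij})f_c(R_{ik})[f_c(R_{jk})]$$

where the bracketed factors distinguish the narrow (G4) from the wide (G5)
variant; an optional shift $R_s$ generalizes each squared distance to
$(R-R_s)^2$ and reduces to the textbook forms at $R_s = 0$. Parameters live
in three plain-text files (`input.type`, `input.rad`, `input.ang`;
whitespace-separated, `#` comments) whose row order fixes the descriptor
slot order. Per-neighbor-element radial resolution is the shipped default
(the alternative, element-agnostic summation, can be emulated by summing
slots). The angle at the center uses the normalized dot product; zero-length
interatomic distances raise an error rather than returning NaN. No periodic
boundary conditions: these are open-boundary molecular descriptors.

The descriptors are invariant under rotations, translations and reflections
and equivariant under atom relabeling; both properties, plus locality and
agreement to $10^{-12}$ with a naive triple-loop evaluation, are enforced by
the test suite.

The default CHON set (`default_acsf_config()`) uses $R_c = 4.5$ Å, five
radial shifts per neighbor element ($R_s \in \{0.8, 1.15, 1.5, 2.0, 2.8\}$ Å,
$\eta = 4$ Å$^{-2}$) and narrow angular functions for every unordered
element pair at both parities ($\zeta = 1$, $\lambda = \pm 1$,
$\eta = 0.25$ Å$^{-2}$) — 40 slots per atom. This is a compact
general-purpose set sized for the package's synthetic molecules; production
models for real chemistry would typically use denser grids.

## Per-element networks

One independent feed-forward network per element maps that element's
descriptor vector to the target property. Features and targets are z-scored
with training-split statistics (zero-variance slots get unit scale so the
transform is always invertible); the networks are dense
tanh-activated stacks with a linear output, trained with full-batch Adam on
the mean-squared error with early stopping on a held-out validation split.
Defaults: two hidden layers of 64 units, learning rate $10^{-2}$, up to
2000 epochs, validation fraction 0.1, patience 300. Hidden layers use
Xavier-style initialization; the output layer starts at zero, so an
untrained network predicts the target mean — a safe baseline that also
stabilizes the first optimization steps. The RNG seed fixes initialization
and the train/validation shuffle, and training restores the caller's RNG
state, so identical calls yield bit-identical bundles.

A trained bundle persists as a self-describing folder: the three ACSF files,
one JSON file per element (weights, biases, standardization statistics) and
a manifest naming the target property and units. Doubles are serialized as
17-significant-digit strings, which round-trip IEEE doubles exactly —
`load_bundle(save_bundle(b))` predicts bit-identically. The manifest records
a canonical fingerprint of the ACSF configuration at training time; loading
a bundle whose descriptor files were edited afterwards fails, because
networks are only valid for the descriptors they were trained on.

## Synthetic fixtures

The generator produces random connected CHON clusters (each atom placed
$\approx$ 1.3 Å from a previously placed atom, rejecting pairs closer than
0.9 Å) and analytic reference charges

$$q_A = \kappa\,(\bar\chi - \chi_A^P)\,g_A, \qquad
g_A = \sum_{B \ne A} \frac{f_c(R_{AB})}{R_{AB}},$$

shifted by a constant so $\sum_A q_A = 0$ exactly ($\kappa = 0.15$ e,
cutoff 4 Å). The form is chosen so that (i) electronegative atoms come out
negative (water's oxygen is negative, its hydrogens positive), (ii) the
function is smooth in the coordinates and rigid-motion invariant — hence
learnable from the descriptors — and (iii) conservation is exact, giving
equilibration a known ground truth. `perturb_charges()` emulates model
error: per-atom Gaussian noise (default 0.01 e, the order of the shipped
per-element σ values) plus a spread systematic component that sets
$\Delta Q$ to a requested value exactly; the 0.5 e offset used in the
stress tests mirrors the residuals reported for reactive/extrapolative
geometries.

What the fixtures do *not* emulate: chemically valid bonding patterns,
conformational ensembles, electron delocalization, or the heavy-tailed
error distributions of real networks far from their training domain.
Passing tests therefore demonstrate the correctness of the machinery —
descriptors, optimization, conservation, persistence — not chemical
accuracy on real molecules, which requires quantum-chemical reference data
outside this package's scope.

Because the corrections are linear, perturbation with offset $\delta$
followed by any normalized kernel obeys
$\mathrm{MAE}(q^{\mathrm{corr}}, q) \le \mathrm{MAE}(q^{\mathrm{pred}}, q)
+ \delta/N + 3\cdot\text{noise}$, a bound the tests assert across all
schemes.

## Metrics

`error_metrics()` reports MAE, RMSE and the Pearson correlation (with
$r^2$); zero-variance input flags the correlation as undefined rather than
erroring, since MAE/RMSE remain meaningful. `fit_error_distribution()`
returns maximum-likelihood normal parameters — sample mean and $1/n$
standard deviation — matching how the shipped per-element defaults were
fitted; the $1/(n-1)$ convention is available and differs negligibly at
validation-set sizes.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every contract is meaningfully exercised: 2,000
training atoms (250 eight-atom clusters) for the trainer-recovery check
(held-out MAE $\approx$ 0.008–0.011 e against a 0.02 e criterion), 500–1,000
randomized molecule/charge/scheme cases for conservation, 100 random rigid
motions for invariance, and $\le$ 5-atom molecules for the brute-force
descriptor oracle. Conservation tolerances are $10^{-10}\cdot\max(1,N)$;
weight normalization $10^{-12}$; descriptor invariance $10^{-8}$ relative;
oracle agreement $10^{-12}$.

## Known limitations

- No pretrained production model ships with the package; predictions are
  only as good as the model the user trains.
- Elements beyond CHON need rows in the element table and error statistics
  before the statistics-weighted kernels will accept them.
- The featurizer is pure R and sized for molecules of tens to hundreds of
  atoms; very large systems would warrant a compiled neighbor-list
  implementation.
- Equilibration redistributes error; it cannot recover per-atom accuracy
  lost by a poor model, and aggressive kernels can amplify noise when
  $|\Delta Q|$ is large — the per-atom corrections should stay small
  relative to the charges themselves.
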