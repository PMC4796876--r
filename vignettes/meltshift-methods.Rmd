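---
title: "Predicting melting-temperature changes upon point mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting melting-temperature changes upon point mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Protein engineering often needs to know how a single amino acid
substitution changes a protein's *thermal* stability, measured by the
melting temperature $T_m$ — the temperature of the reversible two-state
(un)folding transition, where the folding free energy $\Delta G(T_m) = 0$.
This is harder than predicting the *thermodynamic* stability change
$\Delta\Delta G$ at room temperature, because it requires an estimate of
how each interaction's contribution to $\Delta G(T)$ varies with
temperature. `meltshift` implements a knowledge- and thermodynamics-based
predictor of $\Delta T_m$ (mutant minus wild-type melting temperature;
positive = thermostabilizing) that needs only the wild-type 3D structure
and, when available, the wild-type $T_m$.

# Two-state thermodynamics

For a two-state folder with temperature-independent folding heat capacity
$\Delta C_p$, the stability curve is

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right)
  + \Delta C_p\left(T - T_m - T\ln\frac{T}{T_m}\right),$$

with $\Delta H_m < 0$ (folding convention). Treating a mutation as a small
perturbation with unchanged $\Delta H_m$ and $\Delta C_p$, a first-order
expansion of the zero of the mutant curve gives the linear relation

$$\Delta T_m \simeq \frac{T_m\,\Delta\Delta G}{\Delta H_m},$$

implemented by `dtm_linear()`. Because $\Delta H_m < 0$, $\Delta\Delta G$
and $\Delta T_m$ are exactly anticorrelated in this regime — a
destabilizing mutation lowers $T_m$. When $\Delta\Delta H_m \neq 0$ or
$\Delta\Delta C_p \neq 0$ the relation breaks (stability curves can even
cross: unchanged room-temperature stability yet a shifted $T_m$);
`dtm_two_state()` handles this case numerically, constructing the mutant
curve (enthalpy and heat capacity shifted; constant offset fixed so the
mutant $\Delta G$ at the 298 K reference equals the wild-type value plus
$\Delta\Delta G$) and re-solving for its zero with a bracketed root
search refined to $|\Delta G| < 10^{-9}$ kcal/mol. No closed form for the
general case is assumed. Two design consequences of the linear relation
propagate into the predictors below: the conversion factor between
stability and $\Delta T_m$ scales like $1/\Delta H_m$, and $\Delta H_m$
grows roughly with chain length $N_r$, which motivates dividing by $N_r$
(first model) and the $1/N_r$ polynomial terms (second model).

# Statistical potentials

Effective energies are extracted from a structure set as potentials of
mean force over associations of a *sequence element* $s$ (amino acid
type) with *structure elements*: the side-chain centroid distance $d$ of
a residue pair, the backbone torsion domain $t$, and the relative solvent
accessibility bin $a$. For one sequence and one structure element,

$$\Delta W(c, s) = -\ln\frac{\tilde F(c, s)}{\tilde F(c)\,\tilde F(s)},$$

in units of $kT$ with $kT \equiv 1$: only relative weights matter, since
the trained network supplies all scaling. Three-element forms use the
joint-times-singles-over-pairs factorization

$$\Delta W(x, y, z) =
  -\ln\frac{\tilde F(x,y,z)\,\tilde F(x)\,\tilde F(y)\,\tilde F(z)}
           {\tilde F(x,y)\,\tilde F(y,z)\,\tilde F(x,z)}.$$

A useful check of this form (asserted in the tests): if $s$ and $s'$ are
coupled only through $c$, the triple potential collapses to *minus* the
$(s,s')$ pairwise potential.

Nine temperature-independent forms are derived (`derive_potentials()`):
`sd`, `sds`, `sad`, `std`, `sa`, `saa`, `st`, `stt`, `sst`, named by their
element composition. Pair-based forms count both ordered directions of
every in-range residue pair, so their totals equal twice the pair count.

**Temperature dependence.** Amino acid interactions are temperature
dependent; this is captured by deriving the same potential forms
separately from a mesostable subset ($T_m < 65\,^\circ$C) and a
thermostable subset ($T_m \ge 65\,^\circ$C) of a $T_m$-annotated
structure set (`derive_t_potentials()`). To limit parameter count, each
subset's potentials are grouped into five: `sd`, `sds`, `sad`, an
accessibility group (`sa` + `saa`) and a torsion group (`st` + `stt` +
`sst`); the `std` form is not part of the temperature-dependent set.
Because the grouped tables have different shapes, a group is stored as
its component tables and evaluated as the sum of their energy
contributions — additivity at the evaluation level is asserted in the
test suite.

**Numerical choices.** Observed/expected ratios are shrunk toward 1 with
a pseudocount weight $n_0 = 10$ (`sparse_correct()`): a cell with $n$
observations contributes $(n\,r + n_0)/(n + n_0)$, so empty cells give
exactly zero energy and well-populated cells are nearly unshrunk.
Distance-type potentials are smoothed along the distance axis with an
edge-renormalized triangular window of half-width 2 bins. Defaults:
distances binned over $[3.0, 8.0)$ Å in 0.2 Å steps (side-chain geometric
centroids; CA where no side-chain atom exists), minimum sequence
separation 1, accessibility in five 20 % bins, and a six-region torsion
partition (right/left helical, extended, polyproline II, epsilon, other)
shipped as an explicit table — the domain boundaries, bin widths and
distance definition are package choices exposed through `ms_config()`,
since only the element *types* are fixed by the formalism. Residues
without both backbone torsions (termini, broken backbones) are labelled
`undefined` and skipped by the forms that need them.

Solvent accessibility is computed with an in-package Shrake–Rupley
implementation (probe 1.4 Å, 960 deterministic spiral points per atom)
and normalized per amino acid by a maximal-area reference. Two references
are available: the published theoretical maxima of Tien et al. (2013)
(default, appropriate for real full-atom structures) and a `"computed"`
mode that measures the package's own extended Gly-X-Gly reference built
in the reduced atom representation. The computed mode makes the
normalization exactly self-consistent for synthetic structures — with it,
the relative accessibility of the reference conformation is 100 % by
construction, and accessibility distributions are identical across amino
acid types, which matters for the independence property discussed below.

# The two model structures

Each mutation is summarized by a feature vector: the per-potential energy
changes $\Delta\Delta W$ (mutant minus wild-type total energy, evaluated
on *unchanged wild-type geometry* — only terms touching the mutated
position survive the difference, which the implementation exploits and
the tests verify against a brute-force full recompute), the
Heaviside-split volume change $\Delta V_\pm$ (packing stress vs cavity
formation, from a standard mean residue volume table), the wild-type
residue's relative accessibility $A$, the chain length $N_r$, and
optionally the wild-type $T_m$.

Every input term $\nu$ carries a sigmoid weight in the accessibility of
the mutated residue,

$$\alpha_\nu(A) = \phi_\nu + \frac{r_\nu}{1 + e^{-\omega_\nu (A - b_\nu)}},$$

a smooth interpolation between a core weight and a surface weight —
energy contributions are known to weigh differently in these two regions.

**Tm-free model** (`predict_hot()`, 50 parameters):
$$\Delta T_m = c + \frac{a}{N_r}\left[\sum_{\nu=1}^{9}
  \alpha_\nu(A)\,\Delta\Delta W_\nu + \alpha_+(A)\,\Delta V_+ +
  \alpha_-(A)\,\Delta V_- + \alpha_I(A)\right],$$
with twelve 4-parameter weights plus the global scale $a$ and offset $c$.
The printed parameter count (50) pins down this parameterization; the
$1/N_r$ division reflects the $1/\Delta H_m$ scaling above and can be
disabled (`length_normalize = FALSE`).

**Tm-aware model** (`predict_tm_hot()`, 67 parameters): three hidden
perceptron sums — five mesostable potentials, five thermostable
potentials, and volume + independent terms — combined by polynomial
output weights
$$F_I(T_m, N_r) = q_0 + q_1 T_m + q_2 T_m^2 + \frac{q_3}{N_r} +
  q_4\frac{T_m}{N_r}, \qquad I \in \{M, T, V\},$$
so $\Delta T_m = F_M S_M + F_T S_T + F_V S_V$. The five-coefficient
polynomial (constant, $T_m$, $T_m^2$, $1/N_r$, $T_m/N_r$) reproduces the
printed total of 67 exactly and mirrors the $T_m/\Delta H_m$ structure of
the linear relation. The final prediction (`predict_final()`) is the
arithmetic mean of the two models, falling back to the Tm-free model with
a warning when the wild-type $T_m$ is unavailable.

# Training, cross-validation, evaluation

Parameters minimize the mean squared deviation between experimental and
predicted $\Delta T_m$ by batch gradient descent with analytic gradients
(`fit_dtm()`). Initial weights are random; training restarts (default 30)
guard against local minima, and the restart with the lowest *validation*
error wins (the criterion for restart selection is not uniquely
determined by the training protocol's description; validation error was
chosen as the less overfitting-prone reading). Early stopping tracks
validation error every iteration and returns the best-validation iterate
after a patience window. Plain fixed-step descent is the default;
Adam (`optimizer = "adam"`), hyperbolic learning-rate decay and a
Levenberg–Marquardt polish phase (`polish_iter`) are available behind the
configuration because the model is a smooth least-squares problem with an
exact Jacobian — the polish converges quadratically inside a basin and is
what lets noiseless planted data be fitted to machine precision, while
respecting the early-stopping contract (polish iterates are kept only
while validation error improves).

`crossvalidate_dtm()` runs $k$-fold cross-validation (default 5) with an
inner 8:1 train/validation split of each fold's remainder for early
stopping. The protocol description (5 folds with 90/10/80/10 fractions)
is internally inconsistent — five disjoint folds imply 20 % test — so the
implementation uses $k$ disjoint test folds with the 8:1 inner split of
the remainder, $k$ configurable. Splits are by mutation. `evaluate_dtm()`
reports $\sigma$ (RMSD), Pearson $r$, their outlier-trimmed versions
(removing the $\lfloor 0.1 n \rfloor$ largest-$|$error$|$ points;
"outlier" is defined as largest absolute prediction error, ties broken by
dataset order), and metrics stratified by burial class
($A < 15$, $15 \le A < 50$, $A \ge 50$ %), including $\sigma$ normalized
by the experimental spread of the stratum.

**Dataset curation** mirrors the selection rules of the experimental
$\Delta T_m$ compilation: X-ray resolution below 2.5 Å, $|\Delta T_m| \le
20\,^\circ$C, monomeric protein, no chemical denaturant, two-state
transition, single-site substitution (`filter_mutations()`, first failing
rule recorded). Replicate measurements of the same mutation keep the
entries at pH closest to 7 (within 0.5 pH units of the closest;
unspecified replicate weights are taken equal) and average their
$\Delta T_m$ (`merge_duplicate_mutations()`).

# The synthetic benchmark

Real training data (thousands of curated mutations on thousands of PDB
structures) cannot ship with a package, so every stage is exercised on
synthetic inputs (`synth_spec()`, `generate_structures()`,
`generate_mutations()`):

* **Structures** are single chains of alternating helical and extended
  segments built with ideal peptide geometry (NeRF construction, omega =
  180°, 8° torsion jitter), with a CB pseudo-side-chain-centroid atom on
  *every* residue, including glycine: the CB here is a centroid marker,
  not a chemical atom, and a uniform representation keeps geometry
  strictly independent of sequence. Chain lengths default to 20–60
  residues; melting temperatures are drawn uniformly (default 40–90 °C).
* **Sequences** are drawn uniformly over the 20 amino acids
  (`coupling = 0`) or biased by the local backbone state
  (`coupling > 0`), giving controllable sequence–structure dependence.
  At coupling 0, and with the `"computed"` accessibility reference, every
  structure element is genuinely independent of the sequence, so derived
  potentials converge to zero as the corpus grows. The package measures
  this convergence with the count-weighted RMS energy, a consistent
  estimator of coupling strength; the *maximum* absolute energy, by
  contrast, is an extreme-value statistic dominated by rare element
  tuples whose counts stay small at any realistic corpus size, and it
  plateaus well above zero under the default pseudocount — a sampling
  fact, not an implementation artifact.
* **Mutation datasets** plant a known model (moderate sigmoid steepness
  $\omega \approx 0.1$ per %, so core/surface weight differences are
  visible in stratified metrics) and add Gaussian noise (default sd
  2 °C). Planted-model recovery is the package's strongest end-to-end
  check: noiseless flat-weight data are fitted to $\sigma \le 10^{-3}$ °C,
  and at 2 °C noise the pooled out-of-fold $\sigma$ of 5-fold
  cross-validation returns to the noise floor.

What passing these tests shows — and what it does not: the synthetic
generator emulates structure-derived descriptors and a realizable
mutation-to-$\Delta T_m$ map, so the tests validate counting, energy
algebra, gradients, optimization, cross-validation mechanics and metric
arithmetic end to end. They do not demonstrate predictive accuracy on
real proteins: synthetic chains are small reduced-representation
backbones, real experimental noise is not Gaussian or homoscedastic, and
the planted map is by construction inside the model family. Benchmark
sizes used by the test-suite and the acceptance script (a 4-structure
potential corpus, 2,000-mutation planted datasets, 200-structure
independence corpora, 3 restarts with Adam + polish) were chosen to probe
each property at the smallest scale where it is statistically decidable.

# Known limitations

* Mutant structures are never modelled: energies are evaluated on
  wild-type geometry, with structural change encoded only through
  $\Delta V_\pm$. Mutations inducing real rearrangements are outside the
  model, which is also why the $|\Delta T_m| \le 20$ °C curation cut
  exists.
* The formalism's element definitions (distance metric, bin edges,
  torsion-domain boundaries, accessibility reference) are configurable
  package choices; alternative choices give different potential tables.
* The temperature-dependent potentials inherit the small size of any
  $T_m$-annotated structure set; sparse-data shrinkage keeps them finite
  but biased toward zero.
* Multi-site mutations and $\Delta\Delta G$ prediction as an end product
  are out of scope.
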