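---
title: "Ensemble hydrogen-bond stability and mechanical stiffness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble hydrogen-bond stability and mechanical stiffness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enstab)
```

## The model

`enstab` compares protein variants through their harmonic dynamics.
Each structure becomes an anisotropic elastic network: nodes (atoms or
residues, by policy) within a cutoff distance are joined by identical
Hookean springs of constant γ. For a connected pair (i, j) separated
by the equilibrium vector $R_{ij}$, the Hessian carries the 3×3 block

$$H_{ij} = -\frac{\gamma}{|R_{ij}|^2} \, R_{ij} R_{ij}^\top,$$

with diagonal blocks equal to minus the sum of the row's off-diagonal
blocks. This matrix is symmetric and positive semidefinite; for a
connected, generically shaped network it has exactly six zero
eigenvalues (rigid translations and rotations). The low-frequency
non-trivial eigenvectors approximate the molecule's collective
motions.

Key assumptions, inherited from elastic-network practice: the native
structure is the energy minimum; all springs share one constant;
solvent, side-chain chemistry and anharmonicity are ignored. The
model therefore resolves *geometry-driven* differences between
variants — which is precisely what a comparative hydrogen-bond
stability analysis needs — and nothing thermodynamic.

### Mode selection and conformer generation

Modes are ranked by collectivity, the entropy-based measure
$\kappa = N^{-1}\exp(-\sum_i p_i \ln p_i)$ where $p_i$ is node i's
normalized squared displacement. This is the standard definition used
by elastic-network conformer generators; it is adopted here because
highly collective modes describe domain-scale motion rather than
local dangling-end wiggles. Ties in the ranking go to the
lower-frequency mode.

The `n_modes = 5` most collective non-trivial modes are each swept
over the perturbation grid `dq_min = -100` to `dq_max = 100` in steps
of `dq_step = 20` — 11 points including 0, hence 55 conformers per
structure, with the dq = 0 conformer identical to the input. The
perturbation unit is deliberately explicit: eigenvectors are rescaled
to unit *maximum nodal displacement*, and $|dq| = 100$ maps to
`amplitude_scale` (default 2.0 Å) of maximum displacement. The linear
map keeps the amplitude interpretable in Å; any stability numbers
should be read alongside the amplitude used.

Node policy defaults: `heavy_atoms` for the ensemble stage (hydrogens
ride rigidly with their bonded heavy atom — they must exist in the
conformers for bond detection, but as independent nodes they would
triple the eigenproblem for no benefit at this resolution);
`calpha` plus one node per metal ion for the stiffness stage, the
standard residue-level ANM practice. Rotation-translation-block
approximations are not implemented; structures at the intended scale
diagonalize exactly in well under a second, and `ensemble_config()`
accepts and ignores an `nrbl` key for config-file compatibility.

## Hydrogen-bond stability (SEA)

A donor is any N or O heavy atom with a hydrogen within 1.2 Å; an
acceptor is any N or O. A bond is formed when the donor–acceptor
distance is ≤ 3.0 Å and the donor–H–acceptor angle is ≥ 135°
(both configurable). These are the defaults of the widely used
trajectory-analysis tools this stage mirrors; the thresholds matter
less than their consistency across structures, since SEA is always
compared between columns computed under identical criteria.
Intra-residue pairs are excluded; bond keys are orientation-specific
and never merged with their reversals.

The SEA table assembles the union of bonds seen in any conformer of
any structure; absent bonds are explicit zeros. This union-with-zeros
convention is what makes the deviation
$D^m = \sqrt{\sum_i (SEA_i^m - SEA_i^{WT})^2}$ symmetric in bond
discovery: a bond present only in the variant contributes exactly as
one present only in the wild type.

## Destructive-bond detection

Contributions $\xi_j^m = (SEA_j^m - SEA_j^{WT})^2 / (D^m)^2$ sum to 1
per variant; a variant identical to the wild type (D = 0) gets a
zero row and a flag, never NaN. The 9-bin histogram (table H) counts
bonds with ξ in [0.1(i−1), 0.1·i); read literally the last range
leaves ξ ≥ 0.9 unbinned, so bin 9 closes at 1.0 inclusive — the
minimal consistent completion. Bin edges are evaluated with a 1e-9
guard so exactly representable boundary values land deterministically.

Which bonds are counted per row is genuinely ambiguous; both policies
are implemented. The default `variant_present_bonds` counts bonds
observed in the variant or the wild type, because union counting
makes every row sum to the same universe size while observed row
sums in this kind of analysis typically fall short of it —
present-bond counting is the reading consistent with that. The
`union_bonds` policy remains one argument away.

Variant selection clusters H rows by mean-shift and keeps clusters
with positive mean $\bar S_H$; with a single cluster nothing stands
out and the selection is empty (warned). The destructive threshold is
the empirical 95% quantile (linear interpolation, `tail = 0.05`) of
the mean contributions $\bar\xi_j$ *restricted to positive values*:
quantized SEA leaves a large mass of bonds with exactly zero
deviation, and including that mass would drag the quantile to zero
and flag a fixed 5% of the whole universe regardless of signal. With
the positive-value base, the detected set scales with how many bonds
actually moved. Shrinking the tail can only shrink the set
(monotonicity is tested).

A consequence worth stating plainly: the detected set is the top
`tail` *share* of moved bonds, not "the planted bonds" — when diffuse
background noise moves every bond a little, the 5% tail contains the
planted signal plus the upper tail of the noise. The recovery tests
therefore assert containment and ranking (planted bonds present and
ranked first), which is the property the procedure actually
guarantees.

## Mechanical stiffness

Pairwise stiffness uses the uniaxial-extension formulation: the
compliance of pair (i, j) under equal-and-opposite forces along the
pair axis $\hat n_{ij}$ is

$$c_{ij} = \sum_k \frac{1}{\lambda_k}
  \left[(u_k(j) - u_k(i)) \cdot \hat n_{ij}\right]^2,
\qquad \kappa_{ij} = 1 / c_{ij},$$

summed over non-trivial modes, in units of γ. All non-trivial modes
are used by default: truncation is a modelling *choice*, not an
approximation — dropping positive compliance terms can only stiffen
(tested) — and no truncation is assumed. The mode sum is verified
against an independent pseudo-inverse force-response oracle
(solve $Hx = f$ with paired unit forces, project rigid modes, invert
the relative displacement) to 1e-6 relative on random networks, and
against the closed forms κ = γ for a single spring and κ = γ/(n−1)
for an n-node series chain.

Pairs whose compliance underflows 1e-12 are mechanically rigid at
model resolution; their κ is stored as an `Inf` sentinel, flagged,
and excluded from means and quantiles. Per-residue summaries: `K̄_i`
is the row mean over residue partners (the divisor is the actual
partner count; a `same_chain` scope is available for the
single-subunit reading), and `κ_site,i` is the κ row of a named metal
node. Tail extraction takes keys at or above the (1−fraction)
empirical quantile, ties included.

The "transmission path" between two sites is defined as the widest
path — maximizing the minimum edge κ — on the contact graph of node
pairs within 8 Å. Widest-path is the natural operationalization of
"a chain of spatially close residues that transmits mechanical
impact": the bottleneck edge governs how much of a perturbation
survives the route. It is computed on the maximum spanning tree
(whose unique path between any two vertices is widest) and verified
against brute-force path enumeration on small graphs.

## Statistics

Mean-shift uses a flat kernel, all points as seeds, convergence at
displacement < 1e-5·bandwidth (cap 300 iterations, warned), and
greedy mode merging by decreasing support at radius = bandwidth —
fully deterministic, no binned seeding. The bandwidth estimator is
restated explicitly as the mean distance to the ⌈q·n⌉-th nearest
neighbour (q = 0.3 default, self excluded, capped at n−1) so results
cannot drift with any library's internals. Cluster ids are dense from
1. Pearson correlations use the two-sided t-approximation;
Kolmogorov–Smirnov is the asymptotic two-sided test;
multiple-testing control is Benjamini–Hochberg at q = 0.05.

Position-list comparisons map chain-A/chain-F positions onto a
1..306 dimer axis, bin into 10 equal-width windows (edges at
multiples of 30.6, last bin closed), and correlate the two count
vectors. Intersection significance is the hypergeometric upper tail
over the 306-position universe — the natural enrichment test for
"are these two residue lists the same places"; where the original
analysis left its intersection test unnamed, published p-values are
treated as reference points, not assertions.

## The synthetic-data generators

The generators exist so every stage runs without external inputs, and
they emulate the *statistical shape* of the real inputs, not their
chemistry:

* `make_toy_structure()` builds ideal backbones (N, H, CA, C, O per
  residue) from internal coordinates. The helix uses φ/ψ = −62°/−47°,
  chosen once so the i→i+4 amide–carbonyl geometry (N···O 2.86 Å,
  angle ≈ 162°) clears the default bond criteria with margin; a
  12-residue helix carries n−4 = 8 backbone bonds. The hairpin is two
  antiparallel β-strands (φ/ψ = −139°/135°) at sheet geometry with a
  placement fixed once to maximize inter-strand rungs (about n/2 − 2
  bonds); the strands are joined elastically, not covalently. Chains
  of a multi-chain toy are packed so the nearest inter-chain contact
  sits at 4.6 Å — inside the elastic cutoff (connected dimer network),
  outside clash range. Metals go at the centroid of their
  coordinating residues' Cα positions. Everything is deterministic
  given the spec.
* `make_variant()` adds Gaussian coordinate noise (sd σ) to all atoms
  of listed residues — a stand-in for relaxed point mutants that
  keeps numbering and atom order identical, as the SEA comparison
  requires.
* `simulate_sea_table()` draws a wild-type column uniformly on the
  1/55 occupancy grid, adds grid-rounded noise per variant entry, and
  shifts planted (bond, variant) pairs by δ away from the wild-type
  value (downward when occupancy ≥ 0.5), clipped to [0, 1]. Ground
  truth is returned beside the table, never embedded in it. The
  default conditions (200 bonds, 9 variants, 5 planted, δ = 0.4,
  σ = 0.02) satisfy the detectability condition δ > 2σ.
* `simulate_survival()` draws $s_m = a + b\,\kappa_m + \varepsilon$,
  truncated below at 0.1 years. In the recovery tests the noise is
  tuned to a planted correlation of −0.4 at n = 32; at that size the
  sampling sd of a correlation is ≈ 0.15, so individual seeds scatter
  around the planted value and the tests assert the mean and the bulk,
  not every draw.

What passing tests on these toys shows — and what it does not: the
machinery (Hessian assembly, mode algebra, bond detection, the
deviation/contribution/histogram chain, stiffness algebra, the
statistics) is correct, deterministic and internally consistent. It
does not show that a 24-residue ideal dimer reproduces the contrast
structure of a 934-bond native protein: with a bond universe of a few
dozen, even diffuse mild noise concentrates into few bonds, so the
mild/severe separation of the contribution histograms is much weaker
than on full-size structures. The workflow reports whatever the
clustering finds and falls back to an all-variant tail scan when
nothing separates.

## Numerical choices and degenerate inputs

* Eigenvalues below 1e-8 × λ_max count as rigid-body modes; more than
  six means a disconnected network or mechanically degenerate
  geometry and raises an error unless explicitly allowed
  (`allow_degenerate = TRUE`, used for collinear-chain closed-form
  checks, which are legitimately floppy in an ANM).
* Degenerate eigenvalue ties take the solver's ascending order;
  collectivity ties prefer lower frequency.
* Alternate-location atoms resolve to the highest-occupancy record;
  insertion codes stay part of the residue key; residue numbering is
  taken verbatim from the file.
* SEA TSV export writes 17 significant digits so the text round-trip
  is bit-exact; the TSV→pipeline route is tested identical to the
  in-memory route.
* Problem sizes in the tests and the acceptance script (12-residue
  chains, 36 structures, 55-conformer ensembles, 20–50 seed
  replicates) were chosen as the smallest systems that exercise every
  code path with stable statistics.

## Known limitations

Uniform spring constants and a single cutoff; no solvent or
side-chain energetics — SEA measures geometric persistence under
harmonic motion, not free energy. Mutant structures are consumed as
given (or simulated); building them is out of scope. The stiffness
maps are wild-type properties; variant stiffness enters only through
position-wise summaries. Spreadsheet input is not parsed directly —
export stability tables to TSV first.
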