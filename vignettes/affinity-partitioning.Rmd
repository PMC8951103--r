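---
title: "Partitioning binding affinity into fragment contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning binding affinity into fragment contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragshare)
```

## The model

Free energy of binding is not additive over the chemical groups of a
ligand, yet medicinal chemistry reasons in group contributions, and in
practice additive models are decent first-order approximations — most
scoring functions are themselves nearly additive over fragments. This
package implements the "reverse" fragment-based view: instead of growing a
fragment into a ligand, take an existing ligand in a fixed complex
geometry, treat each of its fragments as a small capped molecule *frozen at
the coordinates it occupies in the complex*, and ask how each would score
against the receptor there.

Given per-fragment single-point scores $S_j$, the stakeholder share of
fragment $j$ is

$$\omega_j = \frac{S_j}{\sum_i S_i},$$

and the molecular interaction energy $\Delta E_{mol}$ (experimental or
scored, kcal/mol) is partitioned as

$$E_j^{scaled} = \omega_j\,\Delta E_{mol}, \qquad
  \sum_j E_j^{scaled} = \Delta E_{mol}.$$

Group efficiency, the fragment analog of ligand efficiency, divides the
contribution by the fragment's heavy-atom count:

$$GE_j = \frac{|E_j^{scaled}|}{NH_j}.$$

Four assumptions underlie the procedure: (1) additivity of fragment
contributions is an acceptable model; (2) what is estimated is the
feasibility of each fragment *at its position in the complex*, not its
global best binding mode; (3) a simple stakeholder normalization is an
adequate partition rule (the same principle behind Hirshfeld population
analysis); (4) scoring functions are accurate enough to estimate a *share*
— in particular, any multiplicative error cancels exactly in $\omega_j$,
which is why shares formed from pKd-unit or knowledge-based scores are as
usable as kcal/mol ones. The linearity of the built-in scorer in its term
weights (tested) makes this cancellation property exact for weight
rescalings.

## Fragmentation and capping

Fragmentation is the user's choice: a scheme names fragments, lists their
1-based heavy-atom serials, and declares which inter-fragment bonds to cut.
`validate_scheme()` enforces that the fragments are pairwise disjoint,
cover exactly the ligand's heavy atoms, and that the cut set matches the
ligand's inter-fragment bonds; ring and multiple-order cut bonds are
flagged because a hydrogen cap cannot preserve a ring or the hybridization
of a double bond (cutting order > 1 bonds needs an explicit override).

`cut_and_cap()` never moves an original atom — coordinates are copied
bit-for-bit, which the tests assert with `identical()`, since any implicit
transform would invalidate scoring the fragment "in place". Each severed
bond is capped along the exact unit vector toward the departed atom, so the
cap occupies the direction of the former bond. Cap bond lengths are fixed
per-element values from a versioned config (C–H 1.09 Å, N–H 1.01 Å, O–H
0.96 Å; methyl C–C 1.54 Å with tetrahedral hydrogens staggered against the
stub's remaining substituents). Fixed lengths rather than a force-field
relaxation are deliberate: the method is single-point by design, and a
relaxation would move the cap geometry away from the bond it replaces.

Two conventions matter downstream:

* **NH excludes caps**, for hydrogen *and* methyl caps. The heavy-atom
  count in $GE_j$ describes the fragment as a part of the ligand; caps are
  artifacts of the method. With hydrogen caps this also makes
  $\sum_j NH_j = NH_{ligand}$, so the identity
  $\sum_j GE_j \cdot NH_j = |\Delta E_{mol}|$ holds exactly (tested on
  random partitions to 1e-9).
* Formal charges of retained atoms are unchanged — a carboxylate fragment
  is scored as the anion it is in the complex.

A known caveat, reported rather than corrected: the caps of two adjacent
fragments both occupy the neighborhood of the cut bond, so that region is
double-counted across the capped-fragment scores. With hydrogen caps the
effect enters only through geometry (hydrogens contribute no pairs to the
built-in scorer); with methyl caps the heavy cap atom does score, and its
contribution is accepted as method noise.

## The built-in scoring function

The built-in backend is an empirical pairwise function of the surface
distance $d = r - R_i - R_j$ between heavy atoms: two Gaussians
($e^{-(d/w_1)^2}$ and $e^{-((d-o_2)/w_2)^2}$), a quadratic repulsion $d^2$
for $d<0$, and piecewise-linear hydrophobic (both atoms hydrophobic) and
hydrogen-bond (donor–acceptor pairs) ramps. Two parameter sets ship in a
versioned config: `vina_default` (weights −0.035579 / −0.005156 / 0.840245
/ −0.035069 / −0.587439; Gaussian widths 0.5 and 2 Å at offsets 0 and 3 Å;
ramps 0.5–1.5 Å and −0.7–0 Å) and `vinardo_default` (single wider Gaussian,
weights −0.045 / 0.8 / −0.035 / −0.6, ramps 0–2.5 Å and −0.6–0 Å). The
vinardo variant here shares the vina radii table; its source's per-element
radius adjustments are not reproduced, and the `parameter_set_id` stamped
on every score records exactly which table produced it.

Numerical conventions:

* The pair cutoff (8 Å) applies to the **surface distance** $d$, matching
  the term interface, which receives only $d$. At $d = 8$ Å every term is
  below $10^{-3}$ in magnitude before weighting, so this choice is
  numerically indistinguishable from a center-distance cutoff while keeping
  `pair_terms()` self-contained.
* Hydrogens contribute no pairs (heavy-atom treatment); interaction typing
  is rule-based from a versioned table: carbon is hydrophobic unless bonded
  to N/O, halogens are hydrophobic, N/O accept, and N/O donate when they
  carry a hydrogen.
* Fragment scores are computed **without** the rotatable-bond entropy
  scaling $1/(1 + w_{rot} N_{rot})$: shares compare in-place interaction
  strength, and the entropic penalty belongs to whole-ligand,
  LE-style scores, where a flag enables it.
* Intramolecular terms are never computed (fixed conformation).

The vectorized scorer is verified against an independent scalar double-loop
reference (`oracle_score()`, separate formulas and typing code) to 1e-9 on
random fixtures, and its exact additivity over receptor subsets and rigid
frame invariance are property-tested.

External score-only programs join through a contract adapter (command
template, one-capture-group parse pattern, units, favorable direction); the
repository exercises the contract with mock shell backends only, so no
third-party binary is needed to build or test. Whether to partition an
external backend's whole-ligand score or an experimental affinity when both
exist is left to the user — both are accepted as $\Delta E_{mol}$, with the
source recorded.

## Shares, units and degenerate inputs

Scores are mapped to favorable-positive before the share is formed
(negative-is-better values are negated), which leaves all-favorable
kcal/mol shares identical to the raw ratio and gives positive-is-better
backends (pKd-like) the same convention. Two degeneracies are guarded:

* **Mixed signs** — one fragment scored unfavorable while others are
  favorable puts raw shares outside $[0,1]$; this errors by default, and an
  explicit `clip_to_zero` policy zeroes the unfavorable entries and flags
  the result.
* **Near-zero denominator** — $|\sum_i S_i| < 10^{-6}$ (backend units) is
  refused to prevent share blow-up; this is what a ligand placed beyond the
  cutoff produces.

Measured constants convert through $\Delta G = RT\ln(K)$ with
$R = 1.98720425\times10^{-3}$ kcal/(mol·K) at a configurable temperature,
default 298.15 K (the temperature is stamped into the provenance note
because published efficiencies rarely state it); IC50-derived energies are
flagged approximate. No scaffold rigidity bonus of any kind is applied to
anchor fragments — the analysis is kept directly comparable to plain LE,
and no option is provided to add one.

## Pose selection

When the analyzed geometry comes from docking, the pose to analyze is the
one whose **anchor fragment** (the experimentally positioned one) lies
closest to its crystal position: RMSD over corresponded heavy atoms,
computed **without superposition** because poses and reference share the
receptor frame — fitting would defeat the positional criterion.
Correspondence is explicit (atom-name matching by default, serial maps or
explicit pairs otherwise; at least 3 heavy atoms); symmetry-equivalent
mappings such as ring flips are deliberately not auto-detected. Ties within
0.01 Å go to the better docking score. Hydrogens are excluded (docking
hydrogens are unreliable).

## Consensus and decision flags

Because different scoring functions err differently, the analysis runs the
whole chain per backend and aggregates on **GE**, the unit-consistent
quantity — never on raw heterogeneous scores. Consensus is the unweighted
mean ± SD across backends; no weighting scheme is imposed. Flags follow the
method's decision heuristics:

* `below_threshold`: mean GE under 0.30 kcal/mol/atom (the customary LE
  threshold; configurable);
* `optimization_focus`: the below-threshold fragment with the lowest mean
  GE — the part of the molecule to redesign; when nothing is below the
  threshold the report states so explicitly;
* `anchor_violation`: raised when any non-anchor fragment's mean
  contribution magnitude reaches the anchor's. This operationalizes a
  qualitative warning — if a grown fragment contributes as much as the
  experimentally validated anchor, the binding mode likely contradicts the
  premise that grounded the optimization, and that geometry should not be
  used for further design. The comparison rule ($\geq$, with an optional
  slack factor) is this package's convention for that qualitative
  diagnostic.

## The synthetic fixture generator

`make_toy_complex()` emulates only what the algebra needs: a ligand of
bonded heavy atoms in fragments spaced beyond the cutoff, and isolated
receptor probe atoms at chosen surface distances, so each probe interacts
with exactly one fragment and the per-fragment scores — hence shares — are
known in closed form (e.g. 3 probes vs 1 at equal distance gives
$\omega = (0.75, 0.25)$ exactly). Fixtures are deterministic per seed,
round-trip through the PDBQT writer/reader, and validate under the scheme
checker. They are *not* realistic: no protein environment, no conformational
strain, no desolvation, no correlated contacts. Passing tests on fixtures
therefore demonstrates the correctness of the machinery — parsing, capping
geometry, term evaluation, partition algebra, decision logic — not the
scientific accuracy of any scoring function on real complexes, which is
bounded by the scoring power of the chosen backends.

## Problem sizes and numerical tolerances

The test and acceptance runs use 1000 random score vectors for the
partition invariants (normalization to 1e-12, conservation to 1e-9,
rescale invariance to ~1e-13), 500 random partitions for the GE identities
(1e-9), 100 random 30×10-atom complexes for scorer-vs-reference agreement
(1e-9), 25 generated ligands for fragmentation fidelity (coordinates
bit-identical; cap lengths to 1e-6 Å), and 50 random pose/reference pairs
for RMSD (1e-12). These sizes make every property check exhaustive enough
to catch term-level mistakes while keeping a full run in seconds.

## Known limitations

* Scores of adjacent capped fragments double-count the cut-bond region
  (see above).
* Crystallographic waters are stripped by default during preparation;
  water-mediated fragment contacts are thereby attributed to nothing. A
  keep option exists, but a kept water belongs to the receptor and its
  assignment among fragments is not modeled.
* The built-in backend's vinardo parameter set does not reproduce its
  source's radius adjustments.
* No automatic fragmentation (BRICS/RECAP-like) is provided, by design;
  protonation states and hydrogen placement are expected from external
  preparation tools.
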