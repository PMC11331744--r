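---
title: "Automatic molecular fragmentation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic molecular fragmentation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molfrag)
```

## The problem

Fragmentation methods make quantum-chemical calculations on large molecules
tractable: the system is split into monomers of roughly a target size
$n_t$, broken valences are saturated with hydrogen caps, and the total
energy is assembled with the many-body expansion (MBE)

$$E_{MBE} = \sum_I E_I + \sum_{I<J} \Delta E_{IJ} + \sum_{I<J<K} \Delta E_{IJK} + \dots$$

with $\Delta E_{IJ} = E_{IJ} - E_I - E_J$ and the analogous three-body
correction. Which bonds are cut matters: chemically similar-looking cut sets
can differ by tens of kJ/mol in the final energy error, and evaluating that
error directly requires the very full-system calculation that fragmentation
is meant to avoid. `molfrag` therefore scores candidate fragmentations with
a cheap six-penalty surrogate and minimises that score with a genetic
algorithm (GA) inside a recursive driver.

## The molecular graph

A structure (XYZ or PDB, Angstrom) becomes an attributed graph. Bonds and
bond orders are perceived from interatomic distances against a bundled
reference-length table: a bond exists when the distance is within the
longest tabulated reference for the element pair plus 0.25 Å, and the order
is the nearest reference. Hybridisation follows multiple-bond counts
(triple or two doubles → sp, one double → sp2, else sp3), with a second
pass that promotes N/O/S atoms adjacent to sp2/sp atoms into the π path —
this is what gives the pyrrole nitrogen its lone-pair contribution of two
π electrons and puts amide groups into three-atom O=C–N conjugated systems.
Conjugated systems are maximal connected sp2/sp components with at least
three atoms; each carries a conjugation score
$cs = \frac{1}{N_A}\sum_i N_e^i/N_A$.

The source material does not specify perception algorithms for
hybridisation or formal charge; the rules above are this package's choices,
validated against the worked molecular examples (pyrrole $cs = 6/25$;
methanol; 3-chloroprop-1-ene). Formal charges are trusted from input
metadata and default to zero.

### Hyperconjugated pairs

Donor/acceptor pairs combine one σ group with one π group at a graph
separation of one to three bonds. π groups: conjugated systems, isolated
C=C / C≡C (donor/acceptor), isolated C=O (acceptor), charged sp2 carbons,
and sp3 N/O lone pairs (donors). σ groups: C–H (donor/acceptor) and
C–halogen (acceptor). Three enumeration choices were genuinely open and are
resolved as follows:

* **Per-carbon precedence.** A halogen-bearing carbon contributes its
  C–X bond only, not its C–H bonds. This makes 3-chloroprop-1-ene contain
  exactly one pair (C=C donor, C–Cl acceptor) while propene keeps its
  allylic C–H pairs.
* **Orientation.** When both directions are admissible (two dual-role
  groups) the π group is the donor, matching the worked chloropropene
  assignment; each group pair is counted once.
* **C–H vs delocalised systems.** C–H σ bonds pair with *localised* π
  groups only, not with multi-atom conjugated systems; C–halogen acceptors
  pair with both. The disruption term (below) yields its maximum 0.95 for
  *any* cut that separates an intact donor from its acceptor, so if every
  backbone C–H paired with the adjacent amide system, any peptide backbone
  cut would cost $\approx 0.95\,\beta_{hyper} \approx 0.30$ — more than the
  largest possible volume-penalty saving ($0.5\,\beta_{vol} \approx 0.055$)
  — and no peptide would ever be fragmented. Restricting C–H partners to
  localised π systems preserves the worked examples and the observed
  behaviour that backbone cuts are feasible, with amide cuts ranked worst
  through the conjugation penalty.

## The score

A fragmentation is a binary vector over *allowed edges*: order-1 bonds that
are bridges of the graph (ring bonds are never cut — severing one leaves
the molecule connected, so capping would be ill-defined) and whose removal
leaves both sides at least $\lceil 0.6\,n_t \rceil$ atoms. Its score is

$$s = \beta_{pe} p_{pe} + \beta_{conj} p_{conj} + \beta_{hyper} p_{hyper}
    + \beta_{vol} p_{vol} + \beta_{comp} p_{comp} + \beta_{vrange} p_{vrange}$$

with non-negative weights summing to one. The shipped defaults are the
published optimum with the component-count term removed
(`default_weights()`; the six-decimal reference values sum to 1.000001, so the
normalisation check accepts 1e-5). All sigmoid steepnesses derive from one
convention: a logistic is "saturated" when it is within 5% of its
asymptote.

* **Potential energy** — two mirrored logistics of
  $\Delta_{pe} = E_{tot} - E_{MBE1}$ (kJ/mol; whole-system force-field
  energy minus the sum of capped-monomer energies), with steepness
  $\lambda = 1.963$ and offset $d = 6$, scaled by
  $\gamma = \sqrt{N_f}\,N_A^{min}/n_t$. The reference values of $\lambda$
  and $d$ are used verbatim; note $\lambda = 2\ln 19/3$ corresponds to
  5%/95% boundary points at 1 and 4 on the $\Delta_{pe}$ axis rather than
  at 10 and 40 kJ/mol, so the constants and the boundary-point reading
  cannot both hold — the constants win. $\gamma$ uses
  cap-exclusive atom counts: caps are artifacts of the cut, not of the
  target size.
* **Conjugation** — for each conjugated system containing a broken bond,
  $\Delta_{conj} = \frac{1}{cs}(\frac{1}{N_A}\sum_i N_e^i/N_A^i - cs)$
  where $N_A^i$ counts system atoms still connected to atom $i$; the odd
  normaliser $S(x) = \tanh(\lambda x/2)$ is fixed per system by
  $S(N_A - 1) = 0.95$, i.e. $\lambda = \ln 39/(N_A-1)$.
* **Hyperconjugation** — mean of $S(\Delta_{hyper})/\gamma_k$ over
  disrupted pairs ($\gamma_k$ = donor–acceptor bond separation). A pair is
  disrupted when a broken bond lies inside either group or the groups no
  longer share a fragment. A donor fragment contributes the electrons its
  donor atoms still donate over its donor-atom count; an acceptor fragment
  receives the donated electrons only when the entire donor shares its
  fragment. $S(N_e/N_A^d) = 0.95$.
* **Volume** — fragment volumes use hard spheres minus pairwise Gaussian
  overlaps over *all* intra-fragment atom pairs (van der Waals radii,
  amplitude $2\sqrt 2$), caps included since the capped geometry is what a
  backend evaluates. The penalty is a sigmoid (exponent 14.654) of the
  squared mean relative deviation from the reference volume
  $V_{ref} = n_t \frac{1}{N_A}\sum_s N_s V_s$, where the per-element
  characteristic volume subtracts only the *mean* overlap with bonded
  neighbours. Two consequences are worth knowing: the shipped exponent
  gives $p_{vol}(|\Delta_{vol}| = 0.5) = 0.975$ rather than a 0.95
  boundary point; and because
  $V_{ref}$ ignores non-bonded overlaps it systematically exceeds the
  all-pairs volume of a fragment with exactly $n_t$ atoms, so
  volume-balanced fragments sit somewhat above the nominal target for
  hydrogen-rich systems. The driver compensates structurally (below).
* **Volume range** — logistic ($\lambda = 11.78 \approx \ln 19/0.25$,
  $d = -0.25$) of the relative spread $(V_{max} - V_{min} - V_{ref})/V_{ref}$,
  discouraging uneven fragment sizes.
* **Component count** — $1/N_f$; retired (statistically insignificant
  weight) and carried with weight zero behind a flag.

Penalties are clamped to $[0, 1]$, so $s \in [0, 1]$ for normalised
weights, and every geometric ingredient is distance-based, making the score
invariant under rigid motion.

## Energy backends

The production backend is single-point UFF through Open Babel's `obenergy`
(kJ/mol; kcal/mol outputs are converted at 4.184). Because the scoring and
MBE machinery only need a deterministic `geometry → energy` function,
closed-form toy backends (per-atom additive; additive + Gaussian pair term;
a variant with a genuine three-body term) are first-class `ff_backend`
objects. They make exact bookkeeping properties testable: the two-body MBE
is exact for a pairwise Hamiltonian, the three-body MBE for the three-body
one — evaluated on uncapped subsets (`cap = FALSE`), since capping is a
separate approximation layered on top of the expansion.

A cut edge's dimer correction $\Delta E_{IJ} = E_{IJ} - E_I - E_J$ (union
with the edge restored, other caps retained, no relaxation) screens
chemically damaging cuts: during the first ten GA iterations, edges
exceeding 10 kJ/mol are blacklisted and forced to zero in every individual.
Memoisation keys on the edge plus the broken edges touching the two
fragments, so each context is evaluated once.

## The optimiser

Each GA individual is a cut vector. Defaults follow the published settings
where stated: at most 100 iterations, stop after 50 without improvement,
blacklisting in the first 10 iterations, two parents for populations of
eight or fewer and $\lfloor 0.25 \cdot \text{population} \rfloor$
otherwise. Population size (16), tournament size (3), per-gene mutation
probability ($1/|\text{genes}|$), elitism (best 1) and the initial-guess
padding flip rate (0.1) are this package's defaults, all configurable.
Mutation applies to offspring only.

Initial guesses come from geometry: primitive monomers (all allowed edges
cut) are grown breadth-first into fragments, starting from the unvisited
monomer nearest each reference point and stopping at 90% of the target
size. Reference points split the bounding box in the principal
inertia frame into $\lceil N_A/n_t \rceil$ equal intervals along the axis
of largest spatial extent (largest extent, not largest eigenvalue, so
degenerate inertia tensors of near-linear molecules need no special case);
as a set they are invariant under rigid motion and reflection. Nearest-monomer
ties break towards the lowest atom index.

## The recursive driver

`fragment_system()` cuts in stages: a GA stage aims at
$n_{stage} = N / \max(2, \lceil N/(2 n_t)\rceil)$ — about $2 n_t$ for large
systems, half the fragment in the endgame — and any resulting fragment
with more than $n_t$ bare atoms recurses on its own subgraph (caps
stripped, so cap hydrogens are never cut sites; the final fragment set is
re-capped on the full system). Two design points deserve their rationale:

* The stage divisor uses `ceiling` and has no $n_t$ floor. Rounding down
  the piece count produces fragments just above $2 n_t$ whose halves land
  in the dead zone $(n_t, 2\lceil 0.6 n_t\rceil)$ — oversized yet
  unsplittable under the 60% rule. Ceiling errs towards one more, smaller
  piece (a 174-atom peptide at $n_t = 20$ gives five first-stage fragments
  of ~35 atoms), and removing the floor lets the endgame halve a
  marginally oversized fragment instead of deadlocking. Final sizes
  therefore sit at or below the target, consistent with published
  size distributions that cluster below $n_t$.
* At a recursion stage the uncut state is infeasible (`forbid_uncut`).
  The driver's contract is that oversized fragments undergo further
  fragmentation; "do nothing" is not a candidate there. Without this, the
  $V_{ref}$ bias described above can make a 1.5×-target fragment score
  better whole than halved.

Stage RNG seeds derive from the master seed and the recursion path, so a
full run is bit-reproducible. Oversized fragments with no allowed edges are
returned as-is with a warning.

## Weight tuning

`tune_weights()` reproduces the published optimisation loop with a
pluggable inner objective
$f = \alpha\,\overline{p_{vol}} + (1-\alpha)\,\overline{S(|\Delta E|)}$
($\alpha = 0.5$; $S$ logistic with 5%/95% boundary points at 1 and 4
kJ/mol, applied to $|\Delta E|$ since the sign of the error carries no
quality information). The 16-row initial grid is shipped verbatim. The
Gaussian-process surrogate uses an RBF kernel with length scale and noise
variance 1 (the published settings; deterministic toy objectives should
pass a small `noise`), a direct Cholesky posterior, and expected
improvement maximised over the probability simplex by candidate sampling —
half global Dirichlet draws, half concentrated Dirichlet perturbations of
the incumbent (4096 candidates/iteration by default). Stopping follows the
published 200-iteration stagnation rule. The original inner objective
(two-body fragmentation errors at HF/6-31G* over 800 proteins) is out of
scope; the loop accepts any callable, and tests drive it with toy
backends and synthetic objectives with known simplex minima. No GP/Bayesian
optimisation package is pre-installed in the supported environment, so the
posterior and acquisition are implemented directly (about thirty lines).

## Synthetic fixtures and what the tests show

`build_named_molecule()` provides idealised geometries (planar pyrrole
with single/double bond alternation chosen so distance-based perception is
unambiguous; chloropropene numbered as in the worked example; an
18-carbon fatty-acid-like chain). `build_chain()` generates extended
glycine/alanine peptides (7 atoms per residue + termini; an alanine adds
3 — 24 residues with one alanine give the 174-atom benchmark fixture) and
alkanes ($3n + 2$ atoms), with a seeded coordinate jitter of at most
0.02 Å. These chains exercise every bond class of the manual comparison
schemes (amide C–N, Cα–N, Cα–C) and carry per-residue amide conjugated
systems, but they are *extended, single-chain, glycine-dominated* models:
no folds, no non-bonded contacts between distant residues, no charged side
chains, no solvent. Passing tests therefore demonstrate the correctness of
perception, scoring, optimisation and assembly on tree-like covalent
topologies — not chemical accuracy on folded proteins, which would require
the ab initio benchmark explicitly out of scope here.

Problem sizes used in the shipped tests and acceptance checks: alkane
chains of 10–15 carbons (GA-vs-exhaustive equivalence over 20 seeds at
≤ 12 allowed edges, i.e. ≤ 4096 enumerated states per chain), the 174-atom
peptide for the recursive contract, and 3-dimensional simplex objectives
for the tuner. These sizes were chosen so every exhaustive oracle remains
exact rather than sampled.

## Numerical choices and degenerate inputs

* Overlapping atoms (< 0.3 Å) are a hard perception error naming the pair.
* Element pairs missing from the bond-length table fall back to the sum of
  Cordero covalent radii as a single-bond reference; elements outside the
  bundled radius table are a hard error.
* Caps land on the severed bond axis at fraction
  $(r_i + r_H)/(r_i + r_j)$; collinearity holds to 1e-10 Å by
  construction.
* Conjugation scores reproduce from their π-contribution maps to 1e-12.
* A single fragment has $V_{range} = 0$, giving the near-zero
  volume-range penalty; $N_{cs} = 0$ or $N_{hs} = 0$ define the
  corresponding penalty as exactly 0.
* GA score evaluations are memoised by bit pattern; the uncut state's
  $\Delta_{pe}$ is exactly 0 by construction, not by cancellation.

## Known limitations

Ring bonds are never cut, so densely fused polycyclic systems may be
unfragmentable at small targets (reported with a warning). Perception
trusts geometry: badly distorted inputs yield wrong orders, and no
kekulisation, tautomer or protonation handling is attempted. The UFF
backend shells out to `obenergy` per evaluation, which is the cost
bottleneck when used inside the GA; the dimer-correction memoisation
mitigates but does not remove this. Fragment sizes are controlled through
the volume model, not atom counts, so hydrogen-rich systems equilibrate
slightly below (after the driver's staging) the nominal target.
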