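---
title: "Partner identification from complete cross-docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner identification from complete cross-docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockmate)
```

## The problem and the model

Complete cross-docking (CC-D) docks every protein of a set against every
protein of the set, including itself. The premise of this package is that
the resulting conformational ensembles — even those of non-interacting
pairs — carry systemic information: where on each surface ligands tend to
dock, how favourably each pair can be posed, and how *sociable* each
protein is overall. dockmate turns that information into a partner-ranking
matrix in four steps.

**1. Coarse-grained rigid-body docking.** Each residue becomes one bead at
the Cα position plus zero (Gly), one, or two side-chain beads placed at
the centroids of heavy-atom groups given by a versioned parameter table
(`inst/extdata/cg_params.json`). Charged residue types (Lys, Arg, Asp,
Glu) carry a net point charge on their second side-chain bead. The docking
energy of a pseudoatom pair at distance $r_{ij}$ is the soft 8-6 form with
a distance-dependent dielectric $\epsilon = 15r$:

$$E_{ij} = \frac{B_{ij}}{r_{ij}^8} - \frac{C_{ij}}{r_{ij}^6}
  + \frac{q_i q_j}{15\, r_{ij}^2}.$$

A 12-6 variant with constant dielectric $\epsilon = 10$,

$$E_{ij} = \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{12}
  - \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{6}
  + \frac{q_i q_j}{10\, r_{ij}},$$

is available for re-scoring: its repulsion decays faster with distance (a
softer treatment of clashes) and its electrostatics persist longer.
External per-conformation scores (for instance assembly-stability scores
computed by other programs) can be ingested as a third energy column.

**2. Conformation scoring.** Every docked conformation of an ordered pair
$(P_1, P_2)$ is evaluated as the product of three successive filters: the
fraction of the docked interface (DI, residues of the two partners closer
than $d$ Å) composed of residues of the reference interfaces (RI),
$FIR = FIR_{P_1} \times FIR_{P_2}$; the docking energy $E$ (negative =
favourable); and optionally a statistical pair-potential factor. The
interaction index is the minimum product over the pair's conformations,

$$II_{P_1,P_2} = \min_c \big( FIR \times E\; [\times PP] \big),$$

with $II = 0$ when no conformation achieves a negative product (no
favourable scored pose). The receptor and ligand surfaces are explored
asymmetrically by the surface-restrained protocol, so $II_{P_1,P_2}$ and
$II_{P_2,P_1}$ come from different docking runs and need not be equal.

**3. Sociability normalisation.** Indiscriminate, "sticky" binders score
well against everything; dividing by how much each protein binds overall
demotes them. The sociability index is

$$S_{P_i} = \frac{1}{2|P|}\sum_{P_j \in P}\big(II_{P_i,P_j} + II_{P_j,P_i}\big),$$

including the self pair. The weighted index is
$II'_{P_1,P_2} = II_{P_1,P_2}/\sqrt{|S_{P_1}||S_{P_2}|}$, symmetrised and
rescaled by the strongest indices each protein attains:

$$NII_{P_1,P_2} = \frac{\min(II'_{P_1,P_2},\; II'_{P_2,P_1})}
 {\big|\min_P II'_{P_1,P}\cdot \min_P II'_{P,P_2}\cdot
       \min_P II'_{P,P_1}\cdot \min_P II'_{P_2,P}\big|^{1/4}}.$$

Finally each protein's row is divided by its strongest entry, so the
predicted best partner scores exactly 1 and all values are clamped to
$[0, 1]$. Normalisation can run over the whole set or within functional
classes.

**4. Evaluation.** Partner discrimination is measured by the rank-sum AUC
of known pairs against all other candidate pairs, and by $P_{topX}$, the
proportion of proteins with at least one known partner ranked in the top
X% of candidates, compared with the partner-count baseline
$\frac{1}{N}\sum_i \mathbf{1}[\frac{X}{100} N_i \ge 1]$. Known pairs can
be extended by homology transfer: a pair is positive if cluster-mates of
its chains form a complex with an interface of strictly more than 5
residues, with multi-chain proteins positive as soon as one chain pair
interacts.

## Reference interfaces

Three sources of reference interfaces are supported.

*Experimental*: detected on bound complex coordinates at $d = 5$ Å
(strict inequality, heavy atoms for atomic structures, pseudoatoms for
coarse-grained ones).

*Predicted*: surface patches grown in three stages — seed, extension,
outer layer — from four per-residue descriptors, all in $[0,1]$:
evolutionary conservation `tjet` (supplied externally; a Shannon-entropy
fallback over an alignment is provided as plumbing, and an uninformative
constant 0.5 is used when nothing is available), interface propensity `pc`
of the amino-acid type (a bundled, configurable table), circular variance
`cv` over a 12 Å neighbourhood (low = protruding), and the
docking-inferred binding propensity `nip` (normalised frequency of
appearing in the docked interfaces of the top 10 lowest-energy
conformations against every partner). Four strategy families combine the
descriptors differently: `SC-juxt` juxtaposes four single-descriptor-set
schemes; `SC-mix` multiplies NIP in at every stage; `SC-monoSeed-mix`
seeds without NIP and mixes it into the growth stages; `SC-dockSeed-mix`
seeds on NIP alone and grows with all four. Stage scores are products of
the selected descriptors (CV entering as $1 - CV$). Each scheme runs 10
times with a stochastic seed-cluster tie-break; residues present in at
least 2 of the 10 runs form the consensus, clustered into connected
patches on the 5 Å surface graph. In oracle mode (used whenever known
interfaces are available for assessment) the patch or union of up to 3
patches maximising F1 against the known interface is retained; in blind
mode the union of consensus patches is used.

*Shifted decoys*: same-size corruptions of an interface used to probe the
sensitivity of partner identification to interface approximation. Each of
$m = \mathrm{round}(f \cdot N)$ iterations removes a border interface
residue $r_s$, finds the interface residue farthest from it, and adds one
of that residue's surface neighbours outside the interface; the standard
series generates 10 decoys at each shift level from 10% to 100%. The swap
bookkeeping gives F1 $= (N - m)/N$ against the source, e.g. 0.9 at a 10%
shift.

## The pair potential

The contact potential is a residue-level interface log-odds table trained
from bound complexes: with contacts defined at 5 Å,

$$s(a,b) = \log\frac{f_{obs}(a,b) + \lambda}{f_{exp}(a,b) + \lambda},$$

where $f_{obs}$ is the observed frequency of the type pair among interface
contacts and $f_{exp}$ the product of the marginal contact-endpoint type
frequencies ($\lambda = 10^{-3}$ by default). Pre-computed scores from any
external pair potential can be ingested per conformation instead. Because
multiplying a signed energy by a signed score can flip the sign of the
product, PP scores enter the interaction index through an affine min-max
map onto $(\delta, 1]$ within each pair's conformation set
($f = \delta + (1-\delta)(s - \min s)/(\max s - \min s)$, floor
$\delta = 10^{-3}$): the best conformation keeps its full energy, worse
ones are attenuated, ordering is preserved, and signs never flip. A raw
product mode is available behind a flag. An optional prefilter retains
only the top fraction of conformations by PP score before the minimum.
One caveat worth knowing: the log-odds enrichment of a pair *saturates*
when that pair dominates the training contacts (its marginals grow with
it), so adding more complexes of an already-dominant pair type can lower
its score; enrichment grows monotonically only while the pair's types also
appear in diverse other contacts.

## Hyper-parameter grid

Four parameters drive the scoring: the DI distance threshold
$d \in \{4.5, 5, 6\}$ Å, the patch strategy (4 families), the energy
(8-6, 12-6, or external) and the pair potential (on/off) — a
$3 \times 4 \times 3 \times 2 = 72$-combination grid with predicted RIs,
or $3 \times 3 \times 2 = 18$ with experimental RIs (the strategy
dimension disappears). Combinations are ranked by the subset-size weighted
mean AUC over the functional classes plus the whole set; the argmax is the
global default. Per subset, the top 20% (ceiling: 15 of 72) or top 30%
(6 of 18) combinations are pooled and partitioned by each parameter's
values (mean, max, mean ± 2 SEM per value). A non-default value with a
higher pool mean overrides the default for that subset only if a
two-sided Mann-Whitney U test over the full per-value AUC distributions
gives $p < 0.01$. The recommended defaults are $d = 5$ Å,
`SC-dockSeed-mix`, the 8-6 energy, pair potential on.

## The synthetic study conditions

All tests run on a seeded fixture module; nothing is downloaded. Its toy
proteins are quasi-spherical shells of ~42 single-bead pseudo-residues
(bead $\sigma = 4$ Å, well depth 0.3, spacing 4.2 Å so the 5 Å surface
graph is connected, 0.15 Å positional jitter). Each protein carries one
designed 8-residue interface patch: a flattened polar cap embossed with a
bump/recess relief of ±1.2 Å and charged with ±24-unit charges. Cognate
pairs carry mirror-image patches with complementary relief and opposite
copies of the same charge code; the codes of different pairs are mutually
orthogonal (Hadamard rows), and the relief pattern is deliberately a
*different* orthogonal code from the charges so that the geometric
displacements do not systematically push like charges together. At
generation time the bound pose is asserted to score below the 5th
percentile of 100 random contact poses under the 8-6 energy without
cutoff, and removing the charge complementarity measurably shrinks that
advantage.

Two data routes exist. The *docking route* runs the real engine
(start-pose generation, minimisation, interface annotation) and is used to
validate the docking machinery itself — determinism, descent, pair
enumeration, oracle equality of the energy sums. The *planted route*
(`make_scored_store()`) bypasses docking and plants per-pair conformations
with controlled docked interfaces, energies and PP scores: each cognate
pair gets one near-native conformation (docked interfaces equal to the
designed patches, energy −10), every pair gets one weak patch-mimic
conformation (energy in [−1.5, −0.5]; non-interactors also dock onto
binding sites), and the rest are random-patch decoys. The planted route is
what the idealized end-to-end check uses: with zero noise, every cognate
partner is ranked first and the AUC is exactly 1; Gaussian energy noise of
increasing standard deviation (0–8, against the 8.5-unit native/mimic
gap) degrades the mean AUC monotonically over 5 seeds. An optional
*sticky* protein binds every partner strongly (energy −8); the
sociability normalisation visibly lowers its score as a candidate partner
relative to the row-scaled raw indices.

What the toys do **not** emulate: real side-chain packing, sequence
realism, conformational change on binding, realistic decoy roughness, or
the physics that makes real cognate poses globally optimal at full
docking resolution — the soft 8-6 potential at this bead scale makes any
surface contact comparably attractive, so pose-level cognate
discrimination through the toy *docking* route is weak by construction.
Passing tests therefore demonstrate the correctness of the scoring,
normalisation and evaluation machinery on controlled CC-D data, not
docking accuracy on real proteins.

## Numerical choices

- **Sign convention**: favourable energies are negative; minima select the
  strongest interaction. The normalisation formulas are ill-defined for
  mixed signs, so square and fourth roots take magnitudes with the
  numerator's sign carried through, and $|S|$ and the four denominator
  minima are floored at $\epsilon = 10^{-9}$.
- **Row scaling**: the row "extreme" is the most negative NII, or the
  largest entry when no entry is negative; all-zero rows stay zero with a
  warning; outputs are clamped to $[0,1]$.
- **Distances**: "closer than $d$" is strict everywhere. Interface
  detection uses all heavy atoms (atomic) or all pseudoatoms
  (coarse-grained); decoy border/farthest/neighbour decisions use Cα
  positions; farthest-residue ties break to the lowest residue index.
- **Decoy swaps**: $m = \mathrm{round}(f N)$ with half-up rounding. Each
  swap preferentially moves a residue of the *source* interface out and a
  residue never in the source in, so F1 $= (N-m)/N$ holds for every seed;
  when no such candidate exists (deep shift levels) any eligible residue
  is used, which allows the small re-entry overlaps seen at the 100%
  level. The residue removed at one iteration is not eligible for removal
  at the next.
- **Energy cutoff**: 12 Å by default, no shifting; the oracle-equality
  tests disable it. A zero interatomic distance raises a clash error.
- **Minimiser**: derivative-free coordinate descent over the rigid degrees
  of freedom (radial + 3 rotational under the surface-restrained protocol;
  all 6 free), with geometrically shrinking steps (initial 1 Å / 0.25 rad,
  stop below 0.02 Å / 0.005 rad or at the energy tolerance $10^{-4}$). It
  is deterministic given the start pose and never returns a higher energy
  than it started with. This is a deliberate simplification of a full
  multiple-minimisation docking engine.
- **Patch growth**: stage thresholds are percentiles among the current
  candidates (seed top 15%, extension top 30%, outer top 40%), plus a
  relative admission floor — a joining residue must score at least half
  the current patch mean for the stage's descriptor product — so growth
  stops at the signal boundary instead of creeping over flat descriptor
  fields. At most 5 admission rounds per stage.
- **Ranking ties**: mid-ranks in the AUC; deterministic protein-id order
  in top-k lists. Self-pairs are included in sociability (the sum runs
  over all $P_j$) but excluded from partner ranking by default.
- **Retention rounding**: ceiling, matching the 15-of-72 and 6-of-18 pool
  sizes.
- **Baseline**: the $P_{topX}$ baseline indicator (expected count ≥ 1) is
  implemented exactly as stated, although a hypergeometric baseline would
  differ — fidelity over improvement.
- **Problem sizes**: the test suite and the acceptance script run at desk
  scale — 8-protein benchmarks (64 ordered pairs), 12 planted
  conformations per pair, docking runs of at most a few hundred
  minimisations, 80-residue decoy surfaces. These sizes are the package's
  declared study conditions for its synthetic checks; real CC-D campaigns
  use the same code paths at larger settings (`dock_settings()` defaults
  to 64 positions × 12 rotations per pair).

## Open design choices

Several points the method description leaves open were resolved as
follows, and are configurable where sensible. Multi-chain proteins are
coarse-grained as a single rigid body over the selected chain set, with
interfaces taken as unions over chains. "Surface residue" is defined as
relative solvent accessibility ≥ 0.25, computed by a Shrake–Rupley
numerical SASA (golden-spiral test points, probe 1.4 Å, per-element radii,
reference = the residue's own atoms in isolation). The per-protein scaling
of NII to $[0,1]$ is row-wise (per focal protein), because "the predicted
partner is the protein with NII = 1" is a per-protein statement. Whether
the pair potential enters as a raw score or a positive factor is not
fixed by the formulas; the factor transform is the default and the raw
mode is behind a flag. Missing side-chain atoms fall back to Cβ, then Cα,
with a warning. The side-chain bead placement table is authored here and
versioned with the package, making results reproducible without any
external parameter source.

## Limitations

The engine is a desk-scale reimplementation: it does not reproduce any
production docking program's numerics, flexible-interface refinement, or
FFT-scale sampling, and the patch predictor is a re-specification of the
seed/extend/outer-layer idea with declared thresholds rather than a port
of any particular tool. AUC values on real benchmarks depend on
grid-scale docking campaigns that are outside what a single CPU can
recompute; the package's verifiable claims are the analytic worked
examples and the controlled synthetic behaviours documented above.
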