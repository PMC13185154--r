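---
title: "Quantifying enzyme stabilization by shell confinement: methods and design"
author: "crowdq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enzyme stabilization by shell confinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Encapsulating an enzyme inside a protein shell — a bacterial microcompartment
(BMC) being the canonical example — can make it markedly more thermostable
than the same enzyme free in solution. Two computable observables capture the
mechanism at residue and whole-protein resolution:

* **Per-residue RMSF** (root-mean-square fluctuation) measures local
  flexibility. Comparing profiles between conditions as
  ΔRMSF = RMSF(solution) − RMSF(confined) localizes where crowding rigidifies
  (positive peaks) or, occasionally, loosens (negative peaks) the chain.
* **The soft fraction of native contacts Q** measures global fold integrity.
  Tracking the distribution of Q across temperatures in both conditions shows
  whether confinement suppresses thermally induced contact loss.

A third, geometric ingredient is the *design* of the crowded system itself:
how many cargo copies must be packed into the shell interior to reproduce a
cytoplasm-like volume fraction (φ ≈ 0.2), and how to place them without
steric clashes.

`crowdq` implements all three stages plus a synthetic conformational-ensemble
generator with known ground truth, so the entire pipeline is testable at desk
scale, without all-atom molecular dynamics.

## The observables

### RMSF and ΔRMSF

For the alpha-carbon of residue *i* with position $r_i(t)$ over an aligned
ensemble,

$$\mathrm{RMSF}(i) = \sqrt{\left\langle \lVert r_i(t) - \langle r_i
\rangle\rVert^2 \right\rangle_t }.$$

Design choices a user should know about:

* **Superposition.** RMSF is meaningless without a rigid-body fit.
  `superpose()` implements determinant-constrained (proper-rotation-only)
  least squares, either onto the first frame or onto the iterated mean
  structure (default; converges when the mean shifts < 1e-6 Å). The
  iterated-mean reference avoids biasing the profile toward whichever frame
  happened to come first.
* **Per-monomer treatment.** Homodimers (and multi-copy crowded systems) are
  analyzed one monomer at a time: each chain is superposed *independently*
  before its profile enters the position-wise average (`pool_monomers()`).
  Copies tumble freely inside a shell, so a global fit would count rigid-body
  motion as flexibility.
* **Replica averaging** (`average_replicas()`) is an unweighted mean:
  replicas are equal-length by design, and the profile's `n_replicas`
  metadata accumulates so provenance is never lost.
* **Equilibration discard.** The RMSF time average uses the entire ensemble
  by default (`discard_fraction = 0`); synthetic ensembles are stationary
  from frame one, and user-supplied trajectories can set a nonzero discard.

Region calling (`detect_regions()`) thresholds |ΔRMSF| at 2.0 Å and keeps
maximal runs of uniform sign at least 2 residues long. Two points are
deliberate: the criterion is applied to the *magnitude* with the sign
recorded, because negative regions (more flexible under crowding) are a real
and interesting outcome, not noise; and the 2-residue minimum suppresses
single-residue threshold crossings, which at realistic frame counts are
dominated by estimation noise. Both knobs are exposed.

### Fraction of native contacts

A native contact is an atom pair closer than 4.5 Å in the reference
structure with sequence separation |i − j| > 3 (excluding trivial local
contacts). Per frame,

$$Q(X) = \frac{1}{N} \sum_{(i,j)} \frac{1}{1 + \exp\!\big[\beta\,( r_{ij}(X)
- \lambda\, r^0_{ij})\big]},$$

with $r^0_{ij}$ the reference distance of the same pair, β = 5 Å⁻¹ the
switching sharpness and λ = 1.8 the tolerance allowing for thermal
fluctuation around the native distance.

* **Contact mode.** The literature definition of the pair set varies between
  heavy-atom pairs and Cα pairs. The default here is `alpha-carbon` (it is
  also the only mode available to Cα-only coarse models); `heavy-atom` mode
  is implemented and recorded in every output, with N counting atom pairs.
* **Numerics.** The logistic argument is clipped at ±500 before
  exponentiation. At that point the term is already 0 or 1 to machine
  precision, so clipping changes nothing measurable while preventing
  overflow.
* **Per-monomer evaluation.** `q_series()` maps a contact set built on one
  reference chain onto every congruent chain by residue position, yielding
  one labelled series per monomer; summaries pool monomers within a
  (condition, temperature) group and report median, mean, IQR and 5th/95th
  percentiles. Interfacial (inter-chain) contacts are out of scope.

### Packing design

`copy_number()` computes $N = \lfloor \varphi\,(R/r)^3 \rfloor$ under the
spherical assumption for shell interior (radius R) and cargo (radius r).
Floor, not rounding: the copy count must not exceed the capacity at the
stated fraction. Since the copy count is only reproducible once the radius
conventions are pinned, they are named and explicit:

* cargo `equal-volume`: radius of the sphere matching the summed residue
  volumes (mean residue volume 134 Å³ when residue identity is unknown);
  for a 500-residue dimer this gives 25.2 Å;
* cargo `max-extent`: maximum centroid-to-atom distance;
* shell `innermost-atom`: minimum centroid-to-shell-atom distance minus a
  probe margin (default 0 Å).

With a shell interior of 90 Å (innermost-atom) and a 500-residue cargo
(equal-volume, 25.2 Å), φ = 0.2 gives N = 9 — the copy count used for a
TPI-loaded HP shell at cytoplasmic crowding.

Placement (`place_copies()`) automates what is usually done by hand, as
seeded random sequential insertion: uniform candidate centers in the allowed
ball of radius R − r, accepted only at ≥ 2r from every accepted center, with
uniform random proper-rotation orientations. The acceptance predicate is
exactly the original constraint — no contact with other copies or with the
shell — but reproducible per seed. Infeasible requests fail loudly with the
number of copies placed. `clash_screen()` then re-checks the result (and,
for atomic assemblies, checks what sphere-level placement cannot see:
actual interatomic distances below 2.0 Å against other copies or the shell
wall). Flagged copies are recorded in the plan's exclusion list and dropped
from pooled analyses downstream — mirroring the practical reality that one
of nine placed dimers can turn out to clash and must be excluded, leaving
eight. Output tables report the achieved volume fraction both before and
after exclusion, since the effective crowding changes when a copy is
dropped.

## The synthetic ensemble generator

The ensembles this package was designed around come from microsecond-scale
all-atom MD, which is neither a reasonable test dependency nor deposited in
a reusable form. `crowdq` therefore generates its own ensembles at two
tiers with different purposes:

**Tier 1 — analytic Gaussian (`sample_gaussian_trajectory`).** Each frame is
the native structure plus independent Gaussian noise with per-coordinate
standard deviation

$$\sigma_i = \sigma_0 \sqrt{T/T_\mathrm{ref}} \cdot a_i \cdot s,$$

where $\sigma_0$ is the base scale (`base_sigma`), $a_i$ an amplification
factor on planted flexible regions, and $s \le 1$ a confinement suppression
factor. The expected RMSF is exactly $\sigma_i\sqrt3$, making every
downstream statistic verifiable against a closed form. The √T scaling is the
equipartition heuristic for harmonic fluctuations; it also produces the
qualitative thermal behavior of Q — gradual native-contact loss with
temperature in the free condition.

**Tier 2 — elastic-network Langevin (`simulate_enm_langevin`).** A Cα
elastic network (springs between pairs within 10 Å, at native lengths)
propagated by Euler–Maruyama overdamped Langevin dynamics with per-step
noise variance $2k_BT\,\Delta t/\gamma$. Confinement here is *mechanistic*:
a harmonic spherical wall plus repulsive crowder spheres propagated
alongside the chain, so fluctuation suppression emerges rather than being
dialled in. An optional harmonic tether to native coordinates makes the
single-particle harmonic well — the classical equipartition oracle, with
stationary per-coordinate variance $k_BT/k$ — expressible in the same
integrator. Construction rejects time steps with
$\Delta t\,k/\gamma \ge 0.25$ (and simulation re-checks the bound against
realized network connectivity) rather than diverging silently.

Boltzmann's constant is fixed at 0.0019872041 kcal/(mol·K) in a single
constants table (`cq_constants`), with coordinates in Å and times in ps
throughout; no observable converts units internally.

### Default study conditions

The generator defaults encode the paired study design, chosen once:

| parameter | default | rationale |
|---|---|---|
| temperatures | 25, 50, 65, 80 °C | the four-temperature paired design |
| `base_sigma` | 1.0 Å at 25 °C | RMSF ≈ 1.7 Å, typical of a folded core |
| `suppression` | 0.6 | baseline ΔRMSF ≈ 0.7 Å, below the 2 Å threshold, while leaving visible Q stabilization |
| planted flexible region | residues 40–48, ×3 (solution) | positive ΔRMSF ≈ 4.2 Å, twice the threshold |
| planted enhanced region | residues 20–24, ×5 (confined) | negative ΔRMSF ≈ −3.5 Å, the "more flexible when crowded" analog |
| `phi`, shell/cargo radii | 0.2, 90 Å, 25.2 Å | cytoplasmic volume fraction; the radii that give 9 copies |
| fold | 64-residue hairpin | cross-strand contacts guarantee a nonempty native-contact set |

The two condition specs must agree on chain length, fold, frame count,
fluctuation scale and reference temperature; they may differ in confinement
and in planted regions (which is what lets the generator exercise both signs
of ΔRMSF peak).

### What the generator does and does not emulate

It reproduces the *statistical structure* the analysis assumes:
temperature-scaled fluctuations, their suppression under confinement,
localized flexibility differences, and gradual thermal contact loss. It does
not reproduce anharmonicity, cooperative unfolding, solvent effects,
transient nonspecific protein–shell interactions, or any quantitative
mapping from confinement geometry to suppression — the suppression factor is
a free synthetic parameter, not a claim about a real shell. Passing tests
therefore validate the *estimators and the pipeline*, not any prediction
about a specific enzyme; conclusions about real systems still require real
trajectories, which the same functions accept through multi-model PDB or DCD
input.

## Numerical and interface choices

* **Trajectory formats.** Multi-model PDB is the portable, text-based format
  (lossless round trip at the format's 3-decimal precision); DCD
  (CHARMM-style, little-endian, single precision) is what MD engines emit.
  Readers validate before parsing: malformed ATOM records are reported with
  their line number, per-frame atom-count mismatches with their frame
  number, and an empty trajectory file is an error rather than an empty
  object.
* **Selections** are small declarative expressions
  (`"alpha-carbon"`, `"chain=A and residues=3..5"`); an empty selection is
  an error, because silently empty masks propagate confusing zeros.
* **Residue indexing** is 1-based PDB numbering; the |i − j| > 3 contact
  rule is residue-number arithmetic, so renumbering is never done behind the
  user's back.
* **Determinism.** Every stochastic stage takes an explicit seed, derives
  sub-stream seeds deterministically, and restores the caller's RNG state.
  Re-running `run_pipeline()` with the same configuration yields
  byte-identical tables; TSV numbers are written with fixed formatting to
  make that contract meaningful.
* **Degenerate inputs** fail in documented ways: single-frame ensembles give
  an all-zero RMSF with a warning flag in metadata; empty contact sets carry
  a warning and make Q evaluation an explicit error; collinear superposition
  masks are rejected; unstable Langevin time steps error at construction.

## Problem sizes

The test suite and the reproduction script run the Gaussian oracle at 20 000
frames (where the per-residue sampling error of RMSF is ~0.3%, comfortably
inside the 2% check), the paired four-temperature datasets at 5 000 frames
per condition, the single-particle Langevin runs at 5 × 10⁵ steps, and the
packing sweep over 100 seeds. These sizes were chosen so every statistical
check sits several standard errors away from its threshold while the whole
suite completes in about a minute.

## Known limitations

* The Gaussian tier has no inter-residue correlations, so it cannot test
  estimators of correlated motion (and none are included; PCA and
  fluctuation tensors are out of scope).
* The ENM crowder interaction is a soft harmonic repulsion, adequate for
  demonstrating excluded-volume suppression but not for quantitative
  crowding thermodynamics.
* Packing is sphere-based; shape-aware packing and energy minimization are
  out of scope, which is why the atomic-level `clash_screen()` exists as a
  second line of defense.
* `heavy-atom` contact mode counts atom pairs (not residue pairs); both
  conventions appear in the literature, and the choice is recorded in every
  output.
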