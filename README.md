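# crowdq

Confinement and crowding analysis of protein conformational ensembles.

Encapsulating an enzyme inside a protein shell — a bacterial
microcompartment (BMC) being the canonical case — can make it substantially
more thermostable than the same enzyme free in solution. `crowdq` is an R
package for the computational side of that question. Given conformational
ensembles of a protein in two conditions (free solution vs. confined in a
crowded shell) across a temperature series, it quantifies:

* **local flexibility** — per-residue root-mean-square fluctuations
  (RMSF) with rigid-body superposition, replica averaging and homodimer
  monomer pooling;
* **where confinement acts** — the difference profile
  ΔRMSF = RMSF(solution) − RMSF(confined), with detection of contiguous
  regions where |ΔRMSF| ≥ 2.0 Å (positive regions: more flexible free in
  solution; negative: more flexible when crowded);
* **global fold integrity** — the soft fraction of native contacts

  ```
  Q(X) = (1/N) Σ_(i,j) 1 / (1 + exp[ β ( r_ij(X) − λ r⁰_ij ) ])
  ```

  over native pairs (reference distance r⁰_ij < 4.5 Å, sequence separation
  |i − j| > 3), with β = 5 Å⁻¹ and λ = 1.8, summarized per condition and
  temperature;
* **crowded-system design** — the number of cargo copies needed to fill a
  shell interior to a target volume fraction (N = ⌊φ (R/r)³⌋; φ ≈ 0.2
  matches bacterial cytoplasm), seeded clash-free sphere packing inside the
  shell, and atomic steric-clash screening with exclusion of offending
  copies from pooled analyses.

Because the motivating ensembles come from large all-atom MD simulations
that are impractical as a test dependency, the package includes a
first-class synthetic generator with known ground truth: an analytic
Gaussian tier (expected RMSF is exactly σ√3) and an elastic-network
overdamped-Langevin tier in which confinement is an explicit wall with
crowder spheres. Real trajectories are read from multi-model PDB or DCD
files through the same interfaces.

## Worked example

Generate a paired free/confined dataset at two temperatures for a 64-residue
hairpin with a planted flexible region (residues 40–48, amplified ×3, free
condition only) and a planted crowding-enhanced region (residues 20–24,
confined condition only), then compute Q summaries and ΔRMSF regions:

```r
library(crowdq)

sf <- ensemble_spec(64, "hairpin", n_frames = 2000, base_sigma = 1,
                    flexible_regions = data.frame(start = 40, end = 48, amp = 3),
                    seed = 11)
sc <- ensemble_spec(64, "hairpin", n_frames = 2000, base_sigma = 1,
                    flexible_regions = data.frame(start = 20, end = 24, amp = 5),
                    confinement = list(radius = 45, suppression = 0.6),
                    seed = 11)
ds <- make_two_condition_dataset(sf, sc, c(25, 80) + 273.15)

cs <- reference_contacts(ds$structure)
#> cq_contact_set: 30 contacts (alpha-carbon, cutoff 4.50 A, |i-j| > 3)

q_summary(lapply(unname(ds$trajectories), q_series, contacts = cs))
#>   condition temperature    n median  mean    iqr   q05   q95
#> 1  confined         298 2000  0.936 0.940 0.0494 0.884 0.998
#> 2  confined         353 2000  0.932 0.929 0.0579 0.867 0.990
#> 3  solution         298 2000  0.864 0.862 0.0690 0.778 0.939
#> 4  solution         353 2000  0.836 0.834 0.0752 0.740 0.925

ca <- select_atoms(ds$structure, "alpha-carbon")
prof <- function(k) rmsf(superpose(ds$trajectories[[k]], ca), ca)
d <- delta_rmsf(prof("solution_353.15"), prof("confined_353.15"))
detect_regions(d)
#>   label start_residue end_residue     sign peak_value
#> 1     I            20          24 negative  -3.774569
#> 2    II            40          48 positive   4.475005
```

Reading the output: free-solution Q drops with temperature
(0.864 → 0.836) and has the wider spread, while confined Q barely moves
(0.936 → 0.932) — confinement suppresses thermally induced contact loss.
Region II recovers the planted flexible span exactly (residues 40–48, more
flexible in solution); region I is the negative peak (residues 20–24, more
flexible in the crowded environment).

Designing the crowded system at cytoplasmic volume fraction:

```r
copy_number(0.2, shell_interior_radius = 90, cargo_radius = 25.2)
#> [1] 9
plan <- place_copies(9, 90, 25.2, seed = 7, max_attempts = 1e5)
clash_screen(plan)   # 0 rows: placement honors both distance invariants
```

The full pipeline — generation, superposition, RMSF/ΔRMSF/regions, Q
series and summaries, packing plan, manifest — runs from a flat `key =
value` configuration:

```r
run_pipeline(validate_config("run.cfg"), out_dir = "results/run1")
```

and is byte-identical on re-run with the same configuration and seeds.

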