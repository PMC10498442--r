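# metalff

Molecular-mechanics force fields describe transition-metal centers poorly
out of the box: standard biomolecular and organic force fields have no
types, no bonded terms and no charges for a Cu, Mo or Co site and its
coordination shell.  The *bonded model* fixes this by treating every
metal–ligand contact as an explicit harmonic bond (plus angles and point
charges) whose parameters are derived from a quantum-mechanical Hessian of
the specific complex.  Setting this up by hand — perceiving connectivity,
splitting the system into fragments, extracting force constants, fitting
charges, assembling parameter files, solvating, and finally distilling
conformers out of a trajectory — is tedious and error prone.

`metalff` automates the computational core of that workflow for R users in
computational chemistry and structural modelling:

* **Bond perception and fragmentation** — atoms *i*, *j* are bonded when
  `d(i,j) < f * (r_i + r_j)` with van der Waals radii `r` and scale
  `f = 0.6`.  Contacts involving a metal are recorded separately and kept
  out of the fragment graph, so an iterative depth-first search splits the
  system into ligand fragments plus metal singletons, each with a
  user-assigned total charge.
* **Seminario bonded parameters** — for a bond *i–j*, the negated 3×3
  interatomic block of the Cartesian Hessian `A = −∂²E/∂r_i∂r_j` is
  eigendecomposed, `k(i→j) = Σ_m λ_m |û·v_m|`, the two directions are
  averaged, and the result is reported in the Amber convention
  `E = k_r (r − r_eq)²`.  Angles *i–j–k* combine the two arm projections
  perpendicular to each arm in series:
  `1/k_θ = 1/(R_ji² k_PA) + 1/(R_jk² k_PC)`.
* **RESP charges** — Merz–Kollman shells at 1.4/1.6/1.8/2.0 × vdW radius
  (deterministic Fibonacci sampling, 1 pt/Å²), then a restrained
  least-squares fit of point charges to the grid potentials,
  `min Σ_p (v_p − Σ_a q_a/r_pa)² + a Σ_a (√(q_a²+b²) − b)` subject to
  `Σ q_a = Q_total`, with the standard two-stage protocol when equivalence
  groups are given.
* **File assembly** — fresh atom types for the metal and its first
  coordination shell; Amber `frcmod` and TRIPOS `mol2` writers/readers.
* **MD setup** — solvent box packing at the template's experimental
  density on a jittered checkerboard lattice with a hard minimum-distance
  guarantee, face-placed counterions, and Amber mdin decks for a heating /
  cooling equilibration ladder plus a 100 ns NVT production run at 300 K.
* **Conformer analysis** — Kabsch alignment on a user atom list,
  heavy-atom RMSD matrices, clustering (`kmeans` as k-medoids,
  average-linkage `hierarchical`, `dbscan`, cutoff-kernel `dpeaks`),
  medoid representatives and energy ranking.

Quantum engines and MD engines are deliberately out of scope: the package
consumes their outputs (ORCA-dialect `.hess` files, energy tables) and
emits their inputs.  All synthetic fixtures (analytic harmonic Hessians,
point-charge ESP grids, labeled two-basin trajectories) are first-class,
tested code, so every stage can be exercised without external software.

## Worked example

A synthetic tetraammine Cu(II) complex ships as `demo_complex()` together
with a harmonic model whose analytic Hessian stands in for a quantum one:

```r
library(metalff)
dc <- demo_complex()
dc$structure
#> <xyzmol> 17 atoms, charge +2, multiplicity 1
#>   formula: CuH12N4

g <- detect_bonds(dc$structure)
g
#> <bondgraph> 17 atoms, 12 bonds, 4 metal contacts

frags <- assign_fragment_charges(find_fragments(g), dc$fragment_charges, 2L)
frags
#> <fragset> 5 fragments over 17 atoms
#>   F01: 1 atoms, charge +2
#>   F02: 4 atoms, charge +0
#>   ...

h <- analytic_hessian(dc$model, dc$structure)
seminario_bond(h, 1, 2)[c("k_r", "r_eq")]
#> $k_r   120       # kcal/mol/A^2 — the generating constant, recovered
#> $r_eq  2.05      # A
```

The Cu–N force constant comes back at exactly the value used to build the
Hessian (120 kcal mol⁻¹ Å⁻²).  The N–Cu–N angle estimate
(`seminario_angle(h, 2, 1, 6)` → 100 kcal mol⁻¹ rad⁻² for a generating
constant of 50) illustrates a property of the Seminario angle formula
discussed in the vignette: angles sharing an arm pool their curvature, so
angle constants are effective values, not term-by-term inverses.

RESP charges and parameter files:

```r
pts <- build_mk_grid(dc$structure)      # 930 Merz-Kollman points
v   <- point_charge_esp(q_ref, dc$structure$coords, pts)  # synthetic ESP
res <- parametrize_complex(dc$structure, h, esp_grid(pts, v),
                           dc$fragment_charges)
res$charges
#> <chargeset> 17 charges, sum +2.000000, rrms 9.832e-05
cat(res$frcmod)
#> MASS ... BOND
#> M1-Y1     120.0000     2.0500
#> ...
```

Solvation and input decks:

```r
box <- build_box(dc$structure, solvent_template("water"), margin = 6,
                 ions = list(ion_template("Cl", -1L)))
decks <- emit_inputs(sim_protocol())   # 8 equilibration stages + production
```

Trajectory clustering (a labeled two-basin fixture):

```r
tb <- two_basin_trajectory(50, displacement = 3, noise_sigma = 0.1)
t  <- align_trajectory(tb$trajectory, 1, 1:8)
cl <- cluster_frames(rmsd_matrix(t), "kmeans", k = 2)
cl <- rank_clusters(cl, c(3.0, 1.0))
cl
#> <clusterresult> kmeans: 2 clusters over 100 frames
#>   rank cluster  frames  rep  dE(kcal/mol)
#>      1       2      50   ..         0.000
#>      2       1      50   ..         2.000
```

A thin command-line wrapper over these functions lives at
`inst/cli/metalff.R` (subcommands `fragment`, `cluster`, `fixtures`).

## File formats

XMOL xyz (single and multi-frame), ORCA `$hessian` text dialect or plain
whitespace matrices (units converted from hartree/bohr² when applicable),
plain `x y z value` ESP grids (Å / atomic units), Amber frcmod (force
constants stored in the `k(x − x₀)²` convention, no half-k applied),
TRIPOS mol2, Amber mdin, and whitespace `cluster energy` tables.
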