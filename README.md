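# chainscales

Geometry statistics and Monte Carlo for tangent-sphere chains and protein
backbones.

Coarse-grained polymer models and real protein backbones can be compared
with the same geometric yardsticks: the bond-bending angle θ and dihedral
μ of consecutive monomers, the radius R of the circle through three points
(locally, the discrete radius of curvature R = b / (2 cos(θ/2)) for bond
length b), the radius of the sphere through four points, and the distance
from each monomer to its nearest *non-local* neighbour (sequence
separation |i − j| ≥ 3).  `chainscales` is for polymer physicists and
structural bioinformaticians who want these statistics as tested,
reproducible code:

* **Geometry kernels** — angles, three-body circumradii (R = abc/4A),
  four-body circumsphere radii via the equidistant-center linear system,
  (θ, μ) maps, nearest-contact maps with a 6 Å near/far flag, and
  characteristic local/non-local length scales with a documented mode
  estimator.
* **Distribution theory** — for a d-dimensional fixed-bond random walk,
  p(θ) ∝ sin^(d−2) θ and the inverse radius X = 1/R has density
  P(X) ∝ (Xb)^(d−2) [1 − (Xb/2)²]^((d−3)/2), so the CDF of X follows a
  power law with exponent d − 1 (exactly (Xb/2)² in 3D).  Closed forms,
  normalizations and a log–log slope fitter are included.
* **Monte Carlo** — an Rcpp engine for the tangent-hard-sphere chain
  (σ = b = 3.81 Å) with square-well attraction (range 1.6 σ, depth ε):
  crankshaft / reptation / endpoint / pivot moves, Metropolis sampling at
  any reduced temperature including T = ∞, replica exchange on a
  0.3–4 ladder, and WHAM specific heat C_V/Nk_B.
* **Synthetic data** — fixed-bond random walks in any dimension,
  plane-constrained walks, uniform ball points, self-avoiding segments,
  and ideal α-helix / β-sheet Cα traces with ground-truth labels.
* **Protein ingestion** — Cα traces from PDB files (via bio3d),
  trans/cis classification, DSSP label parsing, per-class length-scale
  tables.

## Worked example

```r
library(chainscales)
set.seed(42)

# power law of the inverse circumradius for 3D fixed-bond walks
w   <- random_walk_batch(200000, n_steps = 2, d = 3, b = 3.81)
cdf <- inverse_radius_cdf(walk_triplet_inverse_radii(w), b = 3.81)
fit_loglog_slope(cdf)
#> [1] 1.99

# an ideal alpha-helix C-alpha trace and its contact signature
helix <- ideal_alpha_helix(30)
helix
#> <conformation> 30 monomers, b = 3.829778 A, labels: alpha:30
head(contact_map(helix), 3)
#>   i j distance separation near
#> 1 1 4 5.053712          3 TRUE
#> 2 2 5 5.053712          3 TRUE
#> 3 3 6 5.053712          3 TRUE
per_class_statistics(helix, classes = "alpha")
#>   class local_mode nonlocal_mode n_triplets n_monomers
#> 1 alpha   2.702703      5.063291         28         30
```

The fitted slope 1.99 is the d − 1 = 2 power law of three-dimensional
walks.  Every helix residue finds its nearest non-local neighbour exactly
three positions away at ≈ 5.05 Å (within the 6 Å contact threshold), and
the helix geometry pins the local radius of curvature near 2.70 Å — the
two characteristic length scales of α-structure.

Simulation-backed analyses run the same way:

```r
model <- square_well_model(n = 80)          # sigma = b = 3.81 A, R_att = 1.6 sigma
inf   <- run_infinite_temperature(model, sweeps = 50000)
snapshot_length_scales(inf$snapshots, model$sigma)
re    <- run_replica_exchange(model, ladder = replica_ladder(2),
                              snapshot_temps = 0.3)
wham_specific_heat(re, T_grid = seq(0.3, 2, 0.02))
```

Named end-to-end analyses (CDF experiments, (θ,μ) maps, length-scale
tables, contact maps, C_V curves) are packaged as
`run_experiment(<name>, out_dir, seed)`, each writing CSV products plus a
`summary.json` with the seed and a config hash; `inst/scripts/chainscales`
is a thin command-line front end over the same function.

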