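---
title: "Methods: chain geometry statistics and tangent-sphere Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chain geometry statistics and tangent-sphere Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainscales)
```

# The scientific problem

A linear chain molecule can be summarized locally by two angles — the
bond-bending angle $\theta$ at each monomer and the dihedral $\mu$ of each
quartet — and by two families of radii: the circle through three points
(whose local version is the discrete radius of curvature) and the sphere
through four points.  Local triplets probe curvature; non-local pairs probe
how closely two parts of the chain approach.  `chainscales` implements
these kernels together with a Monte Carlo sampler for the simplest
attractive homopolymer — the tangent-hard-sphere chain with a square-well
potential — so that polymer ensembles and protein C$_\alpha$ traces can be
compared with the same geometric yardsticks.

# The model

The chain is $n$ hard spheres of diameter $\sigma$ with bond length fixed
to exactly $\sigma$ (consecutive spheres touch).  Non-adjacent pairs
$|i-j|\ge 2$ interact through a square well: energy $-\varepsilon$ when
their distance is at most $R_{att} = 1.6\,\sigma$, zero beyond, infinite
inside the hard core.  $\varepsilon$ sets the energy unit, so total
energies are integer contact counts and temperatures are reduced
($k_BT/\varepsilon$).  Defaults: $n = 80$, $\sigma = b = 3.81$ Å — the
mean C$_\alpha$–C$_\alpha$ distance of a trans peptide, which makes the
polymer and protein length scales directly comparable.

## Key relations

For a fixed-bond chain the local triplet circumradius depends only on the
bending angle,

$$R \;=\; \frac{b}{2\cos(\theta/2)},$$

so the steric floor $\theta \ge 60^\circ$ (two spheres one bond apart may
not overlap) maps to $R \ge b/\sqrt 3$.  For a $d$-dimensional fixed-bond
random walk the bending angle has density $p(\theta)\propto
\sin^{d-2}\theta$; changing variables gives the density of the inverse
radius $X = 1/R$ on $(0, 2/b)$,

$$P(X) \;\propto\; (Xb)^{d-2}\,\bigl[1 - (Xb/2)^2\bigr]^{(d-3)/2},$$

whose cumulative distribution behaves as $X^{\,d-1}$ for $Xb \ll 1$.  In
$d = 3$ the bracket exponent vanishes and the CDF is exactly
$(Xb/2)^2$ on the whole support — the `analytic_theory` functions
(`p_theta()`, `pdf_inverse_radius()`, `cdf_exponent()`,
`cdf_inverse_radius_closed_form()`) expose these closed forms, with
normalization constants computed by quadrature to `1e-10`.

# Monte Carlo sampler

Four bond-preserving moves are drawn with equal probability: crankshaft
(rotate an interior bead about the chord of its neighbours, angle uniform
in $(-\pi,\pi]$), endpoint re-graft (terminal bond re-pointed uniformly on
the sphere), reptation (delete one end bead, regrow a uniformly-directed
bond at the other end) and pivot (one arm rigidly rotated by a uniform
random rotation about an interior bead).  All four are self-inverse with
symmetric proposal densities, so the Metropolis rule
$\min(1, e^{-\Delta E/k_BT})$ — with hard-core violations always rejected
— satisfies detailed balance.  At $T=\infty$ every self-avoiding candidate
is accepted, which samples self-avoiding tangent chains uniformly.

Implementation notes:

* Moves are exact rotations/re-grafts, so bond lengths are preserved to
  machine precision; the suite asserts drift below $10^{-9}$ relative
  over long runs.
* Energy updates are incremental: a single-bead move rescans only that
  bead's $O(n)$ pairs, a pivot only the $O(k(n-k))$ cross pairs between
  the moved and fixed arms.  At $n = 80$ this outperforms any cell-list
  bookkeeping, and the trace energies are asserted against full
  recomputation in the tests.
* Replica exchange runs the ladder $0.30\text{–}0.50$ (step $0.02$),
  $0.55\text{–}1.0$ (step $0.05$), $1.2\text{–}4.0$ (step $0.2$) — finer
  where the chain collapses, so neighbouring energy histograms overlap.
  Neighbour swaps use $\min(1, e^{\Delta\beta\,\Delta E})$; the stride is
  configurable (default every 10 sweeps at desk scale; swap acceptances
  are returned and a warning is raised when any falls below 1%).
* All randomness flows through R's RNG (`set.seed()` reproduces runs
  bit for bit, including inside the compiled engine).

WHAM combines the per-replica energy histograms into one density of
states over the discrete energy levels, iterating the free-energy shifts
to `1e-8` in log space; the specific heat per bead
$C_V/Nk_B = (\langle E^2\rangle - \langle E\rangle^2)/(nT^2)$ is then
evaluated on any reduced-temperature grid.  The degenerate single-trace
case must (and in the tests does) match the direct fluctuation
estimator, and a two-level system with known partition function is used
as a closed-form oracle.  At desk-scale run lengths the $C_V$ curve of
the 80-bead chain shows its maximum in the collapse region near reduced
temperature 0.3–0.4, but the peak location remains noisy; the package
reports the full curve rather than asserting a peak position.

## Problem sizes

The published simulations of this model ran $10^9$ sweeps per replica;
the package's defaults are desk scale, chosen so the whole test suite and
the acceptance script stay in the minutes range: $10^4$–$2.4\times10^4$
sweeps for replica exchange (burn-in over half), $5\times10^4$–$4\times
10^5$ sweeps for athermal sampling, $10^6$ walks for the CDF slopes, and
$10^5$ angles for distribution tests.  Convergence diagnostics
(`energy_autocorrelation_time()`, swap acceptances, quarter-mean energy
drift) are exposed so users can scale up.

# Characteristic length scales

Two numbers summarize an ensemble: the modal local radius of curvature
over interior triplets, and the modal distance to the nearest non-local
contact ($|i-j|\ge 3$; ties broken to the smallest $j$; end monomers have
no interior triplet and are excluded from local statistics).

**Mode estimation.**  For sharply peaked distributions (ideal fixtures,
protein secondary structure) any reasonable estimator agrees.  The
polymer ensembles are harder: at $T=\infty$ the density of $R$ itself is
monotone *decreasing* from the steric floor $b/\sqrt3$, so an $R$-space
fullest-bin mode is pinned at the floor and cannot distinguish the
athermal coil from the low-temperature globule.  The package therefore
estimates modes on the inverse scale $X = 1/\text{length}$ — the variable
in which all of its distribution theory is formulated — where the
athermal local-radius density has a genuine interior maximum.  The
estimator is: histogram $X$ (bins $0.004$ Å$^{-1}$ for local radii,
matching $0.02$ Å resolution at the floor, and $0.001$ Å$^{-1}$ for
contact distances), smooth the counts with a loess fit (span 0.25,
degree 2), take the argmax bin, report its inverse.  Smoothing stabilizes
the argmax on flat distributions, where a raw fullest-bin choice jitters
by several bins between runs; distributions occupying fewer than 15 bins
skip the smoothing.  A direct-scale estimator (`estimator = "direct"`,
bins 0.02/0.04 Å) is retained for comparison.

Per-class statistics enforce *pure* triplets — all three monomers
carrying the same structural label — and filter contact distances by the
label of monomer $i$.

# Synthetic data

The generators produce every non-simulated input class the analyses
need, each with exact bond lengths (checked to $10^{-12}$):

* `random_walk()` / `random_walk_batch()` — fixed-bond walks with
  uniform step directions (normalized Gaussians) in any $d \ge 2$;
* `constrained_random_walk()` — first two steps in a fixed plane, third
  step in full 3D, the mixed-dimension case whose quartet CDF exponent
  falls strictly between the planar and spatial values;
* `uniform_ball_points()` — the no-chain baseline (radial inverse CDF),
  which lacks any steric small-$R$ cutoff;
* `self_avoiding_segment()` — rejection-sampled tangent-sphere walks;
* `ideal_alpha_helix()` — rise 1.5 Å, radius 2.3 Å, twist 100°/residue,
  the canonical C$_\alpha$ helix; these imply a bond of ≈ 3.83 Å, a
  constant bending angle near 92° and nearest non-local contacts at
  sequence separation 3;
* `ideal_beta_sheet()` — 120° zigzag strands stacked 4.8 Å apart
  (parallel or antiparallel), joined by equal-chord circular-arc turns
  labeled `loop`;
* `compose_labeled_chain()` — concatenation with ground-truth labels and
  optional Gaussian jitter.

These fixtures emulate geometry only: no hydrogen bonding, no side
chains, no sequence content, no solvent.  Tests passing on them show the
pipeline's bookkeeping and the geometric signatures (contact bands,
angle clusters) are right; they do not validate any claim about real
protein statistics, which depend on a curated structure set.

# Protein ingestion

`read_calpha_trace()` extracts one chain's C$_\alpha$ coordinates via
bio3d (first model; highest-occupancy altloc), treating a consecutive
C$_\alpha$ gap above 4.5 Å as a chain break (reject or keep the longest
piece).  Peptide bonds are classed trans/cis by the consecutive
C$_\alpha$ distance with a 3.4 Å threshold — the midpoint between the
trans (≈ 3.81 Å) and cis (≈ 2.95 Å) populations — or, when a full
backbone is present, by the $\omega$ dihedral
CA$(i)$–C$(i)$–N$(i{+}1)$–CA$(i{+}1)$ with $|\omega| \le 90^\circ$ as
cis.  Secondary-structure labels are *parsed from DSSP output*, mapping
H (optionally G/I) to `alpha` and E to `beta`, everything else `loop`;
the bundled $(\theta,\mu)$-window fallback exists only so the pipeline
runs without external tools and is flagged `theta-mu-heuristic` in its
output — it is not a DSSP replacement.

# Numerical choices and degenerate inputs

* Collinear triplets: flagged infinite radius when $4A/(abc) <
  10^{-12}$ Å$^{-1}$; coplanar quartets when the circumsphere system's
  determinant falls below $10^{-12}$ of its row-norm scale.  Both enter
  CDFs at $X = 0$.
* Dihedral sign: right-handed about the $p_2\!\to\!p_3$ axis, range
  $(-180^\circ, 180^\circ]$; coplanar quartets give exactly $0$ or
  $180^\circ$; a collinear interior triplet is an error (undefined
  binormal).
* Power-law fits: least squares of $\log_{10}$CDF vs $\log_{10}X$ over
  $Xb \in [0.05, 0.5]$ by default, evaluated on a log-spaced grid.  The
  correction factor in the inverse-radius density is $O((Xb)^2)$, so
  exponent checks against the closed forms use the deeper window
  $Xb \in [0.001, 0.05]$.
* Overlap tolerance: a candidate is rejected when any non-adjacent pair
  is closer than $\sigma(1 - 10^{-9})$; conformations claiming fixed
  bonds are validated to $10^{-9}$ relative.
* Contact ties broken to the smallest partner index; chains shorter than
  `min_sep + 1` yield an empty contact set with a warning.

# Known limitations

* Desk-scale replica exchange equilibrates the low-temperature packing
  statistics (local angles, touching contacts) quickly, but the total
  energy of the globule still drifts slowly at these run lengths; deep
  low-$T$ observables other than the two length-scale modes should be
  treated with care unless the run is extended.
* The characteristic scales of broad, flat distributions are intrinsically
  soft numbers: the athermal ensemble's local-radius density varies by a
  few percent over a 0.3 Å range around its maximum, so different
  histogram conventions shift the reported mode by ~0.1–0.2 Å even at
  large sample sizes.  The package fixes one documented convention.
* The heuristic structure classifier uses fixed angle windows calibrated
  on ideal fixtures; on real, irregular chains it under-calls both helix
  and strand relative to DSSP.
* No knot detection, no continuum-tube thickness machinery, no dataset
  curation: chains are analyzed exactly as given.
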