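---
title: "Linear network controllability of structural connectomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear network controllability of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netctrl)
```

## The model

A structural connectome is a weighted, undirected network: `N` brain
regions, edge weights `a_ij` counting the white-matter streamlines between
regions `i` and `j` (`A` symmetric, nonnegative, zero diagonal). The
package equips this network with noise-free, discrete-time, linear
dynamics

    x(t+1) = A_s x(t) + B_K u(t)

where `x(t)` is the vector of regional activity magnitudes, `A_s` a
stabilized version of `A`, and `B_K` selects the control regions `K`
(its columns are canonical vectors `e_i`). Linear dynamics are a coarse
but deliberate simplification: a substantial fraction of slow neural
dynamics measured with fMRI is captured by linearizations around an
operating point, and the linear theory gives exact, interpretable
controllability diagnostics. All diagnostics here use single-region
control sets (`B = e_i`), asking what each region could do alone.

### Stabilization

The infinite-horizon controllability Gramian exists only when the
spectral radius `rho(A_s) < 1`. Two schemes are implemented in
`stabilize()`:

* **spectral** (default): `A_s = A / (c (1 + lambda_max(A)))`, `c = 1`.
  For nonnegative symmetric `A` this guarantees
  `rho = lambda_max / (1 + lambda_max) < 1`, always.
* **mean_edge_weight**: `A_s = A / mean(nonzero off-diagonal weights)`,
  the normalization conventional in parts of the connectome literature.
  It does *not* bound the spectral radius — a single-edge network already
  yields `rho = 1` — so Gramian operations refuse such systems rather
  than silently diverging. The mean is taken over *nonzero* off-diagonal
  entries; averaging over all `N(N-1)` cells is the other defensible
  reading, and dividing by a different constant only rescales `A_s`, so
  rank-based downstream results are unaffected.

The spectral scheme is the default precisely because the infinite-horizon
quantities must exist; the mean-edge-weight scheme is kept for
comparability. Note the `+1` offset means the spectral scheme is not
exactly scale invariant (`alpha A` and `A` stabilize to slightly
different `A_s`), whereas mean-edge-weight normalization is.

### The Gramian and its solvers

For a control set `K`, the Gramian is the fixed point of the discrete
Lyapunov equation `W = A_s W A_s' + B_K B_K'`, equal to
`sum_{tau>=0} A_s^tau B_K B_K' (A_s')^tau`. `controllability_gramian()`
solves it two ways:

* **lyapunov** (primary): because `A_s` is symmetric, with
  eigendecomposition `A_s = V diag(lambda) V'` the solution is exactly
  `W = V M V'`, `M_jk = (V'BB'V)_jk / (1 - lambda_j lambda_k)`. One
  eigendecomposition per scan (stored inside the `stabilized_system`)
  serves every control node.
* **series**: horizon doubling `W_{2h} = W_h + A^h W_h (A^h)'`, stopped
  when the residual bound `rho^{2h} ||W_h|| / (1 - rho^2)` drops below
  `1e-14`. This route is retained purely as an independent numerical
  oracle; the test suite requires the two to agree to `1e-8`.

Results are symmetrized (`(W + W')/2`) to remove round-off asymmetry.

## The four diagnostics

**Global controllability** — `lambda_min(W_i)`. Strictly positive means
every state is reachable from region `i` alone. On realistic networks
the value is astronomically small: with `rho` close to 1 the Gramian's
condition number exceeds `1e16` within a few dozen regions, and the
computed smallest eigenvalue is round-off noise (magnitudes such as
`1e-23` reported for real data are below double-precision
reproducibility). `global_controllability()` therefore clamps values
within `-1e-12` of zero to 0 and flags results under `1e-15` as
effectively singular. For a *rigorous* positivity statement,
`controllability_certificate()` uses the closed form of the spectral
Lyapunov solution: `W_i = V diag(c) P diag(c) V'` with `c_j = v_ij` and
`P` a Pick (Cauchy-type) matrix, whose determinant has the classical
closed form

    det W_i = prod_j v_ij^2 * prod_{j<k} (lambda_j - lambda_k)^2
              / prod_{j,k} (1 - lambda_j lambda_k)

computable entirely in log space without underflow. `det W_i > 0` —
exact-arithmetic controllability — holds iff the eigenvalues are simple
and no component `v_ij` vanishes (the PBH condition for symmetric
systems). The certificate also reports a certified log10 lower bound on
`lambda_min` (often of order `1e-2000`): the quantitative meaning of
"controllable in principle, infeasible in practice". On networks with
continuous random weights the condition holds almost surely; the
certificate can still decline to certify a specific node when an
eigenvector component falls below what double precision can distinguish
from zero (exponential localization of distant modes), which is a
statement about arithmetic, not about the network.

**Average controllability** — `Trace(W_i)`, the impulse-response energy
(squared H2 norm) of the network driven from region `i`. The trace is
used instead of `Trace(W_i^{-1})` (the exact average-energy quantity)
because the Gramian is far too ill-conditioned to invert; the two are
inversely related. For symmetric stable systems
`Trace(W_i) = diag((I - A_s^2)^{-1})_i`, which the tests use as an
independent oracle. Values are >= 1 and grow with coupling; empirically
they track node strength: hubs steer the network into many easily
reachable states.

**Modal controllability** — `phi_i = sum_j (1 - lambda_j^2) v_ij^2`,
an aggregate of region `i`'s ability to excite all `N` eigenmodes, with
the weight emphasizing fast-decaying (hard-to-reach) modes. The closed
form `phi_i = 1 - sum_j a_ij^2` (for orthonormal `V`) is the test
oracle. `phi_i` lies in `(0, 1]` for stable systems and anti-tracks
strength: weakly connected regions are the ones that can push the system
into difficult-to-reach states. Eigenvalues of the *stabilized* matrix
enter the formula, and eigenvector sign conventions are irrelevant
because only squares appear.

**Boundary controllability** — a value in `(0, 1]` marking how early a
region is exposed at a community interface:

1. a robust consensus partition of the network is computed;
   every region with at least one positive-weight edge crossing community
   lines (the `N_1` first-level boundary nodes) receives value 1;
2. each community is recursively bipartitioned by the sign pattern of the
   Fiedler eigenvector of its induced subnetwork's Laplacian `L = D - A`;
   regions newly exposed as crossing the new split at depth `d` receive
   `(N - n_assigned_before_d) / N`;
3. subnetworks of two or fewer regions bottom out, their unassigned
   members taking the current depth's value; iteration continues until
   every region is assigned.

Values weakly decrease with assignment depth, and the maximum is 1
whenever any inter-community edge exists.

### Design choices in the boundary algorithm

The literature leaves several details open; the package fixes them as
follows, each switchable where it is a genuine alternative:

* *Robust partition*: consensus over `n_runs = 100` Louvain runs
  (resolution 1). The igraph Louvain implementation is deterministic for
  a fixed vertex order, so run-to-run variability is induced by a seeded
  random permutation of vertex order per run — which also makes the
  whole consensus reproducible from one integer seed. The co-assignment
  matrix is thresholded at the 0.95 quantile of a label-permutation null
  and the surviving weighted association graph is reclustered. If
  nothing survives the null (no consensus structure), the
  best-modularity single run is used.
* *Boundary-node definition*: at least one positive-weight crossing edge
  — the minimal reading of "lying at the boundary". Participation-
  coefficient thresholds are a stricter alternative; they introduce a
  tunable cut-off, so the minimal definition was preferred.
* *Recursion order*: all remaining subnetworks are split breadth-first
  at each depth, so values depend only on depth and the `(N - assigned)/N`
  formula generalizes the printed two-level case naturally. The
  alternative traversal — descend into the least controllable (smallest
  mean average controllability) subnetwork first — is available via
  `order = "least_avg_ctrl"`.
* *Fiedler ties and degeneracy*: zero eigenvector entries go to the
  positive side; symmetric subnetworks (e.g. unit-weight triangles) have
  degenerate Fiedler spectra, broken by a seeded symmetric perturbation
  of magnitude `1e-9` on existing edges. Disconnected subnetworks split
  into first component versus rest.
* When the consensus partition has more than two communities, *all*
  crossing nodes receive value 1 at level 1 (not only a pairwise
  subset); nothing in the value formula requires a binary first level.

## Cohort aggregation

Raw diagnostic scales differ across subjects and by orders of magnitude
across diagnostics, so `cohort_analysis()` (i) ranks each diagnostic
within each scan (ascending, mid-ranks on ties), (ii) averages ranks over
all scans and subjects, (iii) takes the top `k = 30` regions per
diagnostic as control hubs (ties broken lexicographically by region id so
hub sets are deterministic), and (iv) computes:

* Pearson correlations of each diagnostic with weighted degree, on the
  aggregated ranks (the convention for these scatter summaries), with
  raw-value correlations also emitted for comparison;
* size-normalized cognitive-system enrichment: the share of hubs in
  system `c` divided by the system size `n_c`, rescaled to sum to 100
  across systems. The rescaling makes the normalized shares comparable
  across diagnostics; the un-rescaled normalized scores are kept in the
  output table alongside;
* group-wise hub means for three hypothesis groups (default mode;
  frontoparietal + cingulo-opercular; ventral + dorsal attention), with
  the s.d. of per-subject group means as the dispersion measure.

Weighted degree defaults to node strength (`sum`); the mean-weight
variant (`mode = "mean"`) is exposed because both appear in the
literature. Rank correlations are unaffected by the constant divisor on
degree-homogeneous graphs, and only mildly affected otherwise.

## The synthetic cohort generator

No imaging data ships with the package; `generate_cohort()` supplies
surrogate cohorts with the statistical features the analysis relies on.
The model is a **degree-corrected weighted stochastic block model with a
rich club**:

* every region has a log-normal propensity `s_i` (`prop_sd = 0.7`), the
  analogue of regional seed volume in tractography — larger regions
  accumulate more and stronger streamlines;
* within a community, edge presence is `min(1, p_within theta_i theta_j)`
  (`p_within = 0.6`, `theta` the mean-normalized propensity); weights are
  `round(lognormal(2, 0.5) * s_i s_j)`, clamped at 1 — positive integers,
  median around 16 with a heavy right tail;
* between communities, a `between_gateway_frac = 0.4` share of
  `p_between = 0.01` is propensity-independent (long-range tracts exist
  where anatomy provides a pathway, independent of regional size) and the
  rest is degree-corrected;
* `n_hubs = 12` regions, spread round-robin over the `n_communities = 8`
  communities, have their propensity multiplied by `hub_boost = 3`
  (boosting all their expected incident weights), receive extra
  between-community attachment (`hub_p_extra = 0.02`), and are
  near-fully interconnected (`hub_rich_p = 0.9`): a rich-club backbone.

These choices are structural, not cosmetic. With independent edge
weights and no degree correction, the leading eigenmode of the
stabilized system localizes on whichever community happens to draw the
largest spectral radius, and average controllability — dominated by that
mode, whose amplitude `1/(1 - rho^2)` exceeds the others a hundredfold —
decouples from strength, which real connectomes do not do. Degree
correction ties a region's coupling into the global core to the same
propensity that sets its strength (the empirical rich-club/assortative
core of brain networks), restoring the strong positive
average-controllability/strength and strong negative modal/strength
relationships at realistic magnitudes. The gateway share of
between-community presence keeps membership of the boundary set from
being a pure proxy for strength, so the boundary/strength relationship
stays weak — the third empirical signature.

Scan-to-scan noise multiplies each existing weight by
`exp(N(0, sigma))` with `sigma = scan_noise * sqrt(pi)/2`, calibrated so
the mean relative weight difference between two scans of a subject is
about `scan_noise` (integer rounding deflates it slightly), and resamples
an `edge_flip = 0.02` fraction of edges; both preserve symmetry and
integrality, and `scan_noise = 0` reproduces the template exactly. One
master seed drives everything through deterministic per-subject/per-scan
sub-seed streams.

Cognitive-system labels are generated at random (eight systems, all
non-empty, sizes loosely matching cortical parcellations). The generator
therefore emulates the *topological* preconditions of the analysis; it
does not emulate spatial embedding, hemispheric symmetry, or any genuine
coupling between systems and network structure. Consequently the
enrichment machinery is exercised — shares sum to 100, size
normalization is verifiably correct — but which system tops the
enrichment table on synthetic data is arbitrary, and passing tests say
nothing about where real control hubs sit in a real brain.

## Problem sizes and numerical conventions

The bundled analysis and the heavier tests use the full study design —
234 regions, 8 subjects, 3 scans (24 matrices; about half a minute for
the three regional diagnostics, plus the per-node eigenvalue sweep when
global controllability is requested). Oracle-equivalence ensembles use
200 random symmetric stable systems up to `N = 50`; Gramian bound checks
use 20 networks at `N = 60`, every node as control set. Key tolerances:
Lyapunov-vs-series and trace-vs-inverse agreement `1e-8`; modal closed
form `1e-10`; Gramian PSD tolerance `-1e-10`; `lambda_min` clamp
`-1e-12`; effective-singularity threshold `1e-15`; series residual
`1e-14`; Fiedler degeneracy perturbation `1e-9`.

## Known limitations

* Undirected networks only; directed connectivity (tract tracing
  asymmetries) needs the non-symmetric Lyapunov machinery.
* Single-node control sets for the diagnostics (the Gramian solver
  itself accepts any `K`); no minimum-energy input design, no
  continuous-time Gramian.
* The boundary algorithm's first level inherits whatever granularity the
  consensus partition finds; on dense networks where every region has a
  crossing edge the diagnostic degenerates to the constant 1 — a property
  of the minimal boundary definition, reported as-is.
* Individual differences in global controllability are not measurable in
  double precision; only its order structure and the positivity
  certificate are meaningful.
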