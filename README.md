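# netctrl

Network controllability analysis of structural brain networks in R.

Which brain regions are positioned to steer large-scale neural dynamics?
Given a structural connectome — a symmetric matrix `A` of streamline
counts between `N` parcellated regions — the package equips it with
noise-free discrete-time linear dynamics `x(t+1) = A_s x(t) + B_K u(t)`
and quantifies, for every region `i` used as a single control input
(`B = e_i`), four diagnostics from the infinite-horizon controllability
Gramian `W_i = Σ_τ A_s^τ e_i e_i' (A_s')^τ` and from the network's
community structure:

| diagnostic | definition | interpretation |
|---|---|---|
| global | `λ_min(W_i)` | strictly positive ⇒ every state reachable from region `i` alone; minute in practice |
| average | `Trace(W_i)` | impulse-response energy; high for hubs that reach many easy states |
| modal | `φ_i = Σ_j (1 − λ_j²) v_ij²` | ability to excite all eigenmodes; high for weak regions driving hard-to-reach states |
| boundary | iterative partition values in `(0, 1]` | how early a region is exposed at a community interface |

A cohort layer ranks diagnostics within each scan, averages ranks across
subjects and scans, extracts the top-`k` control hubs, and computes
size-normalized enrichment of hubs over eight cognitive systems. A
seeded generator supplies synthetic cohorts (degree-corrected weighted
stochastic block model with a rich-club hub backbone and scan-to-scan
noise) so the whole pipeline runs and validates without imaging data.
It is intended for network neuroscientists and methodologists who want
a tested, reproducible reference implementation of these diagnostics.

## Worked example

```r
library(netctrl)

# a 2-node network with one edge of weight 1
conn <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
sys  <- stabilize(conn)          # spectral: A_s = A / (1 + lambda_max)
sys$rho
#> [1] 0.5

controllability_gramian(sys, 1)$W
#>              [,1]         [,2]
#> [1,] 1.066667e+00 3.603133e-17
#> [2,] 3.603133e-17 2.666667e-01

average_controllability(sys)     # Trace(W_i) = 16/15 + 4/15 = 4/3
#>     R001     R002
#> 1.333333 1.333333
modal_controllability(sys)       # 1 - 0.5^2
#> R001 R002
#> 0.75 0.75
global_controllability(sys, 1)   # lambda_min(W_1) = 4/15
#> [1] 0.2666667
#> attr(,"below_tol")
#> [1] FALSE
```

Driving the network from node 1 costs little energy in the direction of
`e_1` (Gramian eigenvalue 16/15 ≥ 1, as always) and four times more in
the direction of its neighbour (4/15) — yet both are reachable, so the
2-node system is controllable from one node.

The full synthetic-cohort analysis lives in `analysis/`:

```sh
Rscript analysis/01_generate_cohort.R    # 8 subjects x 3 scans, N = 234
Rscript analysis/02_control_profiles.R   # 4 diagnostics per region x scan
Rscript analysis/03_cohort_analysis.R    # rank aggregation, hubs, enrichment
Rscript analysis/04_figures.R            # scatter / bar figures
```

Stage 3 prints the degree relationships on the aggregated ranks, e.g.

```
     diagnostic   r_ranked      p_ranked
1      avg_ctrl  0.8843294  1.055987e-78
2    modal_ctrl -0.9855149 8.814671e-181
3 boundary_ctrl  0.2450204  1.531588e-04
```

— average controllability tracks weighted degree (hubs move the brain to
many easily reachable states), modal controllability strongly
anti-tracks it (weakly connected regions push it into hard-to-reach
states), and boundary controllability is largely independent of degree.
Because the generator assigns cognitive-system labels at random, the
enrichment table demonstrates the arithmetic (shares sum to 100,
size-corrected), not any neuroscientific claim.

`run_pipeline()` performs all stages from a single `pipeline_config()`
(or YAML file) and writes byte-reproducible result tables plus a run
manifest.

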