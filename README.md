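# coevnet

Allosteric communication in proteins — how a perturbation at one site
(an inhibitor, a dimerisation interface, a mutation) reaches a distant
functional site — leaves fingerprints in three places at once: the
collective motions implied by the fold's contact topology, the
coevolutionary record of the protein family, and the fluctuation
statistics of a conformational ensemble. `coevnet` is an R package for
structural bioinformaticians and computational biophysicists that builds
all three into one weighted **residue interaction network** and reads
communication pathways off it. It was designed with multi-domain systems
such as side-to-side kinase dimers in mind, where cross-protomer
signalling routes are the question of interest, but works on any
structure + alignment (+ optional ensemble) triple.

## The model

1. **Elastic network (GNM).** Alpha-carbons within *r<sub>c</sub>* = 7.0 Å
   are connected into the Kirchhoff matrix Γ; modes come from
   Γ = UΛUᵀ and residue fluctuations from
   ⟨(ΔR<sub>i</sub>)²⟩ = (3k<sub>B</sub>T/γ) Σ<sub>k</sub> λ<sub>k</sub>⁻¹[u<sub>k</sub>u<sub>k</sub>ᵀ]<sub>ii</sub>.
   The slow-mode mobility profile (default: 5 slowest modes,
   max-normalised) exposes hinge residues; collectivity and cumulative
   overlap with ensemble PCA quantify how well the slow modes span the
   observed structural variation.
2. **Coevolution (MI).** Per-column Kullback–Leibler conservation
   Σ P(i) ln(P(i)/Q(i)); pairwise mutual information with sequence
   weighting and a column-shuffle z-score null; per-residue cumulative MI
   cMI<sub>x</sub> = Σ<sub>y: s(x,y)>t</sub> s(x,y) (t = 6.5, z scale) and
   proximity MI — the mean cMI within 5 Å of a residue, ensemble-averaged
   over conformations.
3. **Ensemble statistics.** Generalized correlation coefficients
   r<sub>MI</sub> = √(1 − e<sup>−2I/3</sup>) from Gaussian mutual
   information of displacement covariances (an MD surrogate ensemble can
   be sampled from the GNM covariance, seeded and reproducible), plus
   per-residue distance / proximity-MI fluctuation variances.
4. **Residue network.** Persistent contacts (≤ 4.5 Å in ≥ 50 % of
   frames) become edges of length
   w<sub>ij</sub> = −ln[(1−α) r<sup>dyn</sup><sub>ij</sub> + α r<sup>coev</sup><sub>ij</sub>].
   On this graph the package computes normalised betweenness centrality,
   communication propensity CP<sub>i</sub> = 3k<sub>B</sub>T / ⟨w₁(d<sub>i</sub>−⟨d<sub>i</sub>⟩)² + w₂(ΔpM<sub>i</sub>−⟨ΔpM<sub>i</sub>⟩)²⟩
   (w₁, w₂ optimised for global network efficiency), Floyd–Warshall
   shortest communication paths with deterministic tie-breaks, and
   block-wise **path ensembles** whose occupancies say how robust a route
   is across the conformational ensemble.

Deterministic fixture generators (bead chains, rings, dumbbell dimers
with a controllable interface, alignments with planted covarying pairs)
make the whole pipeline runnable and testable offline.

## Worked example

```r
library(coevnet)
rc  <- make_reference_case()          # dimer + alignment + 60-frame ensemble
cfg <- run_config(rc$structure, msa = rc$msa, ensemble = rc$ensemble,
                  pairs = rbind(c(1, 24)), blocks = 5, seed = 42)
run <- run_pipeline(cfg)
run
#> <coevnet_run> 24 residues, 33 network edges, efficiency 0.3189, 1 path pair(s)
glance(run)
#> # A tibble: 1 × 7
#>   n_residues n_edges n_frames alpha efficiency    w1    w2
#>        <int>   <int>    <int> <dbl>      <dbl> <dbl> <dbl>
#> 1         24      33       60   0.5      0.319     1     1
tidy(run$paths[[1]])
#> # A tibble: 2 × 4
#>   path                  n_blocks occupancy mean_length
#>   <chr>                    <int>     <dbl>       <dbl>
#> 1 1-2-11-10-13-14-23-24        4       0.8        5.88
#> 2 1-2-11-10-13-14-15-24        1       0.2        5.64
```

The path table reads: across 5 ensemble blocks the dominant
communication route from residue A:1 to B:12 (node 24) runs through the
interface bridge (nodes 14–23) in 80 % of blocks, with one minor variant;
`mean_length` is the summed edge weight of the route in its blocks.
Per-residue scores live in `run$residue_table`:

```r
head(dplyr::select(run$residue_table, label, cmi, pmi, mobility, centrality, cp), 5)
#> # A tibble: 5 × 6
#>   label   cmi   pmi mobility centrality      cp
#>   <chr> <dbl> <dbl>    <dbl>      <dbl>   <dbl>
#> 1 A:1      0    0      0.235     0      0.496
#> 2 A:2      0   53.0    0.207     0.490  0.0251
#> 3 A:3    291.  71.1    0.308     0.0949 0.0215
#> 4 A:4      0   43.0    0.221     0.0870 0.0955
#> 5 A:5      0   10.7    0.219     0.273  0.00551
```

`cmi` is nonzero only for the planted covarying columns (A:3 carries
one), `pmi` smears that signal over 5 Å neighbourhoods, `mobility` is the
slow-mode profile, `centrality` normalised betweenness and `cp` the
communication propensity. `autoplot(run$profile)` and
`plot_residue_profile()` draw the profiles; a thin CLI
(`inst/cli/coevnet`, subcommands `fixtures`, `run`, `compare`) wraps the
same functions for shell use.

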