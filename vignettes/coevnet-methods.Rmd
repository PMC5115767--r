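---
title: "Modelling allosteric communication with coevolution- and dynamics-weighted residue networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allosteric communication with coevolution- and dynamics-weighted residue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

coevnet models how signals travel through a protein — for instance between
the two protomers of a side-to-side kinase dimer — by combining three
independent sources of evidence about residue coupling: the collective
dynamics encoded in the structure's contact topology, the coevolutionary
record in a family alignment, and the fluctuation statistics of a
conformational ensemble. This vignette documents the models, the tunable
parameters, the numerical choices and the known limits of each stage.

## The elastic network stage

A structure with $N$ residues is reduced to its alpha-carbons and treated
as an isotropic Gaussian network: residue pairs within a cutoff
$r_c$ (default **7.0 Å**, the standard alpha-carbon GNM choice) are joined
by springs of uniform force constant $\gamma$. The topology is the
Kirchhoff (graph Laplacian) matrix $\Gamma$, and the normal modes come
from its eigendecomposition $\Gamma = U \Lambda U^{T}$. Residue
mean-square fluctuations restricted to a mode subset are

$$\langle (\Delta R_i)^2 \rangle = \frac{3 k_B T}{\gamma} \sum_k \lambda_k^{-1} \left[ u_k u_k^T \right]_{ii},$$

which with all non-zero modes is the diagonal of the scaled pseudo-inverse
$\Gamma^{+}$. The package reports the *essential mobility profile*: the
cumulative fluctuation of the `k_slowest` slowest non-zero modes
(default **5**), max-normalised so only the profile shape matters —
$k_B T/\gamma$ defaults to 1 for that reason. Local minima of the profile
below a quantile (default the 25th percentile, a deliberately conservative
choice since hinge identification is otherwise qualitative) are flagged as
hinge residues; the spectral tie tolerance of $10^{-9}$ stops
floating-point wrinkles on exactly flat profiles (e.g. rings) from
minting spurious hinges. Zero modes are those below
$10^{-9}\lambda_{max}$ — one per connected component of the contact graph;
a disconnected graph is reported as a warning, not an error, because
trimmed multi-chain inputs legitimately produce one.

Mode quality is summarised two ways. *Collectivity*
$\kappa = N^{-1}\exp(-\sum_i p_i \ln p_i)$ with $p_i = u_i^2$ measures the
fraction of residues a mode moves (1 = all, $1/N$ = one). *Cumulative
overlap*

$$\mathrm{CO} = \sqrt{\frac{1}{K} \sum_{k \le K} \sum_{j \le m} (u_k \cdot v_j)^2}$$

measures how much of the $K$ slowest modes' subspace the first $m$
principal components of an ensemble capture.

**A sign subtlety decided the PCA design.** GNM modes are $N$-vectors;
Cartesian ensemble PCs are $3N$-vectors, so the two must be brought into a
common space before computing CO. Reducing a Cartesian PC to per-residue
displacement *magnitudes* discards the sign pattern that makes a slow mode
what it is (anti-correlated lobes), so a magnitude-projected PC can never
align well with a sign-changing mode and high CO would be unreachable no
matter how good the model is. `ensemble_pca(space = "resdisp")` therefore
performs the $N$-dimensional analysis on *axis-stacked signed
displacements*: each Cartesian axis of the centred displacement field
contributes one $N$-vector sample, and the $3F$ samples are decomposed
together. Under the isotropic-network assumption the axes are
exchangeable, so this directly estimates the $N \times N$ residue
covariance — the space the modes live in. Magnitude projection (with QR
re-orthonormalisation) is retained inside `cumulative_overlap()` only as
a fallback for externally supplied Cartesian PC sets.

## The coevolution stage

Per alignment column, conservation is the Kullback–Leibler divergence
$\sum_i P(i)\ln\left(P(i)/Q(i)\right)$ of the observed amino-acid
frequencies from a background composition $Q$ (natural log throughout).
The shipped default `aa_background_frequencies` is the standard
database-wide composition; it is overridable. Gaps are excluded from
$P$; columns over 50 % gaps are flagged and all-gap columns are reported
missing rather than zero.

Pairwise coupling is mutual information over weighted, optionally
pseudocounted column-pair frequencies. Sequence weighting defaults to
Henikoff position-based weights (identity-cluster weighting at a 62 %
threshold is available); weighting guards against phylogenetic
redundancy, not statistical noise. Significance is calibrated against a
column-shuffle null: permuting one column across sequences preserves both
marginals while destroying covariation, and
$z = (\mathrm{MI} - \mu_{null})/\sigma_{null}$ from at least 20 shuffles
(fewer is refused — a standard deviation from a handful of permutations
is noise). The average-product correction is off by default and
switchable; the per-residue scores below sum plain MI-scale values.

Two per-residue summaries follow. Cumulative MI,
$\mathrm{cMI}_x = \sum_{y:\, s(x,y) > t} s(x,y)$, uses a strict threshold
of **t = 6.5 on the z-score scale**. The threshold is interpreted on the
z scale because raw MI in nats is bounded by the column entropy
($\le \ln 20 \approx 3$) and could never reach 6.5; raw-scale
thresholding remains available through the `score` switch. Proximity MI
is the mean cMI of all residues within **5 Å** (minimum heavy-atom
distance) of a residue, itself included since $d(x,x) = 0$ satisfies any
cutoff; with a conformer ensemble the neighbourhood is recomputed per
frame from alpha-carbon distances and the per-frame values averaged.
Columns are tied to residues by local (Smith–Waterman, BLOSUM62)
alignment of the ungapped reference row against the structure sequence,
refused below 90 % identity.

Sectors — spatially contiguous clusters of strongly coevolving
residues — are a documented heuristic: residues above a cMI percentile
(default 90) are kept, and connected components of the contact subgraph
with at least 3 members are labelled in size order. This is deliberately
not presented as a reproduction of any published sector membership; the
underlying method there is under-specified, so the package commits to a
transparent, testable rule instead.

## The ensemble stage

Molecular-dynamics trajectories are out of scope at desk scale; their
role is filled by sampling conformers from the GNM covariance
$(k_B T/\gamma)\,\Gamma^{+}$, applied independently and identically per
Cartesian axis. The sampler is bit-reproducible given (seed, n_frames)
and the interface is the same `conformer_ensemble` used for multi-model
files, so a real trajectory can be substituted without touching any
downstream stage. What the surrogate emulates is harmonic fluctuation
around one basin with the network's correlation structure; what it does
not emulate is anharmonicity, conformational switching, side-chain
repacking and solvent effects — so passing tests demonstrate the
correctness of the machinery, not fidelity to long-timescale kinase
dynamics.

Pairwise motion coupling is the generalized correlation coefficient
$r_{MI} = \sqrt{1 - e^{-2I/3}}$ with $I$ the Gaussian mutual information
from the 3×3/6×6 displacement covariance blocks,
$I = \tfrac{1}{2}\ln(\det C_i \det C_j / \det C_{ij})$. Unlike Pearson
correlations it is rotation-insensitive and maps to $[0,1]$. Two closed
forms anchor the tests: identical per-axis correlation $\rho$ gives
$r_{MI} = |\rho|$ exactly, and the deterministic
`analytic_gnm_correlation()` — the normalised GNM covariance pushed
through the same map — equals the large-$F$ limit of the sampled
estimator. Residues with singular displacement covariance are assigned 0
with a warning rather than propagating `-Inf` weights.

Per-residue fluctuation statistics feed communication propensity: for
each frame, $d_i$ is the mean alpha-carbon distance of residue $i$ to all
others and $\Delta pM_i$ the mean difference between its pMI and the
others'; their population variances across frames summarise how stable
the residue's "effective position" is.

## The network stage

Edges are *persistent structural contacts*: minimum heavy-atom distance
within **4.5 Å** in at least **50 %** of frames (a static structure
counts as one frame; CA distances are used on CA-only ensemble frames).
The interaction-strength ($I_{min}$) eligibility convention used
elsewhere in the protein-structure-network literature depends on an
external normalisation table, so persistence was chosen as the
reproducible default. Edge length is

$$w_{ij} = -\ln\left[(1-\alpha)\, r^{dyn}_{ij} + \alpha\, r^{coev}_{ij}\right],$$

with the coevolutionary term the pair z-scores min-max rescaled to
$[0,1]$ over the eligible edges and $\alpha = 0.5$ by default — the
sources are blended linearly because nothing in the underlying theory
privileges one normalisation of "combined correlation"; $\alpha$ is
exposed and $\alpha = 0$ recovers a purely dynamic network (it is forced
to 0, with a warning, when no alignment is supplied). Correlations are
clipped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-4}$ so
lengths stay finite and positive; on fixtures without saturated
correlations the efficiency is insensitive to $\varepsilon$ at the 1 %
level (tested).

Centrality is weighted betweenness with all co-optimal paths counted,
normalised per connected component by the $(N-1)(N-2)/2$ pairs excluding
the residue, giving values in $[0,1]$. Communication propensity is, in
the default *ratio* form,

$$\mathrm{CP}_i = \frac{3 k_B T}{\left\langle w_1 (d_i - \langle d_i\rangle)^2 + w_2 (\Delta pM_i - \langle \Delta pM_i \rangle)^2 \right\rangle},$$

so residues with small fluctuations of their effective distance metric
get large CP — matching the stated semantics of the model ("small
fluctuations, large CP"). A literal product form ($3k_BT$ *times* the
fluctuation average) is retained behind a flag for auditability, since
the formula can also be read typographically that way. $k_BT$ defaults
to $0.0019872\,\text{kcal mol}^{-1}\text{K}^{-1} \times 300\,\mathrm{K}$.
The weighting factors $w_1, w_2$ are chosen by grid search to maximise
global network efficiency — the mean inverse shortest-path length over
ordered pairs (unreachable pairs contribute 0) — after pruning the
lowest-CP decile of nodes; ties resolve to the lexicographically smallest
$(w_1, w_2)$.

All-pairs shortest paths use Floyd–Warshall relaxation. Determinism of
reported routes matters more than speed at these sizes, so co-optimal
ties (within $10^{-12}$ relative) are broken to the lexicographically
smallest node sequence via a canonical next-hop table, and the number of
co-optimal paths per pair is recorded by dynamic programming over the
shortest-path DAG. An independent single-source algorithm (igraph)
cross-checks the distances in the test suite.

Path *ensembles* quantify route robustness: the conformer ensemble is cut
into B contiguous equal blocks (default **10**), a network is rebuilt per
block, and the occupancy of a distinct node sequence is the fraction of
blocks in which it is the optimal source→target route. Blocks with no
route count toward an explicit "no path" category so occupancies always
total 1. The estimator is block-frequency because it is seed-stable and
self-documenting; published occupancy figures from long MD runs do not
define their estimator, so no numerical equivalence is claimed.

## Fixtures and what the tests show

Every generator is a pure function of its spec (seed included). The
dumbbell dimer — two cubic-lattice clusters at 3.8 Å spacing, faces 6 Å
apart, with a configurable number of bead pairs pulled to 4.0 Å — gives a
minimal two-domain topology with a controllable interface: exactly one
eligible inter-unit contact when one bridge is requested, which forces
every inter-unit communication path across it (occupancy 1 by
construction, and the suite verifies the package finds that). Planted-MSA
pairs follow a two-state coupled model whose generating joint has MI
exactly $\ln 2$ at full coupling, giving an analytic target for the MI
estimator. Sizes used throughout the suite (24-residue dimers, 250–400
sequence alignments, 60-frame pipeline ensembles, 20 000-frame estimator
checks) were chosen as the smallest at which each statistical target is
comfortably identifiable.

## Known limitations

* The GNM surrogate ensemble cannot show ligand-specific effects
  (inhibitor-bound versus apo differences) — those require externally
  supplied ensembles, which the same interfaces accept.
* Raw z-score magnitudes from the shuffle null grow with alignment depth;
  the 6.5 threshold is a convention, and cMI values should be compared
  within one alignment, not across alignments of different depth.
* Sector assignments depend on the percentile and contact cutoff; they
  are a screening heuristic.
* The anisotropic network model (directional modes) is not implemented;
  all mode vectors are scalar per residue.

## A worked run

```{r}
library(coevnet)
rc <- make_reference_case()
cfg <- run_config(rc$structure, msa = rc$msa, ensemble = rc$ensemble,
                  pairs = rbind(c(1, 24)), blocks = 5, seed = 42)
run <- run_pipeline(cfg)
glance(run)
tidy(run$paths[[1]])
autoplot(run$profile)
```
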