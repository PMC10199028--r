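---
title: "Community detection in multi-frequency multilayer brain networks"
author: "mfnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection in multi-frequency multilayer brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfnets)
```

## The problem

Functional brain networks are usually built within one frequency band at a
time, yet cognition relies on interactions *across* oscillatory bands —
most prominently the modulation of gamma amplitude by theta phase. `mfnets`
models a multichannel recording as a **multilayer network**: each layer is
a frequency band, intra-layer edges carry within-band phase synchrony, and
inter-layer edges — allowed between *any* two electrodes, not only between
an electrode and itself — carry cross-frequency coupling. Community
detection on this object can return communities that span bands, which is
exactly the signature of cross-frequency integration.

The package covers the full chain:

1. network construction from trial-epoched signals (RID-Rihaczek
   time-frequency distribution, PLV intra-layer, dPAC inter-layer);
2. a multilayer modularity with a layer-strength-preserving configuration
   null model, and its greedy multilevel maximizer;
3. surrogate-based selection of the resolution parameter $\gamma_r$ and
   the inter-layer scale $\omega$;
4. group-level consensus over subjects via co-clustering matrices and
   spectral clustering on multi-layer graphs (SC-ML);
5. comparison metrics (NMI, a spectral Jensen–Shannon graph distance);
6. synthetic generators so that every stage is testable without recorded
   data.

## The quality function and its null model

For a multilayer network with supra-adjacency blocks $A^{hk}$, layer-wise
strengths $s_{u^h}^{k} = \sum_{v \in V^k} w_{uv}^{hk}$ and block totals
$m^{hk}$, the **multilayer configuration null model** assigns the expected
weight

$$P_{uv}^{hk} = \frac{s_{u^h}^{k}\, s_{v^k}^{h}}{(1+\delta_{hk})\, m^{hk}},$$

which preserves every layer-wise strength in expectation
($\sum_v P_{uv}^{hk} = s_{u^h}^{k}$, exactly — this is asserted to
$10^{-12}$ in the test suite). Preserving strengths *per layer pair*
matters because band power differs wildly across bands; a null model blind
to that heterogeneity lets the layer label masquerade as community
structure.

The quality of a partition $g$ is

$$Q = \sum_{h} \sum_{i,j \in V^h} (A_{ij}^{hh} - \gamma_r P_{ij}^{hh})\,
\delta_{g_i g_j} \; + \; \omega \sum_{h \neq k} \sum_{i \in V^h, j \in V^k}
(A_{ij}^{hk} - \gamma_r P_{ij}^{hk})\, \delta_{g_i g_j}.$$

Conventions we pin down (and test):

* the inter-layer sum runs over **ordered pairs $h \neq k$** — the intra
  term already covers $h = k$, and the $(1+\delta_{hk})$ factor in the null
  model is precisely what makes the two cases consistent;
* sums include $i = j$, so the all-in-one partition scores exactly 0 at
  $\gamma_r = 1$ for every network and every $\omega$ (a telescoping
  identity used as a regression anchor);
* $Q$ is reported unnormalized: only differences and argmaxima are used
  downstream;
* at $\omega = 0$, $Q$ decomposes into independent single-layer
  modularities, so the single-band analysis is the degenerate case of the
  same machinery;
* zero-strength nodes get zero null expectation and end up as singletons.

## Maximization

$Q$ is a quadratic form over the supra-level matrix
$B = A_\omega - \gamma_r P_\omega$ (off-diagonal blocks of both terms
scaled by $\omega$), so any generalized-modularity engine applies. The
engine here is a greedy multilevel ascent of the Louvain/Leiden family,
written against an arbitrary dense $B$ because library engines tie the
null model to per-node weight products, which cannot express the
block-dependent null above. Three details matter:

* local moves must include the **empty community** as a candidate target —
  with negative entries in $B$ this is frequently the best move and its
  omission silently truncates the search space;
* ties among equal-gain moves are broken uniformly at random under the run
  seed; this run-to-run variability is not a nuisance but the raw material
  for consensus clustering later;
* `maximize_modularity()` takes the best of 20 diversified greedy ascents
  (singletons, all-in-one, and random coarse starts). At desk scale this
  reaches the exhaustively verified global optimum: on ensembles of
  8-layer-node networks the suite checks every result against all
  $B(8) = 4140$ partitions. `maximize_ensemble()` deliberately uses
  single-ascent runs to expose the degeneracy of the modularity landscape.

## Choosing the resolution and inter-layer scale

Both parameters are selected by a surrogate contrast. A surrogate network
permutes edge weights *within every $(h,k)$ block separately*, preserving
each block's weight multiset (hence $m^{hk}$ and the cross-layer
heterogeneity) while destroying weight-topology association. For the fully
connected weighted networks produced by the EEG pipeline this coincides
with the weight-randomization family for weighted graphs; for sparse
input, weights are permuted over existing edges only. The default is a
full within-block permutation — the stationary distribution of repeated
pairwise swaps — with literal `n_swaps` swapping available.

For each grid point $(\gamma_r, \omega)$, `select_parameters()` compares
the mean maximized modularity of the observed network over $c$ runs
($Q_{obs}$) with one detection run on each of $c$ surrogates ($Q_{surr}$),
and returns the argmax of $Q_{obs} - Q_{surr}$. One shared surrogate
ensemble is generated per network and reused across the grid, which keeps
the surface smooth in the parameters. The reference grids
($\Gamma_r = \{0.95 + 0.0025n\}_{n=0}^{40}$,
$\Omega = \{0.0125n\}_{n=0}^{40}$, $c = 100$) are the defaults.

A caution established during validation: when inter-layer blocks are
*noisy but uninformative*, the argmax genuinely drifts to $\omega > 0$,
because modularity maximization harvests whichever inter-layer noise
happens to align with the intra-layer communities — on both the observed
and the surrogate side, but more effectively on the observed side where
intra-layer structure anchors the partition. The sharp
"no inter-layer information" regime is a constant inter-layer block
(generator option `inter_noise_sd = 0`), for which the surface is flat in
$\omega$ and the first grid point $\omega = 0$ is returned. This mirrors
the behaviour of real cohorts, where a fraction of subjects with no
apparent cross-frequency structure still receives small positive optimal
$\omega$.

## Group community structure

Modularity maximization is degenerate; single runs are unstable summaries.
For each subject, $c$ runs are condensed into a **co-clustering matrix**
(counts of shared community membership; diagonal $= c$). The matrices of
all subjects form the layers of a multiplex graph, and SC-ML extracts a
common structure: per layer the symmetric normalized Laplacian $L^h$ and
its $k$ smallest-eigenvector embedding $U^h$, merged through

$$L_{mod} = \sum_h L^h - \alpha \sum_h U^h (U^h)^\top,$$

followed by row-normalized spectral embedding of $L_{mod}$ and k-means
(fixed seed, 50 restarts). $\alpha = 0.5$ follows the method's published
guideline; $\alpha = 0$ reduces to spectral clustering on the summed
Laplacians (tested). The number of groups defaults to the half-up-rounded
mean of the subjects' modal community counts across their runs. Because
co-clustering diagonals are positive, $(D^h)^{-1/2}$ always exists; this
is asserted, not special-cased. Eigenvector sign indeterminacy is
irrelevant to k-means distances; eigenvalue ties resolve by the symmetric
solver's deterministic ordering.

## Comparison metrics

**NMI** uses the arithmetic-mean normalization by default (max, min and
geometric variants are exposed); it is cross-checked in the suite against
an independent graph-library implementation to 12 decimals. Two identical
trivial partitions have NMI 1 by convention.

**Jensen–Shannon graph distance**: each graph is represented by the
density operator $\rho = L_{norm}/\mathrm{tr}(L_{norm})$ and the distance
is $\sqrt{S(\tfrac{\rho_1+\rho_2}{2}) - \tfrac{S(\rho_1)+S(\rho_2)}{2}}$
with base-2 von Neumann entropies, so the $[0,1]$ bound is exact. This is
one pinned member of the spectral Jensen–Shannon family; it satisfies
identity, symmetry and boundedness (tested on random ensembles) but is not
guaranteed numerically identical to other members of that family.

## From epochs to networks

The time-frequency distribution is the **reduced-interference Rihaczek**:
the Rihaczek distribution $C(t,f) = z(t)\,Z^*(f)\,e^{-j2\pi ft}$ of the
analytic signal, smoothed in the ambiguity plane by a Choi–Williams kernel
$\exp(-(\theta\tau)^2/\sigma)$, with doppler $\theta$ and lag $\tau$
wrapped to normalized coordinates in $[-\tfrac12, \tfrac12)$ and
$\sigma = 0.001$ by default. The kernel is 1 on the axes, so the marginals
are untouched; off the axes it suppresses the oscillatory cross-terms of
multicomponent signals (tested as a reduction in ridge-magnitude
oscillation for two-tone inputs). The frequency grid has one bin per
sample, i.e. 1 Hz resolution for 1-s epochs; band membership of bins is
half-open $[f_{lo}, f_{hi})$, as is the analysis window.

Intra-layer weights average the across-trial **PLV** of the
phase-difference field over the analysis window and band; inter-layer
weights average **dPAC** over the window and all (phase-bin,
amplitude-bin) pairs of the band pair. Three interpretation points are
deliberate and documented:

* the "frequency constrained time marginal" that defines the amplitude
  envelope integrates a complex quantity; an envelope must be real and
  nonnegative, so the magnitude of the band-integrated complex marginal
  is used (per-bin amplitudes $|C(t,f_a)|$ inside the weight sum);
* dPAC is directional (amplitude at $u$, phase at $v$); since the network
  model is undirected the two directions are averaged by default
  (`"max"` and one-directional modes are exposed);
* zero-magnitude bins have undefined phase and are excluded from all
  averages, with per-bin valid-trial counts, rather than propagating NaN.

### What the phase of a quadratic distribution does and does not measure

Three properties of Rihaczek-family phases shaped both the generator and
the tests, and are easy to trip over:

1. **Absolute phase cancels.** The distribution is bilinear in the signal,
   so a constant phase offset (or pure delay) common to a trial appears in
   both the instantaneous factor $z(t)$ and the spectral factor $Z(f)$ and
   cancels. The phase difference between two delayed copies of one
   sinusoid at its own frequency bin is 0 — not $2\pi f_0 \Delta t$ as a
   Hilbert-phase intuition would suggest. PLV is unaffected (it only needs
   across-trial consistency), but tests of the phase itself must assert
   the right invariant: the measured phase at bin $b$ of a tone at $f_0$
   advances at $2\pi(f_0 - b)$ per second.
2. **Phases are anchored at the epoch start.** Combining the leakage
   linear phase with the Dirichlet-kernel sign alternation, the measured
   phase of an off-bin tone is $\approx 2\pi(f_0 - b)\,t$ with $t$ counted
   from the epoch start. Across trials with frequency wander $W$ Hz, the
   phase spread at time $t$ is therefore about $W \cdot t$ cycles: phases
   decorrelate only for analysis windows placed late enough in the epoch.
   The default response onset sits mid-epoch (`t0 = 0.5` s) for this
   reason.
3. **Multi-bin stochastic sources self-anchor.** For a narrowband noise
   process, the spectral anchor $\arg Z(f_p)$ is built from the very bins
   being measured, concentrating measured phases across trials with
   circular resultant $\approx 1/\sqrt{\#\text{bins}}$. This raises the
   dPAC baseline at source-occupied bins and, for planted couplings, can
   cancel the planted gain through amplitude-variance inflation.

## The synthetic generators

`make_planted_network()` draws fully connected weighted multilayer
networks with planted partitions: within/between-community means
$\mu_{in} > \mu_{out}$, Gaussian perturbation clipped at zero, per-layer
scale factors for cross-band weight heterogeneity, communities either
spanning layers (with optionally informative inter-layer blocks) or
independent per layer. Everything is a pure function of the spec and seed.

`make_planted_epochs()` emulates trial-epoched recordings. Guided by the
three facts above, a source is an **oscillation with per-trial uniform
frequency within its band and uniform phase**; locked groups share the
draw, independent sources decorrelate through frequency wander, and
`channel_jitter` admixes per-channel same-band oscillations. PAC is
planted **in the measurement frame**: the envelope
$1 + d\cos\phi$ multiplying the amplitude-band source uses the measured
(RID-Rihaczek) low-frequency phase of the phase channel's pre-modulation
noisy signal — the same quantity the dPAC estimator later extracts. This
validates estimator and pipeline without asserting a biophysical phase
convention, and it is the only planting that survives the anchor effects
described above. Real recordings differ in ways the generator does not
emulate — volume conduction, 1/f background, nonstationary burst
structure — so passing tests demonstrate correctness of the estimators and
pipeline, not field-readiness of any particular parameter setting.

Two further findings from validating the dPAC chain, recorded here because
they bound what per-pair coupling tests can claim at desk scale:
same-electrode (diagonal) inter-layer entries carry intrinsic
self-coupling (amplitude and phase are extracted from the same signal),
and the per-pair planted excess at realistic trial counts is comparable to
seed-level noise. Pairwise coupling tests therefore use seed-paired depth
contrasts (monotone response of the planted direction to modulation
depth) rather than single-seed winner-take-all assertions.

## Study-scale validation scenarios

The test-suite and the acceptance script rerun the whole method on fixed
scenarios; all sizes below are the package's chosen desk-scale study
conditions.

* Null-model exactness, zero-point and $\omega = 0$ decomposition: 20
  random 4-layer, 16-node/layer networks; tolerances $10^{-12}$ (relative)
  and $10^{-9}$.
* Optimizer exactness: 20 planted 2-layer, 4-node/layer networks against
  exhaustive enumeration of all 4140 partitions.
* Parameter-regime recovery: 5x5 grid ($\gamma_r \in [0.95, 1.05]$,
  $\omega \in [0, 0.5]$), $c = 20$, ten replicates per regime;
  cross-layer-informative networks must select $\omega > 0$ and
  constant-inter-block networks $\omega = 0$, each in at least 8 of 10.
* Surrogate conservation: exact multiset and total preservation over 100
  seeds.
* Group recovery: five subjects around one planted 16-node, 4-group
  structure; at 5% flipped co-clustering mass NMI must be 1.0, at 20% at
  least 0.9 in 8 of 10 seeds.
* Estimator floors/ceilings: locked noiseless pairs at PLV 1; the
  Cauchy–Schwarz equality case of dPAC at 1; uncoupled dPAC mean below
  0.15 at $K = 100$ over 1000 draws.
* End-to-end: 8 channels, two 4-channel modules, each phase-locked in
  theta (4–7 Hz) and a narrowband gamma source (38–44 Hz) and each
  theta-to-gamma coupled (depth 0.9, $f_p = 5$ Hz via its first channel,
  $f_a = 41$ Hz), $K = 100$ trials at 128 Hz, 1-s response-centered
  epochs, sensor noise sd 0.5. Detection at $\gamma_r = 1, \omega = 1$ on
  the theta/gamma two-layer network must recover the planted cross-layer
  modules with NMI $\ge 0.8$ in every one of ten replicates (observed:
  NMI 1.0 throughout). An earlier asymmetric version of this scenario
  (coupling in one module only) was underpowered — its planted inter-block
  excess matched the shared-source block-coherence noise — and was
  replaced by the symmetric design.

## Known limitations

* The maximizer is exhaustively verified only at small scale; at realistic
  scale it inherits the usual local-optimum caveats of the greedy family,
  mitigated by restarts and by consensus over runs.
* The JS graph distance is one member of its family; absolute values are
  not comparable across definitions, only orderings were validated.
* The surrogate selection of $\omega$ is conservative only in the
  constant-block regime; with noisy uninformative inter-layer weights it
  inherits an upward drift (see above).
* Per-pair dPAC coupling detection at desk-scale trial counts is
  statistically marginal; block-level (module) structure is what the
  end-to-end pipeline reliably recovers.
* The TFD uses circular lags; epochs are treated as periodic, which is
  adequate for windows away from epoch edges (all defaults keep the
  analysis window interior).
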