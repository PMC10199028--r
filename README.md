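# mfnets — community detection in multi-frequency multilayer brain networks

Functional connectivity is usually analysed one frequency band at a time,
but higher-order brain function depends on interactions *across* bands
(theta phase modulating gamma amplitude being the canonical example).
`mfnets` models multichannel electrophysiology as a **multilayer network**
in which each layer is a frequency band, intra-layer edges carry
within-band phase synchrony (time-frequency PLV) and inter-layer edges —
allowed between any two electrodes — carry cross-frequency coupling
(direct phase-amplitude coupling, dPAC), both derived from a
reduced-interference Rihaczek time-frequency distribution. Communities
detected on this object may span bands, which is the signature of
cross-frequency integration.

The package is aimed at researchers analysing trial-epoched EEG/MEG-style
recordings, and at methodologists who need a fully testable multilayer
community detection stack.

## The method

For supra-adjacency blocks $A^{hk}$, layer-wise strengths
$s_{u^h}^{k}$ and block totals $m^{hk}$, the quality of a partition $g$ is

$$Q = \sum_{h}\sum_{i,j \in V^h} (A_{ij}^{hh} - \gamma_r P_{ij}^{hh})\,
\delta_{g_i g_j} + \omega \sum_{h \neq k}\sum_{i \in V^h, j \in V^k}
(A_{ij}^{hk} - \gamma_r P_{ij}^{hk})\, \delta_{g_i g_j},
\qquad
P_{uv}^{hk} = \frac{s_{u^h}^{k}\, s_{v^k}^{h}}{(1+\delta_{hk})\, m^{hk}}.$$

The null model preserves layer-wise node strengths — exactly, in
expectation — so the heterogeneity of edge weights across bands cannot
masquerade as community structure. $Q$ is maximized by a greedy multilevel
(Louvain/Leiden-family) engine over the supra matrix
$B = A_\omega - \gamma_r P_\omega$; the resolution parameter $\gamma_r$
and the inter-layer scale $\omega$ are selected by maximizing
$Q_{obs} - Q_{surr}$ against weight-permutation surrogates that preserve
each block's weight multiset. Group-level structure across subjects is
extracted from co-clustering matrices with spectral clustering on
multi-layer graphs (SC-ML); partitions and graphs are compared with NMI
and a spectral Jensen–Shannon distance.

## Worked example

Simulate a two-layer network of 8 electrodes with two planted communities
that span both layers, select the parameters by surrogate testing, detect
communities, and condense 50 runs into a consensus:

```r
library(mfnets)

spec <- planted_network_spec(n_layers = 2, n_nodes = 8, n_communities = 2,
                             cross_layer = TRUE, inter_structure = TRUE,
                             noise_sd = 0.2, seed = 11)
sim <- make_planted_network(spec)
net <- sim$network
net
#> Multilayer network: 2 layers (L1, L2), 16 layer-nodes
#>   intra-layer weight: L1=18.3, L2=19.1
#>   inter-layer blocks with weight: 1 of 1

grid <- select_parameters(net, gammas = seq(0.95, 1.05, 0.025),
                          omegas = seq(0, 0.5, 0.125),
                          n_surrogates = 20, seed = 7)
grid
#> Parameter grid: 5 gamma_r x 5 omega; argmax gamma_r = 1, omega = 0.5 (Q_obs - Q_surr = 14.3896)

best <- maximize_modularity(net, gamma_r = grid$argmax[["gamma_r"]],
                            omega = grid$argmax[["omega"]], seed = 7)
best
#> Community detection: 2 communities, Q = 17.8994 (gamma_r = 1, omega = 0.5, seed = 7)
nmi(best$partition, sim$partition)
#> [1] 1
```

The selected $\omega > 0$ says the inter-layer edges carry real community
information (they do: the planted communities span layers — for planted
per-layer-only structure with constant inter-layer blocks the same
procedure returns $\omega = 0$). The detected partition recovers the
planted one exactly (NMI 1). A consensus over repeated runs gives the same
answer through the group pipeline:

```r
runs <- maximize_ensemble(net, gamma_r = 1, omega = 0.5,
                          n_runs = 50, base_seed = 7)
grp <- scml(co_clustering(runs), k = 2, seed = 7)
grp
#> Group partition: 16 nodes in 2 groups (alpha = 0.5)
nmi(grp$labels, sim$partition)
#> [1] 1
```

Networks can also be built directly from trial-epoched signals with
`build_eeg_network(trial_epochs(...), band_spec(...))`; see the vignette
(`vignettes/multifrequency-community-detection.Rmd`) for the
time-frequency estimators, their conventions and their validated
floors/ceilings, and `inst/cli/mfnets-cli.R` for a command-line front end
(`simulate`, `detect`, `select-params`, `group`, `compare`).

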