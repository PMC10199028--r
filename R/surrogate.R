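#' Layer-structure-preserving surrogate network
#'
#' Randomizes a weighted multilayer network by permuting edge weights
#' among the existing edges of each (h, k) block separately — intra-layer
#' blocks and each inter-layer block independently. This preserves, for
#' every block, the exact multiset of edge weights (hence the block totals
#' \eqn{m^{hk}} and the heterogeneity of edge weights across layers) and
#' the topology (which pairs carry edges), while destroying the
#' association between weights and node pairs. For the fully connected
#' weighted networks produced by [build_eeg_network()], topology
#' preservation and weight permutation coincide.
#'
#' By default a full random permutation of each block's weights is drawn
#' (the stationary limit of repeated pairwise swaps); `n_swaps` performs
#' that many literal random weight-swaps per block instead.
#'
#' @param net a `multilayer_network`.
#' @param seed integer seed.
#' @param n_swaps optional integer; number of pairwise weight swaps per
#'   block instead of a full permutation.
#' @return a `multilayer_network` with permuted weights.
#' @export
surrogate_network <- function(net, seed = 1L, n_swaps = NULL) {
  withr::with_seed(as.integer(seed), {
    intra <- lapply(net$intra, function(A) {
      pos <- which(upper.tri(A) & A != 0)
      A[pos] <- permute_weights(A[pos], n_swaps)
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      A
    })
    inter <- lapply(net$inter, function(B) {
      pos <- which(B != 0)
      B[pos] <- permute_weights(B[pos], n_swaps)
      B
    })
    multilayer_network(intra, inter, net$layers, net$node_ids)
  })
}

permute_weights <- function(w, n_swaps = NULL) {
  n <- length(w)
  if (n < 2L) return(w)
  if (is.null(n_swaps)) return(w[sample.int(n)])
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(n, 2L)
    w[ij] <- w[rev(ij)]
  }
  w
}

#' Select resolution and inter-layer scale by surrogate testing
#'
#' Sweeps a grid of \eqn{(\gamma_r, \omega)} pairs and, at each pair,
#' compares the mean maximized modularity of the observed network
#' (\eqn{Q_{obs}}, over `n_surrogates` detection runs) to the mean
#' maximized modularity of layer-structure-preserving surrogates
#' (\eqn{Q_{surr}}, one detection run on each of `n_surrogates`
#' surrogates). The pair with the largest difference
#' \eqn{Q_{obs} - Q_{surr}} is selected: it is the setting at which the
#' observed network is most modular relative to chance given its layer
#' structure. One shared surrogate ensemble is generated per network and
#' evaluated at every grid point.
#'
#' Default grids follow the reference analysis:
#' \eqn{\Gamma_r = \{0.95 + 0.0025 n\}_{n=0}^{40}} and
#' \eqn{\Omega = \{0.0125 n\}_{n=0}^{40}} with 100 surrogates.
#'
#' @param net a `multilayer_network`.
#' @param gammas ordered vector of resolution parameters.
#' @param omegas ordered vector of inter-layer scales.
#' @param n_surrogates number of surrogates and of observed-network runs
#'   (the reference analysis uses c = 100).
#' @param seed integer seed driving surrogate generation and all
#'   detection runs; the surface is reproducible given the seed.
#' @param n_swaps passed to [surrogate_network()].
#' @return object of class `parameter_grid`: list with `gammas`,
#'   `omegas`, `q_obs`, `q_surr`, `surface` (all |gammas| x |omegas|
#'   matrices), and `argmax` (named vector `gamma_r`, `omega`).
#' @export
select_parameters <- function(net,
                              gammas = 0.95 + 0.0025 * (0:40),
                              omegas = 0.0125 * (0:40),
                              n_surrogates = 100L, seed = 1L,
                              n_swaps = NULL) {
  if (!length(gammas) || !length(omegas))
    stop("gamma and omega grids must be non-empty")
  stopifnot(n_surrogates >= 1)
  seeds <- derive_seeds(seed, 3L * n_surrogates)
  surr_seeds <- seeds[seq_len(n_surrogates)]
  obs_run_seeds <- seeds[n_surrogates + seq_len(n_surrogates)]
  surr_run_seeds <- seeds[2L * n_surrogates + seq_len(n_surrogates)]

  parts_obs <- supra_parts(net)
  parts_surr <- lapply(surr_seeds, function(s)
    supra_parts(surrogate_network(net, seed = s, n_swaps = n_swaps)))

  combine <- function(p, g, w) p$Ai + w * p$Ax - g * (p$Pi + w * p$Px)
  nG <- length(gammas); nO <- length(omegas)
  q_obs <- q_surr <- matrix(NA_real_, nG, nO,
                            dimnames = list(gammas, omegas))
  for (gi in seq_len(nG)) for (oi in seq_len(nO)) {
    B <- combine(parts_obs, gammas[gi], omegas[oi])
    q_obs[gi, oi] <- mean(vapply(obs_run_seeds,
                                 function(s) detect_on_B(B, s)$quality, 0))
    q_surr[gi, oi] <- mean(vapply(seq_len(n_surrogates), function(i) {
      Bs <- combine(parts_surr[[i]], gammas[gi], omegas[oi])
      detect_on_B(Bs, surr_run_seeds[i])$quality
    }, 0))
  }
  surface <- q_obs - q_surr
  best <- which(surface == max(surface), arr.ind = TRUE)[1L, ]
  structure(list(gammas = gammas, omegas = omegas, q_obs = q_obs,
                 q_surr = q_surr, surface = surface,
                 argmax = c(gamma_r = gammas[best[1L]],
                            omega = omegas[best[2L]])),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "Parameter grid: %d gamma_r x %d omega; argmax gamma_r = %g, omega = %g (Q_obs - Q_surr = %.6g)\n",
    length(x$gammas), length(x$omegas), x$argmax[["gamma_r"]],
    x$argmax[["omega"]], max(x$surface)))
  invisible(x)
}

#' @export
as.data.frame.parameter_grid <- function(x, ...) {
  data.frame(gamma = rep(x$gammas, times = length(x$omegas)),
             omega = rep(x$omegas, each = length(x$gammas)),
             q_obs = as.vector(x$q_obs), q_surr = as.vector(x$q_surr),
             diff = as.vector(x$surface))
}
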