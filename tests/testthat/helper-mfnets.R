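# Enumeration of all set partitions of n elements as restricted growth
# strings; the exhaustive oracle for small-scale modularity maximization.
all_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(g, mx) {
    if (length(g) == n) {
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    for (c in seq_len(mx + 1L)) rec(c(g, c), max(mx, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum of the modularity quadratic form over all partitions.
brute_force_best_q <- function(B, partitions) {
  max(vapply(partitions, function(g) sum(B * outer(g, g, "==")), 0))
}

# Two layers of two 4-cliques each, with inter-layer edges joining clique A
# of layer 1 to clique A of layer 2 (and B to B): planted 2 cross-layer
# communities.
two_clique_multilayer <- function() {
  intra <- matrix(0, 8, 8)
  intra[1:4, 1:4] <- 1
  intra[5:8, 5:8] <- 1
  diag(intra) <- 0
  inter <- matrix(0, 8, 8)
  inter[1:4, 1:4] <- 1
  inter[5:8, 5:8] <- 1
  multilayer_network(list(intra, intra), list("1:2" = inter))
}

clique_truth <- c(rep(1, 4), rep(2, 4), rep(1, 4), rep(2, 4))

# Offsets of the supra rows of each layer.
layer_rows <- function(net) {
  off <- c(0L, cumsum(net$n_nodes))
  lapply(seq_along(net$layers), function(h) off[h] + seq_len(net$n_nodes[h]))
}

# Epochs with one theta-source channel, one gamma-source channel and
# (optionally) extra pure-noise channels; a single PAC link from the theta
# channel's measured 4 Hz phase to the gamma carrier when depth > 0.
pac_pair_epochs <- function(depth, seed, K = 40, n_channels = 2) {
  sp <- planted_epoch_spec(
    n_channels, fs = 128, duration = 1, n_trials = K, t0 = 0.5,
    groups = list(list(channels = 1, band = c(5, 7)),
                  list(channels = 2, band = c(40, 42))),
    pac = if (depth > 0)
      list(list(phase_channel = 1, amp_channel = 2, f_p = 4, f_a = 41,
                depth = depth))
    else list(),
    noise_sd = 0.5, seed = seed)
  make_planted_epochs(sp)$epochs
}

# The end-to-end study design: two modules of four channels, each module
# phase-locked in theta (4-7 Hz) and in a narrowband gamma source
# (38-44 Hz), and each module theta->gamma coupled through its first
# channel's measured 5 Hz phase. Ground truth: each module forms one
# community spanning both layers.
e2e_epoch_spec <- function(seed, depth = 0.9, K = 100) {
  planted_epoch_spec(
    n_channels = 8, fs = 128, duration = 1, n_trials = K, t0 = 0.5,
    groups = list(
      list(channels = 1:4, band = c(4, 7)),
      list(channels = 1:4, band = c(38, 44)),
      list(channels = 5:8, band = c(4, 7)),
      list(channels = 5:8, band = c(38, 44))),
    pac = c(lapply(1:4, function(u)
      list(phase_channel = 1, amp_channel = u, f_p = 5, f_a = 41,
           depth = depth)),
      lapply(5:8, function(u)
        list(phase_channel = 5, amp_channel = u, f_p = 5, f_a = 41,
             depth = depth))),
    noise_sd = 0.5, seed = seed)
}

e2e_bands <- function() {
  band_spec(bands = list(theta = c(4, 7), gamma = c(38, 45)),
            window = c(0.025, 0.075))
}

e2e_truth <- rep(c(1, 2), each = 4, times = 2)

# Noisy co-clustering stacks around one planted group structure: a
# fraction of entries (symmetrically) has its co-clustering mass flipped.
noisy_cocluster_stack <- function(labels, n_subjects, flip, c_runs = 100,
                                  seed = 1) {
  withr::with_seed(seed, {
    n <- length(labels)
    lapply(seq_len(n_subjects), function(i) {
      M <- c_runs * outer(labels, labels, "==")
      f <- matrix(stats::runif(n * n) < flip, n, n)
      f[lower.tri(f)] <- t(f)[lower.tri(f)]
      M[f] <- c_runs - M[f]
      diag(M) <- c_runs
      M
    })
  })
}
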