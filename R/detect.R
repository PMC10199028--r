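#' Maximize multilayer modularity
#'
#' Greedy multilevel maximization of the multilayer modularity (the
#' Louvain/Leiden algorithm family) over the supra-level modularity
#' matrix \eqn{B = A_\omega - \gamma_r P_\omega}. Starting from
#' singletons, nodes are repeatedly moved to the community with the
#' largest positive quality gain (ties broken uniformly at random, driven
#' by the seed), communities are aggregated into super-nodes and the
#' procedure recurses until a full pass yields no improving move. The
#' all-in-one partition is additionally used as a second greedy start, and
#' the better of the two refined results is returned, so the reported
#' quality is never below that of the all-singleton or all-in-one
#' partitions.
#'
#' @param net a `multilayer_network`.
#' @param gamma_r resolution parameter (> 0).
#' @param omega inter-layer scale (>= 0).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param restarts independent greedy ascents to take the best of
#'   (default 20); single-restart runs expose the degeneracy of the
#'   modularity landscape, which [maximize_ensemble()] exploits.
#' @param max_sweeps cap on local-move sweeps per level (safety valve;
#'   convergence normally occurs well before).
#' @return object of class `detection_result`: list with `partition`
#'   (canonical integer labels in supra order), `quality`, `seed`,
#'   `n_iterations` (total local-move sweeps), `gamma_r`, `omega`.
#' @examples
#' net <- make_planted_network(planted_network_spec(
#'   n_layers = 2, n_nodes = 6, n_communities = 2, seed = 1))$network
#' maximize_modularity(net, gamma_r = 1, omega = 1, seed = 7)
#' @export
maximize_modularity <- function(net, gamma_r = 1, omega = 1, seed = 1L,
                                restarts = 20L, max_sweeps = 1000L) {
  check_quality_params(gamma_r, omega)
  B <- modularity_matrix(net, gamma_r, omega)
  res <- detect_on_B(B, seed, max_sweeps, restarts)
  structure(list(partition = res$labels, quality = res$quality,
                 seed = as.integer(seed), n_iterations = res$sweeps,
                 gamma_r = gamma_r, omega = omega),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "Community detection: %d communities, Q = %.6g (gamma_r = %g, omega = %g, seed = %d)\n",
    max(x$partition), x$quality, x$gamma_r, x$omega, x$seed))
  invisible(x)
}

# Core engine on a precomputed modularity matrix. Runs `restarts`
# independent greedy multilevel ascents (randomized node orders and
# tie-breaks) plus one ascent from the all-in-one partition when that
# scores higher, and keeps the best. Returns canonical labels, quality
# (diagonal included) and sweep count. Deterministic given seed; RNG
# state of the caller is untouched.
detect_on_B <- function(B, seed, max_sweeps = 1000L, restarts = 1L) {
  N <- nrow(B)
  withr::with_seed(as.integer(seed), {
    a <- greedy_multilevel(B, init = seq_len(N), max_sweeps)
    if (restarts > 1L) for (r in seq_len(restarts - 1L)) {
      # diversified initializations widen the basins the greedy ascent
      # can reach: all-in-one first, then random partitions of random
      # coarseness
      init <- if (r == 1L) rep(1L, N) else
        sample.int(sample.int(N, 1L), N, replace = TRUE)
      b <- greedy_multilevel(B, init = init, max_sweeps)
      if (b$quality > a$quality) a <- b
    }
    q_one <- sum(B)                      # all-in-one quality
    if (q_one > a$quality + 1e-12) {
      b <- greedy_multilevel(B, init = rep(1L, N), max_sweeps)
      if (b$quality > a$quality) a <- b
    }
    a
  })
}

greedy_multilevel <- function(B, init, max_sweeps) {
  N <- nrow(B)
  map <- seq_len(N)          # original node -> current super-node
  labels <- canonicalize_partition(init)
  total_sweeps <- 0L
  repeat {
    lm <- local_moves(B, labels, max_sweeps)
    labels <- lm$labels
    total_sweeps <- total_sweeps + lm$sweeps
    k <- max(labels)
    if (k == nrow(B)) break            # no merge at this level: done
    # aggregate communities into super-nodes and recurse
    map <- labels[map]
    B <- rowsum(t(rowsum(B, labels, reorder = TRUE)), labels, reorder = TRUE)
    if (nrow(B) == 1L) { labels <- 1L; break }
    labels <- seq_len(nrow(B))
  }
  final <- canonicalize_partition(labels[map])
  # aggregation preserves the quadratic form, so quality can be computed
  # on the top-level aggregated matrix
  q <- quality_from_B(B, labels)
  list(labels = final, quality = q, sweeps = total_sweeps)
}

# One level of greedy local moves on B: repeat full passes over nodes in
# random order, moving each node to the community with the largest
# positive gain (random among ties), until a pass makes no move.
local_moves <- function(B, labels, max_sweeps) {
  N <- nrow(B)
  labels <- as.integer(labels)
  sweeps <- 0L
  eps <- 1e-12
  repeat {
    sweeps <- sweeps + 1L
    moved <- FALSE
    for (i in sample.int(N)) {
      v <- B[, i]
      v[i] <- 0
      w <- rowsum(v, labels, reorder = FALSE)      # link weight to each comm
      comms <- as.integer(rownames(w))
      cur <- labels[i]
      w_cur <- w[match(cur, comms), 1L]
      gains <- 2 * (w[, 1L] - w_cur)               # gain of moving i -> comm
      if (sum(labels == cur) > 1L) {               # i -> fresh community
        comms <- c(comms, max(labels) + 1L)
        gains <- c(gains, -2 * w_cur)
      }
      best <- max(gains)
      if (best > eps) {
        cand <- comms[gains >= best - eps]
        target <- if (length(cand) == 1L) cand else
          cand[sample.int(length(cand), 1L)]
        if (target != cur) { labels[i] <- target; moved <- TRUE }
      }
    }
    if (!moved || sweeps >= max_sweeps) break
  }
  list(labels = canonicalize_partition(labels), sweeps = sweeps)
}

#' Ensemble of modularity maximization runs
#'
#' Modularity maximization is degenerate: many near-optimal partitions can
#' coexist. Running the greedy maximizer repeatedly with different seeds
#' yields a collection of informative community structures that downstream
#' consensus (co-clustering) exploits.
#'
#' @inheritParams maximize_modularity
#' @param n_runs number of runs (the reference analysis uses 100).
#' @param base_seed integer; `n_runs` distinct run seeds are derived from
#'   it reproducibly.
#' @param restarts greedy ascents per run; the default 1 keeps the
#'   run-to-run variability that co-clustering consensus relies on.
#' @return list of `detection_result`, one per run.
#' @export
maximize_ensemble <- function(net, gamma_r = 1, omega = 1, n_runs = 100L,
                              base_seed = 1L, restarts = 1L) {
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(base_seed, n_runs)
  B <- modularity_matrix(net, gamma_r, omega)
  lapply(seeds, function(s) {
    res <- detect_on_B(B, s, restarts = restarts)
    structure(list(partition = res$labels, quality = res$quality,
                   seed = s, n_iterations = res$sweeps,
                   gamma_r = gamma_r, omega = omega),
              class = "detection_result")
  })
}

derive_seeds <- function(base_seed, n) {
  withr::with_seed(as.integer(base_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}
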