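#' Multilayer network data model
#'
#' A multilayer network holds a set of physical entities (e.g. electrodes)
#' replicated across an ordered set of layers (e.g. frequency bands).
#' Intra-layer edges connect nodes within a layer; inter-layer edges may
#' connect any two nodes in different layers (unlike a multiplex graph,
#' which restricts them to node-to-itself). All edges are undirected with
#' finite nonnegative weights and there are no self-loops within a layer.
#'
#' @param intra list of L symmetric nonnegative matrices, one per layer,
#'   with zero diagonals; entry `[u, v]` is the intra-layer weight
#'   w_uv within that layer.
#' @param inter named list of inter-layer blocks; names are `"h:k"` with
#'   layer indices h < k, values are `N^h x N^k` nonnegative matrices.
#'   Missing blocks are treated as all-zero, so a multiplex or
#'   single-layer graph is a degenerate multilayer network.
#' @param layers character vector of layer labels (defaults to
#'   `"L1", "L2", ...`).
#' @param node_ids list of per-layer node id vectors, or a single vector
#'   shared by all layers when every layer has the same size. Defaults to
#'   `"n1", "n2", ...` shared across layers.
#' @return an object of class `multilayer_network` with fields `layers`,
#'   `n_nodes`, `node_ids`, `intra`, `inter`.
#' @examples
#' a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
#' net <- multilayer_network(
#'   intra = list(a, matrix(0, 2, 2)),
#'   inter = list("1:2" = matrix(c(0, 0, 0.5, 0), 2, 2))
#' )
#' n_layer_nodes(net)
#' @export
multilayer_network <- function(intra, inter = list(), layers = NULL,
                               node_ids = NULL) {
  stopifnot(is.list(intra), length(intra) >= 1L)
  L <- length(intra)
  intra <- lapply(intra, as.matrix)
  n_nodes <- vapply(intra, nrow, integer(1))
  if (is.null(layers)) layers <- paste0("L", seq_len(L))
  stopifnot(length(layers) == L, !anyDuplicated(layers))
  if (is.null(node_ids)) {
    node_ids <- lapply(n_nodes, function(n) paste0("n", seq_len(n)))
  } else if (!is.list(node_ids)) {
    node_ids <- rep(list(as.character(node_ids)), L)
  }
  names(intra) <- layers
  net <- structure(
    list(layers = as.character(layers), n_nodes = n_nodes,
         node_ids = node_ids, intra = intra,
         inter = lapply(inter, as.matrix)),
    class = "multilayer_network")
  validate_multilayer_network(net)
  net
}

#' Validate multilayer network invariants
#'
#' Checks symmetry of intra-layer blocks, zero diagonals, finiteness and
#' nonnegativity of all weights, and block dimensions. Called by the
#' constructor; exported so that networks assembled by hand can be checked.
#'
#' @param net a `multilayer_network`.
#' @return `net`, invisibly; signals an error of class
#'   `mfnets_invalid_network` on violation.
#' @export
validate_multilayer_network <- function(net) {
  L <- length(net$layers)
  fail <- function(msg) {
    stop(structure(class = c("mfnets_invalid_network", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (length(net$intra) != L) fail("one intra-layer block required per layer")
  for (h in seq_len(L)) {
    A <- net$intra[[h]]
    n <- net$n_nodes[h]
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      fail(sprintf("intra block %d is not %d x %d", h, n, n))
    if (any(!is.finite(A))) fail("non-finite intra-layer weight")
    if (any(A < 0)) fail("negative intra-layer weight")
    if (any(diag(A) != 0)) fail(sprintf("self-loop in layer %s", net$layers[h]))
    if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12)))
      fail(sprintf("intra block %d is not symmetric", h))
    if (length(net$node_ids[[h]]) != n)
      fail(sprintf("node_ids for layer %d has wrong length", h))
  }
  for (key in names(net$inter)) {
    hk <- parse_block_key(key, L)
    B <- net$inter[[key]]
    if (nrow(B) != net$n_nodes[hk[1]] || ncol(B) != net$n_nodes[hk[2]])
      fail(sprintf("inter block %s has wrong dimensions", key))
    if (any(!is.finite(B))) fail("non-finite inter-layer weight")
    if (any(B < 0)) fail("negative inter-layer weight")
  }
  invisible(net)
}

parse_block_key <- function(key, L) {
  hk <- suppressWarnings(as.integer(strsplit(key, ":", fixed = TRUE)[[1]]))
  if (length(hk) != 2L || anyNA(hk) || hk[1] >= hk[2] || hk[2] > L)
    stop("inter-layer block keys must be 'h:k' with layer indices h < k")
  hk
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("Multilayer network: %d layers (%s), %d layer-nodes\n",
              length(x$layers), paste(x$layers, collapse = ", "),
              sum(x$n_nodes)))
  m <- layerwise_strengths(x)$m
  cat(sprintf("  intra-layer weight: %s\n",
              paste(sprintf("%s=%.3g", x$layers, diag(m)), collapse = ", ")))
  nz <- sum(m[upper.tri(m)] > 0)
  cat(sprintf("  inter-layer blocks with weight: %d of %d\n",
              nz, length(x$layers) * (length(x$layers) - 1) / 2))
  invisible(x)
}

#' Number of layer-nodes
#'
#' @param net a `multilayer_network`.
#' @return total N = sum of per-layer node counts.
#' @export
n_layer_nodes <- function(net) sum(net$n_nodes)

# Retrieve inter block (h, k) with h < k not required; returns the matrix
# oriented rows = layer h, cols = layer k (transposing a stored block if
# needed), or a zero matrix when the block is absent.
inter_block <- function(net, h, k) {
  stopifnot(h != k)
  if (h < k) {
    key <- paste0(h, ":", k)
    if (key %in% names(net$inter)) return(net$inter[[key]])
    matrix(0, net$n_nodes[h], net$n_nodes[k])
  } else {
    t(inter_block(net, k, h))
  }
}

#' Layer-node index table
#'
#' Maps every layer-node (node id, layer) to its global row in the
#' supra-adjacency matrix, in layer-major order.
#'
#' @param net a `multilayer_network`.
#' @return data.frame with columns `global`, `layer` (label),
#'   `layer_index`, `node` (local index), `node_id`.
#' @export
layer_node_index <- function(net) {
  L <- length(net$layers)
  out <- do.call(rbind, lapply(seq_len(L), function(h) {
    data.frame(layer = net$layers[h], layer_index = h,
               node = seq_len(net$n_nodes[h]),
               node_id = net$node_ids[[h]],
               stringsAsFactors = FALSE)
  }))
  out$global <- seq_len(nrow(out))
  out[, c("global", "layer", "layer_index", "node", "node_id")]
}

block_offsets <- function(net) {
  c(0L, cumsum(net$n_nodes))[seq_along(net$n_nodes)]
}

#' Assemble the supra-adjacency matrix
#'
#' Stacks the intra-layer adjacency matrices on the diagonal and the
#' inter-layer incidence matrices off-diagonal, in layer order:
#' \deqn{A = [A^{hk}]_{h,k=1}^{L}, \quad A^{kh} = (A^{hk})^\top.}
#'
#' @param net a `multilayer_network`.
#' @return object of class `supra_adjacency`: list with `matrix`
#'   (dense symmetric N x N), `block_index` (see [layer_node_index()]),
#'   `layers`, `n_nodes`.
#' @seealso [supra_to_network()] for the lossless inverse.
#' @export
build_supra_adjacency <- function(net) {
  validate_multilayer_network(net)
  L <- length(net$layers)
  N <- n_layer_nodes(net)
  off <- block_offsets(net)
  A <- matrix(0, N, N)
  for (h in seq_len(L)) {
    idx <- off[h] + seq_len(net$n_nodes[h])
    A[idx, idx] <- net$intra[[h]]
    if (h < L) for (k in (h + 1L):L) {
      jdx <- off[k] + seq_len(net$n_nodes[k])
      B <- inter_block(net, h, k)
      A[idx, jdx] <- B
      A[jdx, idx] <- t(B)
    }
  }
  structure(list(matrix = A, block_index = layer_node_index(net),
                 layers = net$layers, n_nodes = net$n_nodes,
                 node_ids = net$node_ids),
            class = "supra_adjacency")
}

#' Rebuild a multilayer network from a supra-adjacency matrix
#'
#' Inverse of [build_supra_adjacency()]; the round trip is lossless.
#'
#' @param A symmetric nonnegative N x N matrix (or a `supra_adjacency`).
#' @param layers layer labels.
#' @param n_nodes per-layer node counts summing to N.
#' @param node_ids optional per-layer node ids.
#' @return a `multilayer_network`.
#' @export
supra_to_network <- function(A, layers, n_nodes, node_ids = NULL) {
  if (inherits(A, "supra_adjacency")) {
    layers <- A$layers; n_nodes <- A$n_nodes; node_ids <- A$node_ids
    A <- A$matrix
  }
  A <- as.matrix(A)
  if (sum(n_nodes) != nrow(A))
    stop("declared layer sizes do not match supra-adjacency dimension")
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
    stop("supra-adjacency matrix is not symmetric")
  L <- length(layers)
  off <- c(0L, cumsum(n_nodes))[seq_len(L)]
  intra <- lapply(seq_len(L), function(h)
    A[off[h] + seq_len(n_nodes[h]), off[h] + seq_len(n_nodes[h]), drop = FALSE])
  inter <- list()
  for (h in seq_len(L)) if (h < L) for (k in (h + 1L):L) {
    B <- A[off[h] + seq_len(n_nodes[h]), off[k] + seq_len(n_nodes[k]),
           drop = FALSE]
    if (any(B != 0)) inter[[paste0(h, ":", k)]] <- B
  }
  multilayer_network(intra, inter, layers, node_ids)
}

#' Layer-wise node strengths and block totals
#'
#' The strength of node u in layer h toward layer k is the sum of the
#' weights of its edges into layer k,
#' \eqn{s_{u^h}^{k} = \sum_{v \in V^k} w_{uv}^{hk}}. Block totals
#' \eqn{m^{hk}} are the total weight of edges between layers h and k
#' (each edge once); \eqn{m^{hh}} is the total intra-layer weight so that
#' \eqn{\sum_u s_{u^h}^{h} = 2 m^{hh}}.
#'
#' @param net a `multilayer_network`.
#' @return list with `s` (N x L matrix, rows in supra order: `s[i, k]`
#'   is the strength of layer-node i toward layer k) and `m`
#'   (L x L symmetric matrix of block totals).
#' @export
layerwise_strengths <- function(net) {
  L <- length(net$layers)
  N <- n_layer_nodes(net)
  off <- block_offsets(net)
  s <- matrix(0, N, L, dimnames = list(NULL, net$layers))
  m <- matrix(0, L, L, dimnames = list(net$layers, net$layers))
  for (h in seq_len(L)) {
    idx <- off[h] + seq_len(net$n_nodes[h])
    s[idx, h] <- rowSums(net$intra[[h]])
    m[h, h] <- sum(net$intra[[h]]) / 2
    for (k in seq_len(L)) if (k != h) {
      B <- inter_block(net, h, k)
      s[idx, k] <- rowSums(B)
      m[h, k] <- sum(B)
    }
  }
  list(s = s, m = m)
}
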