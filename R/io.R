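#' Write a multilayer network to disk
#'
#' Two plain-text formats are supported: a layered edge-list TSV with
#' header `layer_u, node_u, layer_v, node_v, weight` (each undirected edge
#' written once), or a Matrix Market (`.mtx`) supra-adjacency matrix. In
#' both cases a YAML manifest records the layer order, per-layer node
#' counts and the node-id table; node ids in the TSV are the string ids of
#' the manifest, so files are insensitive to internal 1-based indexing.
#'
#' @param net a `multilayer_network`.
#' @param path output file; extension `.mtx` selects Matrix Market,
#'   anything else the edge-list TSV.
#' @param manifest manifest path; default replaces the extension of
#'   `path` with `.manifest.yaml`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, manifest = default_manifest_path(path)) {
  validate_multilayer_network(net)
  man <- list(layers = as.list(net$layers),
              n_nodes = as.list(stats::setNames(as.integer(net$n_nodes),
                                                net$layers)),
              node_ids = stats::setNames(lapply(net$node_ids, as.list),
                                         net$layers))
  yaml::write_yaml(man, manifest)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    A <- build_supra_adjacency(net)$matrix
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
  } else {
    df <- network_to_edge_list(net)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

default_manifest_path <- function(path) {
  sub("\\.[A-Za-z]+$", "", path) |> paste0(".manifest.yaml")
}

network_to_edge_list <- function(net) {
  L <- length(net$layers)
  rows <- list()
  for (h in seq_len(L)) {
    A <- net$intra[[h]]
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    if (nrow(idx)) rows[[length(rows) + 1L]] <- data.frame(
      layer_u = net$layers[h], node_u = net$node_ids[[h]][idx[, 1]],
      layer_v = net$layers[h], node_v = net$node_ids[[h]][idx[, 2]],
      weight = A[idx], stringsAsFactors = FALSE)
    if (h < L) for (k in (h + 1L):L) {
      B <- inter_block(net, h, k)
      idx <- which(B != 0, arr.ind = TRUE)
      if (nrow(idx)) rows[[length(rows) + 1L]] <- data.frame(
        layer_u = net$layers[h], node_u = net$node_ids[[h]][idx[, 1]],
        layer_v = net$layers[k], node_v = net$node_ids[[k]][idx[, 2]],
        weight = B[idx], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(layer_u = character(), node_u = character(),
                      layer_v = character(), node_v = character(),
                      weight = numeric()))
  do.call(rbind, rows)
}

#' Read a multilayer network from disk
#'
#' Counterpart of [write_network()]; `read_network(write_network(net))`
#' reproduces `net` exactly up to edge ordering. Rejects unknown layer
#' labels, unknown node ids, negative weights, duplicate edges with
#' conflicting weights, and asymmetric Matrix Market input.
#'
#' @param path edge-list TSV or Matrix Market `.mtx` file.
#' @param manifest manifest path (see [write_network()]).
#' @return a `multilayer_network`.
#' @export
read_network <- function(path, manifest = default_manifest_path(path)) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- yaml::read_yaml(manifest)
  layers <- as.character(unlist(man$layers))
  n_nodes <- as.integer(unlist(man$n_nodes[layers]))
  node_ids <- lapply(layers, function(l) as.character(unlist(man$node_ids[[l]])))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    A <- as.matrix(Matrix::readMM(path))
    if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
      stop("Matrix Market supra-adjacency is not symmetric")
    return(supra_to_network(A, layers, n_nodes, node_ids))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character", "numeric"))
  need <- c("layer_u", "node_u", "layer_v", "node_v", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have header: ", paste(need, collapse = ", "))
  edge_list_to_network(df, layers, n_nodes, node_ids)
}

edge_list_to_network <- function(df, layers, n_nodes, node_ids) {
  L <- length(layers)
  intra <- lapply(seq_len(L), function(h) matrix(0, n_nodes[h], n_nodes[h]))
  inter <- list()
  seen <- new.env(hash = TRUE)
  get_layer <- function(lab) {
    h <- match(lab, layers)
    if (is.na(h)) stop("unknown layer label: ", lab)
    h
  }
  get_node <- function(id, h) {
    u <- match(id, node_ids[[h]])
    if (is.na(u)) stop(sprintf("unknown node id '%s' in layer %s",
                               id, layers[h]))
    u
  }
  for (r in seq_len(nrow(df))) {
    w <- df$weight[r]
    if (!is.finite(w) || w < 0)
      stop("edge weight must be finite and nonnegative, got ", w)
    h <- get_layer(df$layer_u[r]); k <- get_layer(df$layer_v[r])
    u <- get_node(df$node_u[r], h); v <- get_node(df$node_v[r], k)
    if (h == k && u == v) stop("self-loop within a layer is not allowed")
    key <- paste(sort(c(paste(h, u), paste(k, v))), collapse = "|")
    if (!is.null(seen[[key]])) {
      if (seen[[key]] != w)
        stop("duplicate edge with conflicting weights: ", key)
      next
    }
    seen[[key]] <- w
    if (h == k) {
      intra[[h]][u, v] <- intra[[h]][v, u] <- w
    } else {
      if (h > k) { tmp <- h; h <- k; k <- tmp; tmp <- u; u <- v; v <- tmp }
      bk <- paste0(h, ":", k)
      if (is.null(inter[[bk]])) inter[[bk]] <- matrix(0, n_nodes[h], n_nodes[k])
      inter[[bk]][u, v] <- w
    }
  }
  multilayer_network(intra, inter, layers, node_ids)
}

#' Write / read a partition
#'
#' Partitions are stored as a TSV with columns `node_id, layer, community`
#' (one row per layer-node, in supra order).
#'
#' @param part integer vector of community labels in supra order.
#' @param net the `multilayer_network` the partition refers to.
#' @param path output/input TSV path.
#' @return `write_partition`: `path` invisibly; `read_partition`: integer
#'   label vector in supra order.
#' @export
write_partition <- function(part, net, path) {
  idx <- layer_node_index(net)
  stopifnot(length(part) == nrow(idx))
  utils::write.table(
    data.frame(node_id = idx$node_id, layer = idx$layer,
               community = as.integer(part)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(net, path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  idx <- layer_node_index(net)
  key <- paste(df$layer, df$node_id)
  want <- paste(idx$layer, idx$node_id)
  pos <- match(want, key)
  if (anyNA(pos)) stop("partition file does not cover every layer-node")
  as.integer(df$community[pos])
}
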