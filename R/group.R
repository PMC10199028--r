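#' Co-clustering matrix of a partition ensemble
#'
#' Entry (u, v) counts in how many of the supplied partitions layer-nodes
#' u and v share a community. With c runs the diagonal is exactly c and
#' every entry lies in [0, c]; the matrix summarizes the (degenerate)
#' landscape of near-optimal partitions of one subject.
#'
#' @param partitions list of partitions: either `detection_result` objects
#'   or plain integer label vectors, all over the same node set.
#' @return symmetric integer matrix N x N.
#' @export
co_clustering <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "detection_result")) p$partition else as.integer(p)
  })
  n <- unique(vapply(labs, length, integer(1)))
  if (length(n) != 1L)
    stop("all partitions must cover the same node set")
  C <- matrix(0, n, n)
  for (g in labs) {
    C <- C + outer(g, g, "==")
  }
  C
}

#' Spectral clustering on multi-layer graphs (SC-ML)
#'
#' Finds a common community structure shared by the layers of a multiplex
#' graph (here: one co-clustering matrix per subject). Each layer h
#' contributes its symmetric normalized Laplacian
#' \deqn{L^h = (D^h)^{-1/2} (D^h - A^h) (D^h)^{-1/2}}
#' and its spectral embedding \eqn{U^h} (eigenvectors of the k smallest
#' eigenvalues of \eqn{L^h}). The layers are merged through the modified
#' Laplacian
#' \deqn{L_{mod} = \sum_h L^h - \alpha \sum_h U^h (U^h)^\top,}
#' whose k smallest eigenvectors, row-normalized, are discretized by
#' k-means. The subspace term pulls the joint embedding toward each
#' layer's own low-rank structure; \eqn{\alpha} balances the two (0.5 by
#' default, following the method's guidelines). With \eqn{\alpha = 0} the
#' procedure reduces to spectral clustering on the summed normalized
#' Laplacians.
#'
#' @param matrices list of symmetric nonnegative N x N matrices (layers of
#'   the multiplex graph), or a single matrix.
#' @param k number of groups (>= 2).
#' @param alpha subspace-merging weight in [0, 1].
#' @param seed integer seed for the k-means discretization (50 restarts).
#' @return object of class `group_partition`: list with `labels`
#'   (canonical integer vector of length N), `k`, `alpha`, `embedding`
#'   (N x k matrix).
#' @export
scml <- function(matrices, k, alpha = 0.5, seed = 1L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L, k >= 2, alpha >= 0, alpha <= 1)
  N <- nrow(matrices[[1L]])
  if (k > N) stop("k cannot exceed the number of nodes")
  Lmod <- matrix(0, N, N)
  for (A in matrices) {
    stopifnot(nrow(A) == N, ncol(A) == N)
    d <- rowSums(A)
    if (any(d <= 0))
      stop("layer with an isolated (zero-strength) node; co-clustering layers always have positive diagonal")
    dis <- 1 / sqrt(d)
    Lh <- -A * outer(dis, dis)
    diag(Lh) <- diag(Lh) + 1
    Lh <- (Lh + t(Lh)) / 2                    # enforce exact symmetry
    eh <- eigen(Lh, symmetric = TRUE)
    Uh <- eh$vectors[, N - seq_len(k) + 1L, drop = FALSE]  # k smallest
    Lmod <- Lmod + Lh - alpha * tcrossprod(Uh)
  }
  Lmod <- (Lmod + t(Lmod)) / 2
  em <- eigen(Lmod, symmetric = TRUE)
  U <- em$vectors[, N - seq_len(k) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(U, centers = k, nstart = 50L,
                                       iter.max = 100L))
  structure(list(labels = canonicalize_partition(km$cluster),
                 k = as.integer(k), alpha = alpha, embedding = U),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("Group partition: %d nodes in %d groups (alpha = %g)\n",
              length(x$labels), x$k, x$alpha))
  invisible(x)
}

#' Group community structure for a set of subjects
#'
#' Full consensus pipeline: for each subject's multilayer network, run the
#' modularity maximizer `n_runs` times at that subject's
#' \eqn{(\gamma_r, \omega)}; build the subject's co-clustering matrix;
#' stack the matrices as layers of a multiplex graph and extract the group
#' structure with [scml()]. Unless `k` is supplied, the number of groups
#' is the half-up-rounded mean over subjects of their modal community
#' count across runs.
#'
#' @param nets list of `multilayer_network`, one per subject, over the
#'   same layer-node set.
#' @param params per-subject parameters: a data.frame/matrix with columns
#'   `gamma_r` and `omega` (one row per subject, recycled if one row), or
#'   a single `parameter_grid`-style named vector `c(gamma_r=, omega=)`.
#' @param n_runs detection runs per subject (reference analysis: 100).
#' @param seed integer base seed.
#' @param k number of groups; `NULL` (default) selects it from the runs.
#' @param alpha SC-ML subspace weight.
#' @return list with `group` (a `group_partition`), `k`, `co_clustering`
#'   (list of per-subject matrices), `n_communities` (per-subject modal
#'   community counts).
#' @export
group_pipeline <- function(nets, params, n_runs = 100L, seed = 1L,
                           k = NULL, alpha = 0.5) {
  stopifnot(length(nets) >= 1L)
  n_subj <- length(nets)
  if (is.numeric(params) && !is.null(names(params)))
    params <- data.frame(gamma_r = params[["gamma_r"]],
                         omega = params[["omega"]])
  params <- as.data.frame(params)
  if (nrow(params) == 1L) params <- params[rep(1L, n_subj), , drop = FALSE]
  stopifnot(nrow(params) == n_subj)
  subj_seeds <- derive_seeds(seed, n_subj + 1L)
  stacks <- vector("list", n_subj)
  n_comm <- integer(n_subj)
  for (i in seq_len(n_subj)) {
    runs <- maximize_ensemble(nets[[i]], gamma_r = params$gamma_r[i],
                              omega = params$omega[i], n_runs = n_runs,
                              base_seed = subj_seeds[i])
    counts <- vapply(runs, function(r) max(r$partition), integer(1))
    tab <- table(counts)
    n_comm[i] <- as.integer(names(tab)[which.max(tab)])  # modal count
    stacks[[i]] <- co_clustering(runs)
  }
  if (is.null(k)) k <- max(2L, floor(mean(n_comm) + 0.5))  # half-up mean
  grp <- scml(stacks, k = k, alpha = alpha, seed = subj_seeds[n_subj + 1L])
  list(group = grp, k = as.integer(k), co_clustering = stacks,
       n_communities = n_comm)
}
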