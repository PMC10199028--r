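#' Normalized mutual information between two partitions
#'
#' Standard contingency-table NMI: mutual information between the two
#' label assignments divided by a mean of the two label entropies
#' (arithmetic mean by default; max, min and geometric variants are
#' available). Equals 1 iff the partitions are identical up to
#' relabeling; 0 when the labels are independent (e.g. the all-in-one
#' versus the all-singleton partition). When both partitions are the
#' trivial all-in-one partition (both entropies zero) they are identical
#' and NMI is defined as 1.
#'
#' @param p,q partitions over the same node set: integer label vectors or
#'   `detection_result` objects.
#' @param normalization one of `"arithmetic"`, `"max"`, `"min"`,
#'   `"geometric"`.
#' @return NMI in [0, 1].
#' @export
nmi <- function(p, q, normalization = c("arithmetic", "max", "min",
                                        "geometric")) {
  normalization <- match.arg(normalization)
  p <- partition_labels(p); q <- partition_labels(q)
  if (length(p) != length(q))
    stop("partitions must cover the same node set")
  n <- length(p)
  tab <- table(p, q)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  hp <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hq <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  denom <- switch(normalization,
                  arithmetic = (hp + hq) / 2,
                  max = max(hp, hq),
                  min = min(hp, hq),
                  geometric = sqrt(hp * hq))
  if (denom == 0) return(if (all(p == p[1]) && all(q == q[1])) 1 else 0)
  min(1, max(0, mi / denom))
}

partition_labels <- function(p) {
  if (inherits(p, "detection_result")) p <- p$partition
  if (inherits(p, "group_partition")) p <- p$labels
  canonicalize_partition(as.integer(p))
}

#' Jensen-Shannon distance between two graphs
#'
#' Spectral graph distance in [0, 1]: each graph is represented by the
#' density operator \eqn{\rho = L / \mathrm{tr}\, L} built from its
#' symmetric normalized Laplacian, and the distance is the square root of
#' the quantum Jensen-Shannon divergence between the two density
#' operators, with von Neumann entropies taken in base-2 logarithms so
#' that the bound [0, 1] is exact:
#' \deqn{d(G_1, G_2) = \sqrt{S\!\left(\tfrac{\rho_1+\rho_2}{2}\right)
#'   - \tfrac{S(\rho_1) + S(\rho_2)}{2}}.}
#' The distance is 0 iff the density operators coincide, symmetric in its
#' arguments, and is effective at separating graphs with different
#' community structure. This is one pinned member of the spectral
#' Jensen-Shannon family of graph distances; alternative members can be
#' added under new method names.
#'
#' @param g1,g2 symmetric nonnegative weight matrices on the same node
#'   set (e.g. co-clustering matrices).
#' @return distance in [0, 1].
#' @export
js_graph_distance <- function(g1, g2) {
  g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  if (!all(dim(g1) == dim(g2)))
    stop("graphs must share the same node set")
  r1 <- density_operator(g1)
  r2 <- density_operator(g2)
  jsd <- vn_entropy((r1 + r2) / 2) - (vn_entropy(r1) + vn_entropy(r2)) / 2
  sqrt(max(0, min(1, jsd)))
}

# Density operator rho = L_norm / tr(L_norm); PSD with unit trace.
density_operator <- function(A) {
  if (all(A == 0)) stop("all-zero graph has no density operator")
  d <- rowSums(A)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -A * outer(dis, dis)
  diag(L) <- diag(L) + as.numeric(d > 0)
  L <- (L + t(L)) / 2
  L / sum(diag(L))
}

# von Neumann entropy in bits; 0 log 0 = 0, tiny negative eigenvalues
# from roundoff clipped.
vn_entropy <- function(rho) {
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-14]
  -sum(ev * log2(ev))
}

#' Consistency of community structures across subjects
#'
#' Pairwise Jensen-Shannon graph distances between subjects'
#' co-clustering matrices; the mean distance of each subject to all
#' others quantifies how consistent that subject's community structure is
#' with the rest of the cohort.
#'
#' @param stacks list of >= 2 symmetric nonnegative matrices (one
#'   co-clustering matrix per subject, same node set).
#' @return object of class `distance_report`: list with `pairwise`
#'   (symmetric matrix in [0, 1] with zero diagonal) and
#'   `per_subject_mean`.
#' @export
consistency_report <- function(stacks) {
  n <- length(stacks)
  if (n < 2L) stop("at least two subjects are required")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- js_graph_distance(stacks[[i]], stacks[[j]])
  }
  structure(list(pairwise = D,
                 per_subject_mean = rowSums(D) / (n - 1L)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  n <- nrow(x$pairwise)
  cat(sprintf("JS-distance consistency report: %d subjects\n", n))
  cat("  per-subject mean distance to others:\n")
  print(round(x$per_subject_mean, 4))
  invisible(x)
}
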