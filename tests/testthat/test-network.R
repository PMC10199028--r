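test_that("supra-adjacency assembly places blocks correctly and symmetrically", {
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
  net <- multilayer_network(
    intra = list(a, matrix(0, 2, 2)),
    inter = list("1:2" = matrix(c(0, 0, 0.5, 0), 2, 2)))
  A <- build_supra_adjacency(net)$matrix
  expect_equal(dim(A), c(4L, 4L))
  expect_identical(sum(A != 0), 4L)              # one edge each way, twice
  expect_equal(A[1, 2], 1); expect_equal(A[1, 4], 0.5)
  expect_equal(A, t(A))

  empty <- multilayer_network(list(matrix(0, 3, 3), matrix(0, 2, 2)))
  expect_equal(build_supra_adjacency(empty)$matrix, matrix(0, 5, 5))
})

test_that("supra round trip is lossless for random 3-layer networks", {
  for (s in 1:3) {
    net <- random_multilayer_network(3, 5, seed = s)
    sa <- build_supra_adjacency(net)
    back <- supra_to_network(sa)
    expect_equal(build_supra_adjacency(back)$matrix, sa$matrix)
    expect_equal(back$intra, net$intra)
  }
})

test_that("constructor rejects invalid networks", {
  bad_diag <- diag(2)
  expect_error(multilayer_network(list(bad_diag)), "self-loop")
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(multilayer_network(list(asym)), "not symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(multilayer_network(list(neg)), "negative")
  expect_error(
    multilayer_network(list(matrix(0, 2, 2), matrix(0, 2, 2)),
                       inter = list("1:2" = matrix(0, 3, 2))),
    "dimensions")
  expect_error(supra_to_network(matrix(0, 4, 4), c("a", "b"), c(2, 3)),
               "do not match")
})

test_that("layerwise strengths satisfy their totals and match row sums", {
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 2
  x <- matrix(0, 3, 3); x[1, 2] <- 0.5
  net <- multilayer_network(list(a, matrix(0, 3, 3)), list("1:2" = x))
  st <- layerwise_strengths(net)
  expect_equal(unname(st$s[1, 1]), 2); expect_equal(unname(st$s[2, 1]), 2)
  expect_equal(unname(st$m[1, 1]), 2)
  expect_equal(unname(st$s[1, 2]), 0.5)  # node 1 in layer 1 toward layer 2
  expect_equal(unname(st$s[5, 1]), 0.5)  # node 2 in layer 2 toward layer 1
  expect_equal(unname(st$m[1, 2]), 0.5)

  net <- random_multilayer_network(3, 6, seed = 9)
  st <- layerwise_strengths(net)
  A <- build_supra_adjacency(net)$matrix
  rows <- layer_rows(net)
  for (h in 1:3) for (k in 1:3) {
    expect_equal(unname(st$s[rows[[h]], k]),
                 unname(rowSums(A[rows[[h]], rows[[k]], drop = FALSE])))
    expect_equal(sum(st$s[rows[[h]], k]),
                 (1 + (h == k)) * st$m[h, k], tolerance = 1e-12)
  }
})

test_that("edge-list and Matrix Market round trips preserve the network", {
  net <- random_multilayer_network(4, 4, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv)
  back <- read_network(tsv)
  expect_equal(build_supra_adjacency(back)$matrix,
               build_supra_adjacency(net)$matrix)
  expect_identical(back$layers, net$layers)
  expect_identical(back$node_ids, net$node_ids)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_network(net, mtx)
  back2 <- read_network(mtx)
  expect_equal(build_supra_adjacency(back2)$matrix,
               build_supra_adjacency(net)$matrix)
})

test_that("readers reject malformed input", {
  net <- random_multilayer_network(2, 3, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t")

  bad <- df; bad$weight[1] <- -1
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(yaml::read_yaml(sub("\\.tsv$", ".manifest.yaml", tsv)),
                   sub("\\.tsv$", ".manifest.yaml", f))
  expect_error(read_network(f), "nonnegative")

  bad <- df; bad$layer_u[1] <- "delta"
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_network(f), "unknown layer")

  # duplicate edge with conflicting weight
  bad <- rbind(df, df[1, ]); bad$weight[nrow(bad)] <- bad$weight[1] + 1
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_network(f), "conflicting")

  # asymmetric Matrix Market entry
  A <- build_supra_adjacency(net)$matrix
  A[1, 2] <- A[1, 2] + 1
  m <- withr::local_tempfile(fileext = ".mtx")
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"), m)
  yaml::write_yaml(yaml::read_yaml(sub("\\.tsv$", ".manifest.yaml", tsv)),
                   sub("\\.mtx$", ".manifest.yaml", m))
  expect_error(read_network(m), "not symmetric")
})

test_that("partition files round trip", {
  net <- random_multilayer_network(2, 4, seed = 6)
  part <- maximize_modularity(net, seed = 1)$partition
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, net, f)
  expect_identical(read_partition(net, f), part)
})
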