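fs <- 128
n <- 128
tt <- (0:(n - 1)) / fs

test_that("the distribution concentrates energy on a sinusoid's ridge", {
  tfd <- rid_rihaczek(cos(2 * pi * 20 * tt), fs)
  ridge <- apply(Mod(tfd$C[10:118, ]), 1, which.max)
  expect_true(all(ridge == 21))   # 20 Hz bin (1-based column)
  expect_equal(tfd$freqs[21], 20)
  expect_identical(max(Mod(rid_rihaczek(rep(0, n), fs)$C)), 0)
  expect_error(rid_rihaczek(cos(tt), fs, sigma = 0), "positive")
  expect_error(rid_rihaczek(c(1, NaN), fs), "non-finite")
})

test_that("the kernel suppresses two-tone cross-term oscillations", {
  x <- cos(2 * pi * 10 * tt) + cos(2 * pi * 40 * tt)
  rid <- rid_rihaczek(x, fs)$C
  rih <- rid_rihaczek(x, fs, kernel = "none")$C
  # cross-terms of the plain Rihaczek beat along time on the ridges; the
  # reduced-interference kernel flattens the ridge magnitude profile
  cv <- function(v) stats::sd(v) / mean(v)
  expect_lt(cv(Mod(rid[10:118, 11])), cv(Mod(rih[10:118, 11])))
  expect_lt(cv(Mod(rid[10:118, 41])), cv(Mod(rih[10:118, 41])))
})

test_that("time marginal of the plain distribution is the signal energy", {
  withr::with_seed(1, {
    x <- rnorm(n)
    tfd <- rid_rihaczek(x, fs, kernel = "none")
    z <- mfnets:::analytic_signal(x)
    expect_equal(Re(rowSums(tfd$C)), Mod(z)^2, tolerance = 1e-8)
  })
})

test_that("phase differences are zero for identical channels and antisymmetric", {
  withr::with_seed(2, {
    x <- rnorm(n); y <- rnorm(n)
    tx <- rid_rihaczek(x, fs); ty <- rid_rihaczek(y, fs)
    d_self <- tf_phase_difference(tx, tx)
    expect_lt(max(abs(d_self), na.rm = TRUE), 1e-8)
    d_uv <- tf_phase_difference(tx, ty)
    d_vu <- tf_phase_difference(ty, tx)
    ok <- !is.na(d_uv)
    expect_equal(d_uv[ok], -d_vu[ok], tolerance = 1e-8)
  })
  expect_error(tf_phase_difference(rid_rihaczek(cos(tt), fs),
                                   rid_rihaczek(cos(tt[1:64]), 64)),
               "not aligned")
})

test_that("PLV reaches its floor and ceiling cases", {
  phis <- withr::with_seed(3, matrix(runif(12, -pi, pi), 3, 4))
  expect_equal(plv(rep(list(phis), 10)), matrix(1, 3, 4))
  # balanced 0 / pi phases cancel exactly
  expect_equal(plv(list(phis * 0, phis * 0 + pi, phis * 0,
                        phis * 0 + pi)),
               matrix(0, 3, 4))
  expect_error(plv(list(phis)), "two trials")
})

test_that("PLV of independent phases matches the Rayleigh expectation", {
  K <- 50
  withr::with_seed(4, {
    vals <- replicate(60, {
      phases <- lapply(seq_len(K), function(k) matrix(runif(9, -pi, pi), 3, 3))
      mean(plv(phases))
    })
  })
  # E|sum of K unit phasors|/K = sqrt(pi/4)/sqrt(K)
  expect_equal(mean(vals), sqrt(pi / 4) / sqrt(K), tolerance = 0.05)
})

test_that("intra-layer weights hit 1 for noiseless locked pairs and stay low for independent ones", {
  locked <- make_planted_epochs(planted_epoch_spec(
    2, fs = fs, n_trials = 10, t0 = 0.5,
    groups = list(list(channels = 1:2, band = c(4, 7))),
    noise_sd = 0, seed = 1))$epochs
  w <- intra_layer_weights(locked, c(4, 7))
  expect_equal(w[1, 2], 1, tolerance = 1e-9)
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))

  indep <- make_planted_epochs(planted_epoch_spec(
    2, fs = fs, n_trials = 50, t0 = 0.5,
    groups = list(list(channels = 1, band = c(4, 7)),
                  list(channels = 2, band = c(4, 7))),
    noise_sd = 0.3, seed = 2))$epochs
  w2 <- intra_layer_weights(indep, c(4, 7))
  expect_lt(w2[1, 2], 0.5)
  expect_error(intra_layer_weights(locked, c(300, 400)), "no frequency bins")
})

test_that("amplitude envelopes track amplitude modulation", {
  mod <- 1 + 0.5 * cos(2 * pi * 3 * tt)
  x <- mod * cos(2 * pi * 30 * tt)
  env <- amplitude_envelope(rid_rihaczek(x, fs), c(25, 36))
  inner <- 15:114
  expect_gt(cor(env[inner], mod[inner]), 0.8)
  # unmodulated carrier: flat envelope
  env0 <- amplitude_envelope(rid_rihaczek(cos(2 * pi * 30 * tt), fs),
                             c(25, 36))
  expect_lt(stats::sd(env0[inner]) / mean(env0[inner]), 0.2)
  expect_identical(max(amplitude_envelope(rid_rihaczek(rep(0, n), fs),
                                          c(25, 36))), 0)
  expect_error(amplitude_envelope(rid_rihaczek(x, fs), c(300, 400)),
               "no frequency bins")
})

test_that("low-frequency phase advances at the off-bin frequency offset", {
  # a quadratic distribution anchors phase at the trial start, so the
  # measured phase at bin b of a tone at f0 advances at 2*pi*(f0 - b)
  x <- cos(2 * pi * 5.4 * tt)
  phi <- low_freq_phase(rid_rihaczek(x, fs, kernel = "none"), 5)
  inner <- 20:110
  unwrapped <- cumsum(c(phi[inner][1], mfnets:::wrap_angle(diff(phi[inner]))))
  fit <- stats::lm(unwrapped ~ tt[inner])
  expect_equal(unname(stats::coef(fit)[2]), 2 * pi * 0.4, tolerance = 0.05)
  # identical signals share the phase series
  expect_equal(low_freq_phase(rid_rihaczek(x, fs), 5),
               low_freq_phase(rid_rihaczek(x, fs), 5))
})

test_that("dPAC attains the Cauchy-Schwarz equality case and stays in [0,1]", {
  K <- 40
  ph <- matrix(rep(withr::with_seed(5, runif(6, -pi, pi)), each = K), K, 6)
  expect_equal(dpac(matrix(1, K, 6), ph), rep(1, 6))
  expect_identical(dpac(matrix(0, K, 3), ph[, 1:3]), rep(0, 3))
  withr::with_seed(6, {
    a <- matrix(abs(rnorm(K * 6)), K, 6)
    p <- matrix(runif(K * 6, -pi, pi), K, 6)
    v <- dpac(a, p)
    expect_true(all(v >= 0 & v <= 1))
  })
})

test_that("planted coupling raises dPAC above the uncoupled case", {
  K <- 60
  withr::with_seed(7, {
    diffs <- replicate(40, {
      ph <- matrix(runif(K, -pi, pi), K, 1)
      coupled <- dpac(1 + 0.9 * cos(ph), ph)
      uncoupled <- dpac(matrix(1 + 0.9 * cos(runif(K, -pi, pi)), K, 1), ph)
      coupled - uncoupled
    })
  })
  expect_gt(mean(diffs), 0.2)
})

test_that("inter-layer weights respond monotonically to modulation depth", {
  depths <- c(0, 0.45, 0.9)
  W <- vapply(depths, function(d) vapply(1:4, function(s)
    inter_layer_weights(pac_pair_epochs(d, 400 + s), c(4, 7), c(40, 43),
                        sigma = 0.001, direction = "uv")[2, 1],
    0), numeric(4))
  # seed-paired: the planted direction (amplitude at 2, phase at 1)
  expect_true(all(colMeans(W)[2] > colMeans(W)[1],
                  colMeans(W)[3] > colMeans(W)[2]))
  expect_gt(mean(W[, 3] - W[, 1]), 0.01)
})

test_that("uncoupled white-noise channels give near-floor inter-layer weights", {
  noise_only <- make_planted_epochs(planted_epoch_spec(
    3, fs = fs, n_trials = 40, t0 = 0.5, groups = list(),
    noise_sd = 1, seed = 11))$epochs
  B <- inter_layer_weights(noise_only, c(4, 7), c(40, 43))
  # dPAC floor at K = 40 is ~1/sqrt(K) = 0.16 per bin
  expect_lt(max(B), 0.3)
  expect_equal(B, t(B))
})

test_that("the full builder yields a valid normalized multilayer network", {
  ep <- make_planted_epochs(e2e_epoch_spec(1, K = 20))$epochs
  net <- build_eeg_network(ep, e2e_bands())
  expect_s3_class(net, "multilayer_network")
  expect_identical(net$layers, c("theta", "gamma"))
  expect_identical(unname(net$n_nodes), c(8L, 8L))
  expect_identical(net$node_ids[[1]], ep$channels)
  A <- build_supra_adjacency(net)$matrix
  expect_true(all(A >= 0 & A <= 1))
  # deterministic given the same epochs
  net2 <- build_eeg_network(ep, e2e_bands())
  expect_equal(net, net2)
})
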