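#' Specification for a planted-partition multilayer network
#'
#' Describes a fully connected weighted multilayer network with planted
#' community structure: within-community weights have mean `mu_in`,
#' between-community weights mean `mu_out` (< `mu_in`), Gaussian
#' perturbation `noise_sd`, clipped at zero. Per-layer scale factors
#' emulate the heterogeneity of edge weights across frequency bands.
#' Communities either span layers (`cross_layer = TRUE`: node u carries
#' the same community in every layer, and inter-layer blocks are
#' informative when `inter_structure = TRUE`) or are independent per
#' layer (`cross_layer = FALSE`: each layer is partitioned on its own and
#' inter-layer weights carry no community signal).
#'
#' @param n_layers number of layers L.
#' @param n_nodes nodes per layer (scalar or length-L vector; planted
#'   partitions require equal layer sizes).
#' @param n_communities communities per planted partition.
#' @param cross_layer do planted communities span layers?
#' @param inter_structure are inter-layer weights informative about the
#'   (cross-layer) communities? Forced `FALSE` when `cross_layer` is.
#' @param mu_in,mu_out within/between-community weight means,
#'   `mu_in > mu_out >= 0`.
#' @param layer_scales per-layer multiplicative weight scales (> 0);
#'   inter-layer blocks use the geometric mean of the two layers' scales.
#' @param noise_sd Gaussian weight perturbation (scaled like the means).
#' @param inter_noise_sd perturbation of the inter-layer blocks (defaults
#'   to `noise_sd`). Setting it to 0 with `inter_structure = FALSE` gives
#'   constant inter-layer blocks — the sharpest "no inter-layer
#'   information" regime, in which the surrogate surface is flat in the
#'   inter-layer scale; with noisy uninformative blocks the scale
#'   selection genuinely drifts upward, as modularity maximization
#'   harvests aligned inter-layer noise.
#' @param seed integer seed.
#' @return object of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_layers = 2L, n_nodes = 8L,
                                 n_communities = 2L, cross_layer = TRUE,
                                 inter_structure = cross_layer,
                                 mu_in = 1, mu_out = 0.5,
                                 layer_scales = rep(1, n_layers),
                                 noise_sd = 0.1,
                                 inter_noise_sd = noise_sd, seed = 1L) {
  if (length(n_nodes) == 1L) n_nodes <- rep(n_nodes, n_layers)
  stopifnot(length(n_nodes) == n_layers, n_communities >= 1,
            length(layer_scales) == n_layers)
  if (!(mu_in > mu_out && mu_out >= 0))
    stop("planted weights require mu_in > mu_out >= 0")
  if (any(layer_scales <= 0)) stop("layer scales must be positive")
  if (noise_sd < 0 || inter_noise_sd < 0) stop("noise sds must be nonnegative")
  if (!cross_layer) inter_structure <- FALSE
  structure(list(n_layers = as.integer(n_layers),
                 n_nodes = as.integer(n_nodes),
                 n_communities = as.integer(n_communities),
                 cross_layer = cross_layer,
                 inter_structure = inter_structure,
                 mu_in = mu_in, mu_out = mu_out,
                 layer_scales = layer_scales, noise_sd = noise_sd,
                 inter_noise_sd = inter_noise_sd,
                 seed = as.integer(seed)),
            class = "planted_network_spec")
}

#' Generate a planted-partition multilayer network
#'
#' Draws the fully weighted multilayer network described by a
#' [planted_network_spec()] together with its ground-truth partition.
#' Expected within-community weights exceed between-community weights in
#' every informative block; the draw is a pure function of the spec
#' (including its seed).
#'
#' @param spec a `planted_network_spec`.
#' @return list with `network` (a `multilayer_network`) and `partition`
#'   (canonical integer labels over layer-nodes, supra order).
#' @export
make_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  L <- spec$n_layers
  n <- spec$n_nodes
  withr::with_seed(spec$seed, {
    # planted labels per layer; cross-layer communities share labels,
    # per-layer communities get layer-distinct labels over shuffled nodes
    base <- rep_len(seq_len(spec$n_communities), n[1])
    labels <- vector("list", L)
    for (h in seq_len(L)) {
      labels[[h]] <- if (spec$cross_layer) {
        rep_len(seq_len(spec$n_communities), n[h])
      } else {
        (h - 1L) * spec$n_communities +
          rep_len(seq_len(spec$n_communities), n[h])[sample.int(n[h])]
      }
    }
    draw_block <- function(mu, sd) pmax(0, mu + stats::rnorm(length(mu), 0, sd))
    intra <- vector("list", L)
    for (h in seq_len(L)) {
      mu <- ifelse(outer(labels[[h]], labels[[h]], "=="),
                   spec$mu_in, spec$mu_out) * spec$layer_scales[h]
      W <- matrix(0, n[h], n[h])
      up <- upper.tri(W)
      W[up] <- draw_block(mu[up], spec$noise_sd * spec$layer_scales[h])
      W <- W + t(W)
      intra[[h]] <- W
    }
    inter <- list()
    for (h in seq_len(L)) if (h < L) for (k in (h + 1L):L) {
      sc <- sqrt(spec$layer_scales[h] * spec$layer_scales[k])
      mu <- if (spec$inter_structure) {
        ifelse(outer(labels[[h]], labels[[k]], "=="),
               spec$mu_in, spec$mu_out) * sc
      } else {
        matrix(spec$mu_out * sc, n[h], n[k])
      }
      inter[[paste0(h, ":", k)]] <-
        matrix(draw_block(mu, spec$inter_noise_sd * sc), n[h], n[k])
    }
    net <- multilayer_network(intra, inter)
    list(network = net,
         partition = canonicalize_partition(unlist(labels)))
  })
}

#' Random fully connected multilayer network
#'
#' All intra- and inter-layer weights i.i.d. uniform on (0, 1): a
#' structureless but strength-heterogeneous test ensemble.
#'
#' @param n_layers,n_nodes dimensions (nodes per layer).
#' @param seed integer seed.
#' @return a `multilayer_network`.
#' @export
random_multilayer_network <- function(n_layers = 4L, n_nodes = 16L,
                                      seed = 1L) {
  spec <- planted_network_spec(n_layers, n_nodes, n_communities = 1L,
                               mu_in = 1, mu_out = 0, seed = seed)
  withr::with_seed(spec$seed, {
    n <- spec$n_nodes
    intra <- lapply(seq_len(n_layers), function(h) {
      W <- matrix(0, n[h], n[h])
      up <- upper.tri(W)
      W[up] <- stats::runif(sum(up))
      W + t(W)
    })
    inter <- list()
    for (h in seq_len(n_layers)) if (h < n_layers)
      for (k in (h + 1L):n_layers)
        inter[[paste0(h, ":", k)]] <- matrix(stats::runif(n[h] * n[k]),
                                             n[h], n[k])
    multilayer_network(intra, inter)
  })
}

#' Specification for oscillatory epochs with planted PLV and PAC
#'
#' Channels are built from shared narrowband oscillatory sources plus
#' independent white sensor noise. A group is a set of channels driven by
#' one source — an oscillation whose frequency is drawn uniformly from
#' the group's band and whose phase is uniform, both fresh every trial —
#' so group members are phase-locked within the band while independent
#' sources decorrelate across trials through their frequency wander;
#' `channel_jitter` admixes an independent same-band oscillation per
#' channel to soften the locking. A PAC link modulates the
#' amplitude-band source contribution at one channel with
#' `1 + depth * cos(phi)`, where `phi` is the measured low-frequency
#' phase (RID-Rihaczek, Eq.-style frequency-bin phase at `f_p`) of the
#' phase channel's pre-modulation noisy signal: the coupling is planted
#' in the same deviation-phase frame in which the dPAC estimator
#' measures it, so recovery tests validate the estimator and pipeline
#' without asserting a biophysical phase convention.
#'
#' Because a quadratic time-frequency distribution anchors phases at the
#' epoch start, the across-trial spread of measured phases at time t is
#' roughly (band width) x t cycles: analysis windows should sit late
#' enough in the epoch (t0 near the epoch middle) for independent
#' phases to decorrelate.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration epoch length, seconds.
#' @param n_trials number of trials K (>= 2).
#' @param t0 response-onset time within the epoch, seconds.
#' @param groups list of `list(channels =, band = c(lo, hi),
#'   amplitude =)` source descriptions (amplitude defaults to 1).
#' @param pac list of `list(phase_channel =, amp_channel =, f_p =,
#'   f_a =, depth =)` couplings; requires `f_p < f_a`, depth in [0, 1],
#'   and the amplitude channel to belong to a group whose band contains
#'   `f_a`. The phase channel needs no source at `f_p`: the modulator is
#'   whatever phase the estimator measures there.
#' @param channel_jitter in [0, 1]: 0 = perfect within-group locking.
#' @param noise_sd standard deviation of white sensor noise.
#' @param sigma RID kernel parameter used when planting PAC phase.
#' @param seed integer seed.
#' @return object of class `planted_epoch_spec`.
#' @export
planted_epoch_spec <- function(n_channels, fs = 512, duration = 1,
                               n_trials = 30L, t0 = 0.5, groups = list(),
                               pac = list(), channel_jitter = 0,
                               noise_sd = 0.5, sigma = 0.001, seed = 1L) {
  stopifnot(n_channels >= 1, fs > 0, duration > 0, n_trials >= 2,
            t0 >= 0, t0 < duration,
            channel_jitter >= 0, channel_jitter <= 1, noise_sd >= 0)
  for (g in groups) {
    stopifnot(all(g$channels %in% seq_len(n_channels)),
              length(g$band) == 2L, g$band[1] < g$band[2])
    if (g$band[2] > fs / 2)
      stop("group band exceeds the Nyquist frequency")
  }
  for (p in pac) {
    stopifnot(p$depth >= 0, p$depth <= 1)
    if (!all(p$f_p < p$f_a)) stop("PAC links require f_p < f_a")
    if (p$f_a > fs / 2 || any(p$f_p > fs / 2))
      stop("PAC frequencies exceed the Nyquist frequency")
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, n_trials = as.integer(n_trials),
                 t0 = t0, groups = groups, pac = pac,
                 channel_jitter = channel_jitter, noise_sd = noise_sd,
                 sigma = sigma, seed = as.integer(seed)),
            class = "planted_epoch_spec")
}

# Unit-RMS oscillation with frequency drawn uniformly from the band and
# a uniform random phase, both per call (i.e. fresh every trial). The
# trial-to-trial frequency wander is what decorrelates the measured
# time-frequency phases of independent sources across trials; sharing
# one draw across channels is what phase-locks a group.
band_source <- function(n, fs, band) {
  f <- stats::runif(1, band[1], band[2])
  th <- stats::runif(1, 0, 2 * pi)
  sqrt(2) * cos(2 * pi * f * (0:(n - 1L)) / fs + th)
}

#' Generate oscillatory epochs with planted phase locking and PAC
#'
#' Draws the `trial_epochs` described by a [planted_epoch_spec()]. The
#' result is a pure function of the spec (including its seed); the
#' ground-truth group memberships and couplings are returned alongside so
#' that recovery metrics need no external bookkeeping.
#'
#' @param spec a `planted_epoch_spec`.
#' @return list with `epochs` (a `trial_epochs`) and `truth` (the spec's
#'   `groups` and `pac` lists).
#' @export
make_planted_epochs <- function(spec) {
  stopifnot(inherits(spec, "planted_epoch_spec"))
  n <- round(spec$fs * spec$duration)
  nc <- spec$n_channels
  K <- spec$n_trials
  withr::with_seed(spec$seed, {
    data <- array(0, dim = c(nc, n, K))
    for (k in seq_len(K)) {
      # per-group shared source and per-channel contributions
      contrib <- vector("list", length(spec$groups))
      for (gi in seq_along(spec$groups)) {
        g <- spec$groups[[gi]]
        amp <- if (is.null(g$amplitude)) 1 else g$amplitude
        s <- band_source(n, spec$fs, g$band)
        contrib[[gi]] <- lapply(stats::setNames(g$channels, g$channels),
                                function(ch) {
          if (spec$channel_jitter > 0) {
            e <- band_source(n, spec$fs, g$band)
            amp * (sqrt(1 - spec$channel_jitter^2) * s +
                     spec$channel_jitter * e)
          } else amp * s
        })
      }
      noise <- if (spec$noise_sd > 0)
        matrix(stats::rnorm(nc * n, 0, spec$noise_sd), nc, n)
      else matrix(0, nc, n)
      # envelope modulation of the amplitude-band sources, driven by the
      # measured (RID-Rihaczek) low-frequency phase of the phase
      # channel's pre-modulation signal -- the same quantity the dPAC
      # estimator extracts downstream
      if (length(spec$pac)) {
        premod <- noise
        for (gi in seq_along(spec$groups)) {
          g <- spec$groups[[gi]]
          for (ch in g$channels)
            premod[ch, ] <- premod[ch, ] + contrib[[gi]][[as.character(ch)]]
        }
        for (p in spec$pac) {
          ga <- find_group(spec$groups, p$amp_channel, p$f_a)
          tfd_v <- rid_rihaczek(premod[p$phase_channel, ], spec$fs,
                                spec$sigma)
          # f_p may list several phase frequencies; the modulation is
          # spread evenly over them so every phase bin carries coupling
          cosphi <- rowMeans(vapply(p$f_p, function(fp) {
            ph <- cos(low_freq_phase(tfd_v, fp))
            ph[is.na(ph)] <- 0
            ph
          }, numeric(n)))
          env <- 1 + p$depth * cosphi
          key <- as.character(p$amp_channel)
          contrib[[ga]][[key]] <- contrib[[ga]][[key]] * env
        }
      }
      data[, , k] <- noise
      for (gi in seq_along(spec$groups)) {
        g <- spec$groups[[gi]]
        for (ch in g$channels)
          data[ch, , k] <- data[ch, , k] + contrib[[gi]][[as.character(ch)]]
      }
    }
    list(epochs = trial_epochs(data, spec$fs, spec$t0),
         truth = list(groups = spec$groups, pac = spec$pac))
  })
}

find_group <- function(groups, channel, freq) {
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (channel %in% g$channels && freq >= g$band[1] && freq < g$band[2])
      return(gi)
  }
  stop(sprintf("channel %d has no source band containing %g Hz",
               channel, freq))
}
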