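#' Synthetic data with full ground-truth bookkeeping
#'
#' Generators for every input the analyses consume: blinking-channel synapse
#' fields (localization tables), nerve cords of fiducial/target probe clouds,
#' miniature-current amplitude mixtures, docked-vesicle distance tables under
#' stimulation-dependent depletion, and worm centroid tracks. Every generator
#' returns a ledger mapping each observation to its ground truth, so each
#' downstream estimator can be validated by parameter recovery.
#'
#' @name synthgen
NULL

# zero-truncated Poisson ------------------------------------------------------

#' Underlying rate of a zero-truncated Poisson from its observed mean
#'
#' A channel that never blinks is never observed, so the observed
#' blinks-per-channel law is a zero-truncated Poisson. Its observed mean
#' `m = lambda / (1 - exp(-lambda))` is inverted numerically for the
#' underlying rate `lambda` (e.g. observed mean 2.7 gives rate ~2.472).
#'
#' @param mean_obs observed mean, must exceed 1.
#' @return the underlying Poisson rate.
#' @export
ztp_rate <- function(mean_obs) {
  if (!is.finite(mean_obs) || mean_obs <= 1)
    stop("an observed zero-truncated Poisson mean must exceed 1 ",
         "(every observed channel blinked at least once)", call. = FALSE)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_obs,
                 c(1e-8, mean_obs + 10), tol = 1e-10)$root
}

#' Draw zero-truncated Poisson counts
#'
#' Exact inverse-CDF sampling: uniforms are mapped into the untruncated
#' CDF's conditional range `(exp(-lambda), 1]`.
#'
#' @param n number of draws.
#' @param rate underlying (untruncated) Poisson rate.
#' @return integer vector of positive counts.
#' @export
rztpois <- function(n, rate) {
  u <- stats::runif(n)
  stats::qpois(exp(-rate) + u * (1 - exp(-rate)), rate)
}

# photon / precision models ---------------------------------------------------

# log-normal meanlog/sdlog from the distribution's mode and mean
.lognormal_from_mode_mean <- function(mode, mean) {
  stopifnot(mode > 0, mean > mode)
  s2 <- (2 / 3) * log(mean / mode)
  c(meanlog = log(mode) + s2, sdlog = sqrt(s2))
}

# blink localization error: precision = c / sqrt(photons); c calibrated so a
# bright 806-photon blink is localized to 15 nm, putting the photon mode at
# ~17.8 nm, within the 15-29 nm range typical of these recordings
.precision_from_photons <- function(photons, scale = 426) scale / sqrt(photons)

# presets ---------------------------------------------------------------------

#' Channel-field simulation presets
#'
#' Presets bundle the per-probe study conditions: ground-truth channel count,
#' spatial placement model, blinks-per-channel law, photon emission law and
#' the photon-to-precision calibration.
#'
#' * `CaV1`: 79 channels, dispersed hard-core placement (1400 nm field,
#'   100 nm exclusion), observed blink mean 2.7.
#' * `RyR`: 29 channels, dispersed hard-core placement (869 nm field,
#'   100 nm exclusion), observed blink mean 2.7.
#' * `CaV2`: 101 channels densely packed in a 250 nm cluster, observed blink
#'   mean 569/101 (so a synapse shows ~569 blinks per one-minute session).
#'
#' The dispersed fields place channels farther apart than the 60 nm grouping
#' radius plus localization jitter, the operating premise of blink-statistics
#' counting; see the methods vignette for why the CaV1 field is wider than
#' the probe's printed pooled localization spread.
#'
#' @param name `"CaV1"`, `"RyR"` or `"CaV2"`.
#' @return a `synapse_sim_config` list.
#' @export
synapse_preset <- function(name = c("CaV1", "RyR", "CaV2")) {
  name <- match.arg(name)
  placement <- switch(name,
    CaV1 = list(model = "dispersed", extent_nm = 1400, exclusion_nm = 100),
    RyR  = list(model = "dispersed", extent_nm = 869, exclusion_nm = 100),
    CaV2 = list(model = "dense_cluster", diameter_nm = 250))
  cfg <- list(
    preset = name,
    probe = name,
    n_channels = switch(name, CaV1 = 79, RyR = 29, CaV2 = 101),
    placement = placement,
    blink_mean = switch(name, CaV1 = 2.7, RyR = 2.7, CaV2 = 569 / 101),
    photon_mode = 575,
    photon_mean = 765,
    precision_scale = 426,
    duration_s = 60,
    fps = 50,
    background_rate = 0,
    dark_fraction = 0)
  class(cfg) <- "synapse_sim_config"
  cfg
}

.place_channels <- function(n, placement) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  if (placement$model == "dense_cluster") {
    R <- placement$diameter_nm / 2
    r <- R * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    return(cbind(r * cos(th), r * sin(th)))
  }
  # dispersed: random sequential adsorption with a hard-core exclusion
  R <- placement$extent_nm / 2
  excl2 <- placement$exclusion_nm^2
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (try in seq_len(4e5)) {
    r <- R * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th))
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - p[1])^2 +
        (pos[seq_len(placed), 2] - p[2])^2
      if (min(d2) < excl2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
    if (placed == n) return(pos)
  }
  stop("could not place ", n, " channels with ", placement$exclusion_nm,
       " nm exclusion in a ", placement$extent_nm,
       " nm field; the configuration is too dense", call. = FALSE)
}

#' Simulate one synapse's blinking channel field
#'
#' Channels are placed by the preset's spatial model; each visible channel
#' emits a zero-truncated-Poisson number of blinks whose *observed* mean is
#' the preset's blink mean; each blink draws a log-normal photon count, gets
#' a precision of `c/sqrt(photons)`, and is displaced from its channel by
#' isotropic Gaussian error with that precision as per-axis sd. Frames are
#' uniform over the imaging session. Deterministic under a fixed seed.
#'
#' @param cfg a `synapse_sim_config`, e.g. from [synapse_preset()].
#' @param seed optional integer seed.
#' @return list with `locs` (a `loc_set`), `ledger` (list: `channels` data
#'   frame with true positions, blink and photon totals and a `dark` flag;
#'   `blink_channel`, the true source channel of each blink row) and `config`.
#' @export
simulate_synapse <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synapse_sim_config") || is.list(cfg))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_channels
  empty <- localization_set(data.frame(
    x_nm = numeric(), y_nm = numeric(), photons = numeric(),
    frame = integer(), precision_nm = numeric(), probe = character()))
  if (n == 0)
    return(list(locs = empty,
                ledger = list(channels = data.frame(channel = integer(),
                                                    x_nm = numeric(),
                                                    y_nm = numeric(),
                                                    n_blinks = integer(),
                                                    photon_sum = numeric(),
                                                    dark = logical()),
                              blink_channel = integer()),
                config = cfg))
  pos <- .place_channels(n, cfg$placement)
  dark <- stats::runif(n) < cfg$dark_fraction
  rate <- ztp_rate(cfg$blink_mean)
  nb <- integer(n)
  nb[!dark] <- rztpois(sum(!dark), rate)
  src <- rep(seq_len(n), nb)
  ln <- .lognormal_from_mode_mean(cfg$photon_mode, cfg$photon_mean)
  photons <- stats::rlnorm(length(src), ln["meanlog"], ln["sdlog"])
  prec <- .precision_from_photons(photons, cfg$precision_scale)
  locs <- data.frame(
    x_nm = pos[src, 1] + stats::rnorm(length(src), 0, prec),
    y_nm = pos[src, 2] + stats::rnorm(length(src), 0, prec),
    photons = photons,
    frame = sample.int(cfg$duration_s * cfg$fps, length(src), replace = TRUE),
    precision_nm = prec,
    probe = rep(cfg$probe, length(src)))
  ph_sum <- numeric(n)
  if (length(src)) {
    sums <- rowsum(photons, src)
    ph_sum[as.integer(rownames(sums))] <- sums[, 1]
  }
  list(locs = localization_set(locs),
       ledger = list(channels = data.frame(channel = seq_len(n),
                                           x_nm = pos[, 1], y_nm = pos[, 2],
                                           n_blinks = nb,
                                           photon_sum = ph_sum, dark = dark),
                     blink_channel = src),
       config = cfg)
}

# cords of probe clouds for geometry analyses ---------------------------------

#' Geometry presets for probe clouds around the dense projection
#'
#' Per-synapse localization clouds are modelled as isotropic Gaussians offset
#' along the cord axis from the fiducial (dense-projection) cluster centre.
#' The presets plant the measured nanoscale geometry: a tight CaV2 cluster
#' essentially coincident with the fiducial (124 nm offset, 95 percent
#' diameter 297 nm), a dispersed CaV1 field peaking 262 nm away, and a
#' diffuse lateral RyR field 393 nm away.
#'
#' @return named list of target-cloud specs (`offset_nm`, `sd_nm`, `n`).
#' @export
geometry_targets_preset <- function() {
  list(
    CaV2 = list(offset_nm = 124, sd_nm = 297 / 3.92, n = 300),
    CaV1 = list(offset_nm = 262, sd_nm = 869 / 3.92, n = 250),
    RyR  = list(offset_nm = 393, sd_nm = 869 / 3.92, n = 250))
}

#' Simulate a nerve cord of synapses as probe localization clouds
#'
#' Fiducial clusters are planted along the x axis at Gaussian-distributed
#' spacings; each synapse optionally carries target-probe clouds at planted
#' axial offsets. Photon counts and precisions follow the standard blink
#' models so the output is a complete canonical localization table.
#'
#' @param n_synapses number of synapses along the cord.
#' @param spacing_mean_um,spacing_sd_um consecutive-centre spacing law,
#'   default 1.10 +/- 0.16 um.
#' @param fiducial fiducial probe label, default `"ELKS"`.
#' @param fiducial_n localizations per fiducial cluster, default 200.
#' @param fiducial_sd_nm per-axis sd of the fiducial cloud, default 75
#'   (so the 95 percent-interval diameter is ~294 nm).
#' @param targets named list of target clouds as in
#'   [geometry_targets_preset()]; offsets are along the cord (+x).
#' @param seed optional integer seed.
#' @return list with `locs` (a `loc_set` of all probes) and `ledger`
#'   (data frame of true synapse centres and spacings; per-synapse member
#'   counts per probe).
#' @export
simulate_cord <- function(n_synapses = 10, spacing_mean_um = 1.10,
                          spacing_sd_um = 0.16, fiducial = "ELKS",
                          fiducial_n = 200, fiducial_sd_nm = 75,
                          targets = list(), seed = NULL) {
  stopifnot(n_synapses >= 1)
  if (!is.null(seed)) set.seed(seed)
  sp <- pmax(stats::rnorm(n_synapses - 1, spacing_mean_um * 1000,
                          spacing_sd_um * 1000), 100)
  cx <- cumsum(c(0, sp))
  cy <- stats::rnorm(n_synapses, 0, 30)
  ln <- .lognormal_from_mode_mean(575, 765)
  cloud <- function(n, x0, y0, sd, probe) {
    photons <- stats::rlnorm(n, ln["meanlog"], ln["sdlog"])
    data.frame(x_nm = stats::rnorm(n, x0, sd),
               y_nm = stats::rnorm(n, y0, sd),
               photons = photons,
               frame = sample.int(3000, n, replace = TRUE),
               precision_nm = .precision_from_photons(photons),
               probe = probe)
  }
  parts <- list()
  counts <- list()
  for (i in seq_len(n_synapses)) {
    parts[[length(parts) + 1L]] <-
      cloud(fiducial_n, cx[i], cy[i], fiducial_sd_nm, fiducial)
    cnt <- c(stats::setNames(fiducial_n, fiducial))
    for (nm in names(targets)) {
      tg <- targets[[nm]]
      parts[[length(parts) + 1L]] <-
        cloud(tg$n, cx[i] + tg$offset_nm, cy[i], tg$sd_nm, nm)
      cnt[nm] <- tg$n
    }
    counts[[i]] <- cnt
  }
  locs <- localization_set(do.call(rbind, parts))
  ledger <- data.frame(synapse = seq_len(n_synapses), x_nm = cx, y_nm = cy)
  ledger$members <- I(counts)
  list(locs = locs, ledger = ledger,
       spacing_um = sp / 1000)
}

# miniature-current amplitude mixtures ----------------------------------------

#' Quantal mixture presets for miniature-current amplitudes
#'
#' Three-component mixtures of quantal classes k = 1, 2, 3: an event of class
#' k has amplitude `Normal(k * mode, sigma1 * sqrt(k))` (independent quanta
#' sum, so variances add), truncated at 0.
#'
#' * `nemadipine` (CaV1 blocked, release via CaV2 + RyR): mode 7 pA,
#'   weights (0.67, 0.18, 0.15).
#' * `dantrolene_nemadipine` (CaV1 and RyR blocked, release via CaV2 alone):
#'   mode 6 pA, weights (0.75, 0.15, 0.10).
#'
#' The single-quantum width `sigma1 = 2` pA is a generator default (no
#' measured value exists); `noise_sd` adds recording noise, default 0.
#'
#' @param name preset name.
#' @return a `quantal_sim_config` list.
#' @export
quantal_preset <- function(name = c("nemadipine", "dantrolene_nemadipine")) {
  name <- match.arg(name)
  cfg <- switch(name,
    nemadipine = list(preset = name, mode = 7,
                      weights = c(0.67, 0.18, 0.15)),
    dantrolene_nemadipine = list(preset = name, mode = 6,
                                 weights = c(0.75, 0.15, 0.10)))
  cfg$sigma1 <- 2
  cfg$noise_sd <- 0
  class(cfg) <- "quantal_sim_config"
  cfg
}

#' Simulate miniature-current amplitudes from a quantal mixture
#'
#' @param cfg a `quantal_sim_config` (see [quantal_preset()]) or a list with
#'   `mode`, `weights`, `sigma1`, `noise_sd`.
#' @param n number of events.
#' @param seed optional integer seed.
#' @return list with `amplitudes` (pA, all > 0), `classes` (true quantal
#'   class of each retained event) and `n_truncated` (events discarded at 0).
#' @export
simulate_minis <- function(cfg, n, seed = NULL) {
  stopifnot(n >= 0)
  w <- cfg$weights
  stopifnot(abs(sum(w) - 1) < 1e-8, all(w >= 0), cfg$mode > 0)
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(length(w), n, replace = TRUE, prob = w)
  a <- stats::rnorm(n, k * cfg$mode, cfg$sigma1 * sqrt(k))
  if (cfg$noise_sd > 0) a <- a + stats::rnorm(n, 0, cfg$noise_sd)
  keep <- a > 0
  list(amplitudes = a[keep], classes = k[keep], n_truncated = sum(!keep))
}

# docked-vesicle tables -------------------------------------------------------

#' Default docked-vesicle distance profile
#'
#' Mean docked vesicles per synapse per 33 nm bin over 0-594 nm: highest
#' adjacent to the dense projection and decaying laterally to a low plateau,
#' ~11 docked vesicles per synapse in total.
#'
#' @return numeric vector of 18 per-bin means.
#' @export
em_profile_default <- function() 1.8 * exp(-(0:17) / 4) + 0.2

#' Genotype-like depletion presets over the three active-zone zones
#'
#' Per-bin fusion probabilities built from zone patterns: zone 1 adjacent to
#' the dense projection (0-33 nm, central pool, CaV2-driven), zone 2 the
#' intermediate active zone (33-165 nm, CaV2-activated RyR), zone 3 the
#' lateral active zone (165-594 nm, CaV1/RyR-driven).
#'
#' @param name one of `"wild_type"` (uniform 0.5), `"cav2_null"` (no central
#'   fusion), `"ryr_null"` (central fusion only), `"cav1_hypo"` (reduced
#'   everywhere), `"cav1_cav2_null"` (no fusion).
#' @return numeric vector of 18 per-bin depletion probabilities.
#' @export
em_depletion_preset <- function(name = c("wild_type", "cav2_null", "ryr_null",
                                         "cav1_hypo", "cav1_cav2_null")) {
  name <- match.arg(name)
  zones <- switch(name,
    wild_type = c(0.5, 0.5, 0.5),
    cav2_null = c(0, 0.5, 0.5),
    ryr_null = c(0.5, 0, 0),
    cav1_hypo = c(0.2, 0.2, 0.2),
    cav1_cav2_null = c(0, 0, 0))
  c(zones[1], rep(zones[2], 4), rep(zones[3], 13))
}

#' Simulate docked-vesicle distance tables for both stimulation conditions
#'
#' Unstimulated and stimulated synapse cohorts are drawn independently.
#' Per-synapse per-bin docked counts are Poisson around `profile`; in the
#' stimulated cohort each vesicle then fuses (is removed) independently with
#' its bin's depletion probability. Distances are uniform within their bin.
#'
#' @param n_synapses synapses per condition.
#' @param profile per-bin mean docked counts (33 nm bins from 0),
#'   default [em_profile_default()].
#' @param depletion per-bin fusion probabilities in `[0, 1]`, same length as
#'   `profile`.
#' @param genotype label stored in the tables.
#' @param seed optional integer seed.
#' @return list with `no_stim` and `stim` vesicle distance tables (data
#'   frames: `synapse_id`, `genotype`, `condition`, `distance_nm`, including
#'   zero-vesicle synapses via the `synapses` attribute), and `ledger`.
#' @export
simulate_vesicle_profiles <- function(n_synapses, profile = em_profile_default(),
                                      depletion = em_depletion_preset("wild_type"),
                                      genotype = "synthetic", seed = NULL) {
  stopifnot(length(profile) == length(depletion),
            all(depletion >= 0), all(depletion <= 1), all(profile >= 0))
  if (!is.null(seed)) set.seed(seed)
  nb <- length(profile)
  bin <- 33
  draw <- function(condition, thin) {
    rows <- list()
    for (s in seq_len(n_synapses)) {
      cnt <- stats::rpois(nb, profile)
      if (thin) cnt <- stats::rbinom(nb, cnt, 1 - depletion)
      k <- rep(seq_len(nb) - 1L, cnt)
      if (length(k))
        rows[[length(rows) + 1L]] <- data.frame(
          synapse_id = paste0(condition, "_", s), genotype = genotype,
          condition = condition,
          distance_nm = (k + stats::runif(length(k))) * bin)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(synapse_id = character(), genotype = character(),
                 condition = character(), distance_nm = numeric())
    attr(tab, "synapses") <- paste0(condition, "_", seq_len(n_synapses))
    tab
  }
  list(no_stim = draw("no_stim", FALSE), stim = draw("stim", TRUE),
       ledger = list(profile = profile, depletion = depletion,
                     n_synapses = n_synapses))
}

# worm tracks -----------------------------------------------------------------

#' Default locomotion bout model
#'
#' Semi-Markov alternation of forward runs, reversals and pauses with
#' parameters near healthy wild-type crawling: ~300 um/s path speed while
#' moving, ~2 reversals per minute of ~2.2 s, occasional pauses.
#'
#' @return list of bout-model parameters.
#' @export
bout_model_default <- function() {
  list(forward_mean_s = 15, forward_speed = 300, forward_speed_sd = 25,
       p_reverse = 0.8, reverse_mean_s = 2.2, reverse_speed = 250,
       reverse_speed_sd = 25, pause_mean_s = 12, pause_speed = 5,
       turn_sd = 0.1)
}

#' Simulate worm centroid tracks
#'
#' Each worm alternates forward, reversal and pause bouts per the bout model;
#' within a bout the path speed is constant and the heading performs a small
#' random walk (a reversal flips it). Positions are the cumulative path at
#' the frame rate; the per-frame state is recorded both in the track and in
#' the bout ledger.
#'
#' @param n_worms number of worms.
#' @param fps frames per second, default 8.
#' @param duration_s recording length, default 300 (5 min).
#' @param bout_model see [bout_model_default()].
#' @param seed optional integer seed.
#' @return list with `tracks` (list of data frames: `worm_id`, `t_s`, `x_um`,
#'   `y_um`, `direction` in forward/reverse/pause) and `ledger` (data frame
#'   of true bouts: `worm_id`, `state`, `start_frame`, `end_frame`,
#'   `n_frames`).
#' @export
simulate_tracks <- function(n_worms = 10, fps = 8, duration_s = 300,
                            bout_model = bout_model_default(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bm <- bout_model
  n_frames <- duration_s * fps
  tracks <- vector("list", n_worms)
  bouts <- list()
  for (w in seq_len(n_worms)) {
    state <- "forward"
    dirs <- character(n_frames)
    speeds <- numeric(n_frames)
    f <- 1L
    while (f <= n_frames) {
      len <- switch(state,
        forward = stats::rexp(1, 1 / bm$forward_mean_s),
        reverse = stats::rexp(1, 1 / bm$reverse_mean_s),
        pause = stats::rexp(1, 1 / bm$pause_mean_s))
      len <- max(1L, round(len * fps))
      spd <- switch(state,
        forward = stats::rnorm(1, bm$forward_speed, bm$forward_speed_sd),
        reverse = stats::rnorm(1, bm$reverse_speed, bm$reverse_speed_sd),
        pause = abs(stats::rnorm(1, bm$pause_speed, 2)))
      end <- min(n_frames, f + len - 1L)
      dirs[f:end] <- state
      speeds[f:end] <- max(spd, 0)
      bouts[[length(bouts) + 1L]] <-
        data.frame(worm_id = w, state = state, start_frame = f,
                   end_frame = end, n_frames = end - f + 1L)
      f <- end + 1L
      state <- if (state == "forward") {
        if (stats::runif(1) < bm$p_reverse) "reverse" else "pause"
      } else "forward"
    }
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n_frames - 1, 0, bm$turn_sd)))
    sign <- ifelse(dirs == "reverse", -1, 1)
    step <- speeds / fps * sign
    x <- cumsum(c(0, (step * cos(heading))[-n_frames]))
    y <- cumsum(c(0, (step * sin(heading))[-n_frames]))
    tracks[[w]] <- data.frame(worm_id = w, t_s = (seq_len(n_frames) - 1) / fps,
                              x_um = x, y_um = y, direction = dirs)
  }
  list(tracks = tracks, ledger = do.call(rbind, bouts))
}
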