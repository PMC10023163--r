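test_that("generators are deterministic under a fixed seed", {
  a <- simulate_synapse(synapse_preset("CaV1"), seed = 3)
  b <- simulate_synapse(synapse_preset("CaV1"), seed = 3)
  expect_identical(a, b)
  expect_identical(simulate_minis(quantal_preset("nemadipine"), 500, seed = 3),
                   simulate_minis(quantal_preset("nemadipine"), 500, seed = 3))
  expect_identical(simulate_tracks(2, seed = 3), simulate_tracks(2, seed = 3))
})

test_that("zero-truncated Poisson blink law solves and samples correctly", {
  # numeric root-find oracle: lambda / (1 - exp(-lambda)) = 2.7 at ~2.472
  oracle <- stats::uniroot(function(l) l / (1 - exp(-l)) - 2.7, c(0.1, 10),
                           tol = 1e-12)$root
  expect_equal(ztp_rate(2.7), oracle, tolerance = 1e-8)
  expect_equal(ztp_rate(2.7), 2.4721, tolerance = 1e-4)
  expect_error(ztp_rate(1), "exceed 1")
  set.seed(21)
  draws <- rztpois(1e4, ztp_rate(2.7))
  expect_true(all(draws >= 1))
  expect_equal(mean(draws), 2.7, tolerance = 0.05)
})

test_that("synapse ledger is self-consistent and matches the blink law", {
  sim <- simulate_synapse(synapse_preset("CaV1"), seed = 5)
  led <- sim$ledger
  expect_equal(nrow(led$channels), 79)
  expect_equal(length(led$blink_channel), nrow(sim$locs))
  # grouping by the ledger's own assignments reproduces the channel count
  expect_equal(length(unique(led$blink_channel)),
               sum(led$channels$n_blinks > 0))
  expect_equal(sum(led$channels$n_blinks > 0), 79)  # no dark channels
  expect_equal(tabulate(led$blink_channel, nbins = 79), led$channels$n_blinks)
  # hard-core placement honours the exclusion distance
  d <- stats::dist(cbind(led$channels$x_nm, led$channels$y_nm))
  expect_gte(min(d), 100)
  # empty config
  cfg <- synapse_preset("CaV1"); cfg$n_channels <- 0
  empty <- simulate_synapse(cfg, seed = 1)
  expect_equal(nrow(empty$locs), 0)
  expect_equal(nrow(empty$ledger$channels), 0)
})

test_that("photon model reproduces its mode and mean", {
  cfg <- synapse_preset("CaV2")
  cfg$n_channels <- 20000  # pool many channels for a stable histogram
  sim <- simulate_synapse(cfg, seed = 8)
  ph <- sim$locs$photons
  expect_gt(length(ph), 5e4)
  expect_equal(mean(ph), 765, tolerance = 0.02)
  k <- floor(ph / 50)
  mode_bin <- as.numeric(names(which.max(table(k)))) * 50 + 25
  expect_equal(mode_bin, 575, tolerance = 0.02)
  # precision follows c / sqrt(photons) within the typical 15-30 nm band
  expect_equal(sim$locs$precision_nm, 426 / sqrt(ph))
  expect_equal(stats::median(sim$locs$precision_nm), 16, tolerance = 0.15)
})

test_that("mini mixtures hit their planted weights and moments", {
  degenerate <- list(mode = 7, weights = c(1, 0, 0), sigma1 = 1e-9,
                     noise_sd = 0)
  m0 <- simulate_minis(degenerate, 100, seed = 2)
  expect_equal(m0$amplitudes, rep(7, 100), tolerance = 1e-6)
  m1 <- simulate_minis(quantal_preset("nemadipine"), 1e5, seed = 2)
  freq <- as.vector(table(m1$classes)) / length(m1$classes)
  expect_true(all(abs(freq - c(0.67, 0.18, 0.15)) < 0.005))
  m2 <- simulate_minis(quantal_preset("dantrolene_nemadipine"), 1e5, seed = 3)
  # closed-form mixture mean: sum_k w_k * k * mode = 1.35 * 6 = 8.1 pA
  expect_equal(mean(m2$amplitudes), 8.1, tolerance = 0.01)
})

test_that("vesicle-table thinning matches the binomial oracle", {
  same <- simulate_vesicle_profiles(300, depletion = rep(0, 18), seed = 4)
  fp0 <- fusion_profile(bin_docked(same$no_stim), bin_docked(same$stim))
  pooled_sem <- sqrt(fp0$sem_no_stim^2 + fp0$sem_stim^2)
  expect_true(all(abs(fp0$fusion) < 3.5 * pooled_sem))
  only0 <- simulate_vesicle_profiles(50, depletion = c(1, rep(0, 17)),
                                     seed = 5)
  h <- bin_docked(only0$stim)
  expect_true(all(h[, 1] == 0))
  half <- simulate_vesicle_profiles(500, depletion = rep(0.5, 18), seed = 6)
  ns <- bin_docked(half$no_stim); st <- bin_docked(half$stim)
  fp <- fusion_profile(ns, st)
  rec <- fp$fusion / fp$mean_no_stim
  # per-bin recovery within 3 SEM (delta method on the ratio of means)
  sem <- sqrt(apply(st, 2, var) / nrow(st) / colMeans(ns)^2 +
                colMeans(st)^2 * apply(ns, 2, var) / nrow(ns) /
                  colMeans(ns)^4)
  expect_true(all(abs(rec - 0.5) < 3 * sem))
  # and the high-occupancy bin adjacent to the dense projection within 0.05
  expect_lt(abs(rec[1] - 0.5), 0.05)
})

test_that("track generator plants recoverable bouts", {
  bm <- bout_model_default()
  bm$p_reverse <- 0
  tr0 <- simulate_tracks(3, bout_model = bm, seed = 7)
  expect_true(all(vapply(tr0$tracks,
                         function(t) nrow(detect_reversals(t)), numeric(1)) == 0))
  tr <- simulate_tracks(4, seed = 8)
  for (w in 1:4) {
    led <- tr$ledger[tr$ledger$worm_id == w & tr$ledger$state == "reverse" &
                       tr$ledger$n_frames > 4, ]
    det <- detect_reversals(tr$tracks[[w]])
    expect_equal(nrow(det), nrow(led))
    expect_equal(det$start_frame, led$start_frame)
  }
})
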