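test_that("blink grouping follows the density-clustering definition", {
  g1 <- group_blinks(make_locs(c(0, 30), c(0, 0)))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$blink_count, 2)
  expect_false(g1$is_singlet)
  g2 <- group_blinks(make_locs(c(0, 70), c(0, 0)))
  expect_equal(nrow(g2), 2)
  expect_true(all(g2$is_singlet))
  # chain: each link within 60 nm, ends 100 nm apart -> density-reachable
  g3 <- group_blinks(make_locs(c(0, 50, 100), c(0, 0, 0)))
  expect_equal(nrow(g3), 1)
  expect_equal(g3$blink_count, 3)
  expect_equal(nrow(group_blinks(make_locs(numeric(), numeric()))), 0)
})

test_that("groups partition the blinks and match the eps-graph oracle", {
  set.seed(5)
  for (case in 1:3) {
    xy <- cbind(rnorm(300, sd = 200), rnorm(300, sd = 200))
    g <- group_blinks(xy)
    lab <- attr(g, "membership")
    expect_equal(sum(g$blink_count), 300)
    expect_equal(tabulate(lab, nrow(g)), g$blink_count)
    oracle <- brute_components(xy, 60)
    # same partition up to label permutation
    expect_equal(length(unique(oracle)), nrow(g))
    expect_true(all(tapply(oracle, lab, function(v) length(unique(v))) == 1))
    # merging any two groups would violate eps-connectivity
    if (nrow(g) >= 2) {
      cd <- as.matrix(stats::dist(xy))
      inter <- cd[lab == g$group_id[1], lab == g$group_id[2], drop = FALSE]
      expect_gt(min(inter), 60)
    }
  }
})

test_that("group centroids and photon sums are bookkept", {
  locs <- make_locs(c(0, 30, 500), c(0, 0, 0), photons = c(100, 200, 700))
  g <- group_blinks(locs)
  g <- g[order(g$x_nm), ]
  expect_equal(g$x_nm, c(15, 500))
  expect_equal(g$photon_sum, c(300, 700))
})

test_that("the Poisson blink fit is the sample mean", {
  expect_equal(fit_blink_poisson(c(2, 2, 2)), 2)
  expect_equal(fit_blink_poisson(c(1, 2, 3)), 2)
  set.seed(6)
  counts <- rztpois(1e4, ztp_rate(2.7))
  expect_equal(fit_blink_poisson(counts), 2.7, tolerance = 0.02)
})

test_that("count estimators implement their defining ratios", {
  expect_equal(estimate_by_blink_mean(27, 2.7), 10)
  expect_error(estimate_by_blink_mean(27, 0), "positive")
  expect_equal(estimate_by_photon_flux(19960, 1996), 10)
  expect_equal(estimate_by_photon_flux(1996, 1996), 1)
  expect_equal(estimate_by_blink_rate(60, 6, 1), 10)
  expect_equal(estimate_by_blink_rate(569), 94.83, tolerance = 1e-3)
  expect_equal(estimate_by_blink_rate(569, rate = 12), 94.83 / 2,
               tolerance = 1e-3)
})

test_that("ledger-perfect grouping recovers the true channel count exactly", {
  sims <- lapply(1:20, function(i) simulate_synapse(synapse_preset("CaV1")))
  counts <- unlist(lapply(sims, function(s) {
    led <- s$ledger
    led$channels$n_blinks[led$channels$n_blinks > 0]
  }))
  m <- fit_blink_poisson(counts)
  est <- vapply(sims, function(s) estimate_by_blink_mean(nrow(s$locs), m),
                numeric(1))
  expect_equal(mean(est), 79, tolerance = 1e-12)
})

test_that("photon statistics report binned modes and arithmetic means", {
  locs <- make_locs(c(0, 500, 1000), c(0, 0, 0), photons = 575)
  g <- group_blinks(locs)
  ps <- photon_stats(locs, g)
  expect_equal(ps$mode_per_blink, 575)
  expect_equal(ps$mean_per_blink, 575)
  # channels of one blink each: per-channel stats equal per-blink stats
  expect_equal(ps$mean_per_channel, ps$mean_per_blink)
  expect_equal(ps$mode_per_channel, ps$mode_per_blink)
})

test_that("packing bounds reproduce the published capacities", {
  expect_equal(packing_bound(250, 250), 1L)
  expect_equal(packing_bound(250, 60, "optimal_ratio"), 12L)
  expect_equal(packing_bound(250, 300), 0L)
  # explicit centre-anchored lattice enumeration gives 121 for 20 nm circles
  expect_equal(packing_bound(250, 20, "hex_lattice"), 121L)
  caps <- vapply(seq(20, 250, by = 5), function(d)
    packing_bound(250, d, "hex_lattice"), integer(1))
  expect_true(all(diff(caps) <= 0))
  caps2 <- vapply(seq(20, 250, by = 5), function(d)
    packing_bound(250, d, "optimal_ratio"), integer(1))
  expect_true(all(diff(caps2) <= 0))
})

test_that("the cohort pipeline wires estimators to pooled statistics", {
  set.seed(7)
  sims <- lapply(1:30, function(i) simulate_synapse(synapse_preset("RyR"))$locs)
  cc <- count_channels(sims)
  expect_equal(nrow(cc$per_synapse), 30)
  expect_equal(cc$per_synapse$est_blink_mean,
               cc$per_synapse$total_blinks / cc$pooled$m)
  expect_true(all(cc$per_synapse$est_blink_mean <=
                    cc$per_synapse$total_blinks))
  expect_equal(mean(cc$per_synapse$est_blink_mean), 29, tolerance = 0.12)
})
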