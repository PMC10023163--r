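test_that("write/read round trip preserves all fields", {
  sim <- simulate_synapse(synapse_preset("RyR"), seed = 71)
  locs <- sim$locs
  # pad to 1000 records by replication with perturbed coordinates
  idx <- rep_len(seq_len(nrow(locs)), 1000)
  locs <- localization_set(transform(locs[idx, ],
                                     x_nm = x_nm + seq_len(1000) * 1e-3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, path)
  back <- read_localizations(path)
  for (cl in c("x_nm", "y_nm", "photons", "frame", "precision_nm"))
    expect_equal(back[[cl]], locs[[cl]], tolerance = 1e-6)
  expect_identical(back$probe, locs$probe)
})

test_that("dialects map columns and convert micron units to nm", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,photons,probe,precision",
               "1.5,2,600,CaV1,0.02",
               "3,4,700,CaV1,0.03"), path)
  locs <- read_localizations(path, dialect = "xy_um")
  expect_equal(locs$x_nm, c(1500, 3000))
  expect_equal(locs$precision_nm, c(20, 30))
})

test_that("format errors name the offending column and line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,photons", "1,2,3"), path)
  expect_error(read_localizations(path), "probe")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,photons,probe", "1,2,3,A", "oops,2,3,A"), path2)
  expect_error(read_localizations(path2), "line 3")
  expect_error(read_localizations("no/such/file.csv"), "not found")
})

test_that("precision filter is inclusive at the threshold and idempotent", {
  locs <- make_locs(1:4, 1:4, precision = c(15, 79, 80, 81))
  kept <- filter_precision(locs)
  expect_equal(kept$precision_nm, c(15, 79, 80))
  expect_equal(kept$x_nm, c(1, 2, 3))  # order preserved
  expect_identical(filter_precision(kept), kept)
  all15 <- make_locs(1:5, 1:5, precision = 15)
  expect_identical(filter_precision(all15), all15)
  # empirical CDF oracle on a big synthetic draw
  set.seed(4)
  prec <- stats::rlnorm(1e4, log(40), 0.6)
  big <- make_locs(seq_len(1e4), seq_len(1e4), precision = prec)
  expect_equal(nrow(filter_precision(big)) / 1e4, mean(prec <= 80))
  no_prec <- localization_set(data.frame(x_nm = 1, y_nm = 1, photons = 1,
                                         probe = "A"))
  expect_error(filter_precision(no_prec), "precision_nm")
})

test_that("flatten_z drops z and leaves lateral geometry untouched", {
  locs <- make_locs(c(0, 3, 10), c(0, 4, 0), z = c(10, -40, 7))
  flat <- flatten_z(locs)
  expect_null(flat$z_nm)
  d_before <- stats::dist(cbind(locs$x_nm, locs$y_nm))
  d_after <- stats::dist(cbind(flat$x_nm, flat$y_nm))
  expect_equal(as.numeric(d_after), as.numeric(d_before))
  expect_identical(flatten_z(flat), flat)  # no z is a no-op
})

test_that("segment_rois applies the 700 nm window around fiducial centres", {
  fid <- make_blob(0, 0)
  probes <- make_locs(c(650, 750), c(0, 0), probe = "CaV2")
  rois <- segment_rois(rbind(fid, probes), "ELKS", min_size = 20)
  expect_length(rois, 1)
  mem <- rois[[1]]$members
  expect_true(650 %in% mem$x_nm[mem$probe == "CaV2"])
  expect_false(750 %in% mem$x_nm[mem$probe == "CaV2"])
})

test_that("distinct fiducial clusters give disjoint ROIs with tie-breaking", {
  locs <- rbind(make_blob(0, 0), make_blob(2000, 0),
                make_locs(c(600, 1500), c(0, 0), probe = "CaV1"))
  rois <- segment_rois(locs, "ELKS", min_size = 20)
  expect_length(rois, 2)
  n1 <- nrow(rois[[1]]$members); n2 <- nrow(rois[[2]]$members)
  expect_lte(n1 + n2, nrow(locs))
  # the 1500 nm point is within 700 of the second centre only
  expect_true(1500 %in% rois[[2]]$members$x_nm)
  # equidistant point between centres 1200 apart goes to the lower roi_id
  locs2 <- rbind(make_blob(0, 0), make_blob(1200, 0),
                 make_locs(600, 0, probe = "CaV1"))
  rois2 <- segment_rois(locs2, "ELKS", min_size = 20)
  expect_true("CaV1" %in% rois2[[1]]$members$probe)
  expect_false("CaV1" %in% rois2[[2]]$members$probe)
})

test_that("cord segmentation matches generator bookkeeping", {
  cord <- simulate_cord(10, targets = list(CaV2 = list(offset_nm = 100,
                                                       sd_nm = 60, n = 50)),
                        seed = 9)
  rois <- segment_rois(cord$locs, "ELKS")
  expect_length(rois, 10)
  counts <- vapply(rois, function(r) nrow(r$members), numeric(1))
  # every localization lands in exactly one window at ~1.1 um spacing
  expect_equal(sum(counts), nrow(cord$locs))
  for (r in rois) {
    d <- sqrt((r$members$x_nm - r$center[1])^2 +
                (r$members$y_nm - r$center[2])^2)
    expect_true(all(d <= 700))
  }
  expect_warning(segment_rois(make_locs(1, 1, probe = "CaV1"), "ELKS"),
                 "no localizations")
})
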