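# Anagen wave propagation, barrier blocking and aperture distortion.
# A head-to-tail onset gradient establishes a traveling anagen wave; the
# barrier/aperture runs are paired with an open-lattice run on the same
# seed and geometry, and analyzed on an established (third) cycle.

test_that("established anagen waves travel head-to-tail monotonically", {
  m <- unclass(onset_map(open_record(), 3))
  prof <- rowMeans(m)
  expect_true(all(diff(prof) > 0))
  expect_gt(max(prof) - min(prof), 3)  # finite speed: days to cross
})

test_that("arrival behind a barrier is later than in the open lattice", {
  mb <- unclass(onset_map(barrier_record(), 3))
  mo <- unclass(onset_map(open_record(), 3))
  rel_b <- mb - min(mb, na.rm = TRUE)
  rel_o <- mo - min(mo, na.rm = TRUE)
  behind <- rel_b[9:11, 6:11] - rel_o[9:11, 6:11]
  expect_true(all(behind > 0))
  expect_gt(max(behind), 0.25)
  # well upstream of the barrier the wave is essentially unaffected
  expect_lt(max(abs(rel_b[1:4, ] - rel_o[1:4, ])), 0.3)
})

test_that("sites enclosed by barriers are unreachable by exchange", {
  box <- rbind(cbind(4, 4:8), cbind(8, 4:8), cbind(5:7, 4), cbind(5:7, 8))
  lat <- build_lattice(10, 10, coupling_strength = 0.05,
                       features = list(barrier = box))
  inside <- which(lat$site_row %in% 5:7 & lat$site_col %in% 5:7)
  deg <- rowSums(lat$adjacency)
  # interior 3x3 pocket: connected among themselves but not to the outside
  reach <- lat$adjacency
  for (i in 1:20) reach <- pmin(reach + reach %*% lat$adjacency, 1)
  outside <- setdiff(seq_along(lat$sites), inside)
  expect_true(all(reach[inside, outside] == 0))
  expect_true(all(deg[inside] > 0))
})

test_that("aperture fronts bow outward: distortion exceeds the open front", {
  wf_a <- wavefront_arrival(aperture_record(), 3)
  wf_o <- wavefront_arrival(open_record(), 3)
  expect_gt(wf_a$distortion, 0)
  expect_gt(wf_a$distortion, 2 * abs(wf_o$distortion))
  # open lattice: planar front, distortion within discretization
  expect_lt(abs(wf_o$distortion), 1)
  expect_gt(length(wf_a$contours), 0)
})

test_that("waves do not propagate into a hyper-refractory domain", {
  rec <- cached("ear_record", {
    cfg <- preset_config("ear_hyper_refractory")
    cfg$numerics$horizon <- 200
    run_scenario(cfg, file.path(tempdir(), "ear_test"))$result
  })
  lat <- rec$lattice
  ear <- which(lat$domain[lat$sites] == "Ear")
  cranial <- which(lat$domain[lat$sites] == "Cranial")
  tr <- rec$transitions[rec$transitions$to == "anagen", ]
  # anagen sweeps the cranial stripe...
  expect_gt(length(unique(tr$site[tr$site %in% cranial])),
            0.9 * length(cranial))
  # ...but no ear site enters anagen by propagation
  expect_equal(sum(tr$site %in% ear), 0)
})
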