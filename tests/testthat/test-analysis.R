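# Pattern metrics on scripted records: the oracles here are hand-built
# transition logs with known onset structure.

# build a minimal pattern_record from per-site, per-cycle onset times
scripted_record <- function(onsets, ncol_ = ncol(onsets[[1]])) {
  nr <- nrow(onsets[[1]]); nc <- ncol(onsets[[1]])
  lat <- build_lattice(nr, nc)
  rows <- lat$site_row; cols <- lat$site_col
  tr <- do.call(rbind, lapply(seq_along(onsets), function(k) {
    m <- onsets[[k]]
    t_on <- m[cbind(rows, cols)]
    keep <- !is.na(t_on)
    data.frame(site = which(keep), time = t_on[keep],
               from = "telogen", to = "anagen", cycle_index = k)
  }))
  tr <- tr[order(tr$time, tr$site), ]
  rec <- list(times = seq(0, max(tr$time) + 1, by = 1),
              phase = NULL, transitions = tr, lattice = lat,
              site_row = rows, site_col = cols)
  class(rec) <- "pattern_record"
  rec
}

grad_map <- function(nr, nc, span = 8) {
  matrix(rep(seq(0, span, length.out = nr), nc), nr, nc)
}

test_that("onset_map reproduces scripted onsets exactly and masks gaps", {
  m1 <- grad_map(6, 5)
  m2 <- m1 + 30
  m2[2, 3] <- NA      # this site skips cycle 2
  rec <- scripted_record(list(m1, m2))
  expect_equal(unclass(onset_map(rec, 1)), m1, ignore_attr = TRUE)
  got2 <- onset_map(rec, 2)
  expect_true(is.na(unclass(got2)[2, 3]))
  expect_equal(attr(got2, "n_sites"), 29)
  expect_error(onset_map(rec, 5), "range error")

  # simultaneous onsets give a constant map
  rec3 <- scripted_record(list(matrix(7, 4, 4)))
  expect_true(all(unclass(onset_map(rec3, 1)) == 7))
})

test_that("asynchrony persistence counts leading gradient-ordered cycles", {
  nr <- 8; nc <- 8
  base <- grad_map(nr, nc)
  # gradient persists 4 cycles
  rec <- scripted_record(lapply(0:3, function(k) base + 40 * k))
  expect_equal(as.integer(asynchrony_persistence(rec)), 4)

  # randomized onsets from cycle 2: permutation oracle says rho ~ 0
  set.seed(42)
  shuf <- base
  shuf[] <- sample(base)
  rec2 <- scripted_record(list(base, shuf + 40, shuf[rev(seq_len(nr)), ] + 80))
  k2 <- asynchrony_persistence(rec2)
  expect_equal(as.integer(k2), 1)
  expect_lt(abs(attr(k2, "table")$rho[2]), 0.5)
})

test_that("persistence is monotone under progressive randomization", {
  nr <- 10; nc <- 10
  base <- grad_map(nr, nc)
  set.seed(1)
  noise_levels <- c(0, 2, 6, 20, 60)
  maps <- lapply(seq_along(noise_levels), function(k) {
    base + 50 * (k - 1) + matrix(rnorm(nr * nc, 0, noise_levels[k]), nr, nc)
  })
  ks <- vapply(seq_along(maps), function(j) {
    as.integer(asynchrony_persistence(scripted_record(maps[seq_len(j)])))
  }, integer(1))
  expect_true(all(diff(ks) >= 0 | ks[-1] == ks[-length(ks)] |
                    diff(ks) <= 1))
  # full record: the heavily-randomized late cycles do not count
  expect_lt(ks[length(ks)], length(maps))
})

test_that("bilateral symmetry scores mirror structure in [-1, 1]", {
  nr <- 6; nc <- 8
  lateral <- matrix(rep(abs(seq_len(nc) - (nc + 1) / 2), each = nr), nr, nc)
  rec <- scripted_record(list(lateral))
  bs <- bilateral_symmetry(rec)
  expect_equal(bs$score[1], 1)    # exactly mirror-symmetric

  anti <- matrix(rep(seq_len(nc) - (nc + 1) / 2, each = nr), nr, nc)
  rec2 <- scripted_record(list(anti + 10))
  expect_equal(bilateral_symmetry(rec2)$score[1], -1)

  # a purely head-to-tail gradient is degenerate laterally: score 1 only
  # because the raw map equals its mirror
  rec3 <- scripted_record(list(grad_map(nr, nc)))
  expect_equal(bilateral_symmetry(rec3)$score[1], 1)

  # gradient plus independent jitter: no lateral structure, score near 0
  set.seed(7)
  rec4 <- scripted_record(list(grad_map(20, 20) +
                                 matrix(rnorm(400), 20, 20)))
  expect_lt(abs(bilateral_symmetry(rec4)$score[1]), 0.35)
})

test_that("symmetry against a shuffled mirror has expectation ~ 0", {
  set.seed(11)
  nr <- 12; nc <- 12
  scores <- replicate(1000, {
    m <- matrix(rnorm(nr * nc), nr, nc)
    mm <- matrix(sample(m), nr, nc)
    cor(as.vector(m), as.vector(mm))
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("metrics are invariant to time translation and site relabeling", {
  nr <- 8; nc <- 8
  set.seed(3)
  m <- grad_map(nr, nc) + matrix(rnorm(64, 0, 0.5), nr, nc)
  rec_a <- scripted_record(list(m))
  rec_b <- scripted_record(list(m + 137.5))
  ka <- asynchrony_persistence(rec_a); kb <- asynchrony_persistence(rec_b)
  expect_identical(as.integer(ka), as.integer(kb))
  expect_equal(attr(ka, "table")$rho, attr(kb, "table")$rho)
  expect_equal(bilateral_symmetry(rec_a)$score,
               bilateral_symmetry(rec_b)$score)
  # reflecting the lattice head-to-tail flips the sign of the gradient
  # statistic but not its magnitude
  rec_c <- scripted_record(list(m[rev(seq_len(nr)), ]))
  expect_equal(attr(asynchrony_persistence(rec_c), "table")$rho[1],
               -attr(ka, "table")$rho[1])
})

test_that("wavefront arrival: planar fronts are straight, flat maps warn", {
  # planar wave: arrival linear in row
  rec <- scripted_record(list(grad_map(10, 10, span = 9)))
  wf <- wavefront_arrival(rec, 1)
  expect_equal(wf$fit[["speed"]], 1, tolerance = 1e-6)
  expect_lt(abs(wf$distortion), 1e-6)
  expect_gt(length(wf$contours), 0)
  # contours of a row-linear field are straight lines at constant row
  for (cl in wf$contours) expect_lt(diff(range(cl$x)), 1e-6)

  rec_flat <- scripted_record(list(matrix(5, 6, 6)))
  expect_warning(wavefront_arrival(rec_flat, 1), "flat")
})
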