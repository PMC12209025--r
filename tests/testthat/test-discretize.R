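test_that("a stationary animal in the centre occupies no segments", {
  g <- geom50()
  tr <- tracking_series(seq(0, 10, by = 0.04), rep(0, 251), rep(0, 251))
  occ <- discretize(tr, g)
  expect_true(all(lengths(occ$records) == 0))
  expect_equal(occ$n_centre, 251L)
  neg <- compute_neg(occ, g, "total")
  expect_true(all(neg$neg == 0))
})

test_that("a constant 1 cm/s run visits one new segment per second", {
  g <- geom50()
  occ <- discretize(run_track(speed = 1, duration = 50), g)
  neg <- compute_neg(occ, g, "open")
  expect_equal(neg$neg[neg$time == 10], 10)
  expect_equal(neg$neg[neg$time == 50], 50)  # all 50 arm-1 segments
  # one new segment per second over the run
  expect_equal(diff(neg$neg[neg$time >= 1]), rep(1, 49))
  # total scope is half the open percentage at every time (200 vs 100)
  negT <- compute_neg(occ, g, "total")
  expect_equal(negT$neg, neg$neg / 2)
})

test_that("interpolation recovers segments skipped by fast movement", {
  g <- geom50()
  # 5 Hz sampling at 30 cm/s: consecutive samples 6 cm apart
  tr <- run_track(speed = 30, duration = 1.8, frame_rate = 5)
  expect_warning(occ_off <- discretize(tr, g, interpolate = FALSE),
                 "cm/s")
  expect_warning(occ_on <- discretize(tr, g, interpolate = TRUE), "cm/s")
  seg_off <- sort(unique(unlist(occ_off$records)))
  seg_on <- sort(unique(unlist(occ_on$records)))
  expect_true(all(seg_off %in% seg_on))
  expect_gt(length(seg_on), length(seg_off))
  # the interpolated run leaves no gaps along the covered depth range
  expect_equal(seg_on, seq_len(max(seg_on)))
  # threshold is configurable
  expect_silent(discretize(tr, g, speed_warn = 100))
})

test_that("discretisation is deterministic and rejects empty tracks", {
  g <- geom50()
  tr <- run_track(speed = 3, duration = 20)
  o1 <- discretize(tr, g)
  o2 <- discretize(tr, g)
  expect_identical(o1$records, o2$records)
  expect_identical(o1$zone, o2$zone)
  expect_error(tracking_series(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("halving the grid resolution never loses visited coverage", {
  g1 <- epm_geometry(grid_resolution = 2)
  g2 <- epm_geometry(grid_resolution = 1)
  set.seed(42)
  for (r in 1:5) {
    # random walk along open arm 1
    t <- seq(0, 30, by = 0.1)
    x <- 5 + cumsum(abs(rnorm(length(t), 0.3, 0.4)))
    x <- pmin(x, 55)
    tr <- tracking_series(t, x, rep(0, length(t)))
    v1 <- length(unique(unlist(discretize(tr, g1)$records)))
    v2 <- length(unique(unlist(discretize(tr, g2)$records)))
    expect_gte(v2, v1)
  }
})

test_that("conventional measures match their definitions", {
  g <- geom50()
  # never enters the open arms: closed-arm run only
  t <- seq(0, 30, by = 0.04)
  tr_closed <- tracking_series(t, rep(0, length(t)),
                               pmin(5 + t, 30))
  occ <- discretize(tr_closed, g)
  cm <- compute_conventional(occ, g)
  expect_equal(cm$latency_open, occ$duration)
  expect_equal(cm$entries_open, 0L)
  expect_equal(cm$time_open, 0)

  # enter-and-stay from t = 10: latency 10, one entry, open ever after
  t2 <- seq(0, 60, by = 0.04)
  x2 <- ifelse(t2 < 10, 0, pmin(5.2 + (t2 - 10), 20))
  tr_open <- tracking_series(t2, x2, rep(0, length(t2)))
  cm2 <- compute_conventional(suppressWarnings(discretize(tr_open, g)), g)
  expect_equal(cm2$latency_open, 10)
  expect_equal(cm2$entries_open, 1L)
  expect_equal(cm2$time_open, 50)

  # two full open-arm excursions -> exactly two entries
  leg <- function(from, to, t0, t1) {
    tt <- seq(t0, t1, by = 0.04)
    list(t = tt, x = seq(from, to, length.out = length(tt)))
  }
  legs <- list(leg(0, 55, 0, 10), leg(55, 0, 10.04, 20),
               leg(0, -55, 20.08, 30), leg(-55, 0, 30.04, 40))
  tr3 <- tracking_series(unlist(lapply(legs, `[[`, "t")),
                         unlist(lapply(legs, `[[`, "x")),
                         rep(0, sum(lengths(lapply(legs, `[[`, "t")))))
  cm3 <- compute_conventional(discretize(tr3, g), g)
  expect_equal(cm3$entries_open, 2L)
})
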