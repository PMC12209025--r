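test_that("default phenotype parameters encode the three behavioural patterns", {
  e <- phenotype_params("exploratory")
  expect_equal(e$open$k, e$closed$k)
  expect_equal(e$open$t0, e$closed$t0)  # arm-agnostic: same distribution

  d <- phenotype_params("delayed")
  expect_equal(d$open$t0, 150)          # open inflexion at the test mid-point
  expect_lt(d$closed$t0, d$open$t0)

  a <- phenotype_params("avoidant")
  expect_equal(a$open$k, 0)
  expect_equal(a$open$t0, 0)
  expect_true(all(sigmoid_mean(0:300, a$open$k, a$open$t0, a$open$A) == 0))

  expect_error(phenotype_params("bold"))
  expect_error(phenotype_params("delayed", t0_open = 400), "duration")
})

test_that("the anchored sigmoid starts at zero and approaches its asymptote", {
  mu <- sigmoid_mean(0:300, 0.1, 50, 100)
  expect_equal(mu[1], 0)
  expect_true(all(diff(mu) >= 0))
  expect_gt(tail(mu, 1), 99.9)
  expect_lt(max(mu), 100 + 1e-9)
})

test_that("simulated NEG is reproducible, monotone and mean-correct", {
  g <- geom50()
  p <- phenotype_params("delayed", sd_k = 0, sd_t0 = 0)
  s1 <- simulate_neg(p, g, 20, seed = 5)
  s2 <- simulate_neg(p, g, 20, seed = 5)
  expect_identical(s1$count, s2$count)

  # monotone per subject and scope
  by_sub <- split(s1, list(s1$subject, s1$scope))
  expect_true(all(vapply(by_sub, function(d)
    all(diff(d$count[order(d$time)]) >= 0), logical(1))))

  # empirical mean within Monte-Carlo error of the generating curve
  m <- aggregate(neg ~ time, s1[s1$scope == "open", ], mean)
  mu <- sigmoid_mean(m$time, 0.1, 150, 100)
  mc_se <- 100 * sqrt(0.25 / 100 / 20)  # binomial bound, n = 100, 20 subjects
  expect_lt(max(abs(m$neg - mu)), 4 * mc_se + 1)

  # composite identity with noise off
  p0 <- phenotype_params("avoidant", noise = FALSE, sd_k = 0, sd_t0 = 0)
  s0 <- simulate_neg(p0, g, 1, seed = 1)
  expect_true(all(s0$neg[s0$scope == "open"] == 0))
  expect_equal(s0$neg[s0$scope == "total"],
               s0$neg[s0$scope == "closed"] * 100 / 200)
})

test_that("delayed curves inflect closed-first with a plateau between phases", {
  g <- geom50()
  p <- phenotype_params("delayed", noise = FALSE, sd_k = 0, sd_t0 = 0)
  s <- simulate_neg(p, g, 1, seed = 1)
  tot <- s$neg[s$scope == "total"]
  tm <- s$time[s$scope == "total"]
  at <- function(t) tot[tm == t]
  # plateau between the closed and open phases: near-zero growth around
  # 85-100 s, clear growth before (closed phase) and after (open phase)
  expect_lt(at(100) - at(85), 0.6)
  expect_gt(at(60) - at(40), 2)
  expect_gt(at(170) - at(150), 2)
})

test_that("conventional draws respect truncation and phenotype structure", {
  d <- simulate_conventional(n_reps = 500, seed = 3)
  expect_true(all(d$latency_open >= 0 & d$latency_open <= 300))
  expect_true(all(d$time_open >= 0 & d$time_open <= 300))
  av <- d[d$phenotype == "avoidant", ]
  expect_true(all(av$entries_open == 0))
  expect_true(all(av$time_open == 0))
  expect_true(all(av$latency_open == 300))
  # exploratory and delayed share the entries/time generating distributions
  cfg <- negrowth:::conventional_defaults(300)
  expect_identical(cfg$exploratory$entries_open, cfg$delayed$entries_open)
  expect_identical(cfg$exploratory$time_open, cfg$delayed$time_open)
  expect_false(identical(cfg$exploratory$latency_open, cfg$delayed$latency_open))
  # seeded reproducibility
  expect_identical(d, simulate_conventional(n_reps = 500, seed = 3))
})

test_that("trajectory round-trip reproduces separated-phase NEG curves", {
  g <- geom50()
  # delayed-style curves with separated phases; the dash speed must cover
  # the peak first-visit demand plus the arm-to-arm crossing (the
  # generator must bank about rate x transit/2 segments around it)
  p <- phenotype_params("delayed", noise = FALSE, sd_k = 0, sd_t0 = 0,
                        k_open = 0.08, k_closed = 0.08,
                        t0_open = 200, t0_closed = 40)
  s <- simulate_neg(p, g, 1, seed = 2)
  no <- s[s$scope == "open", c("time", "neg")]
  nc <- s[s$scope == "closed", c("time", "neg")]
  tr <- suppressWarnings(simulate_trajectory(no, nc, g, speed = 60))
  occ <- suppressWarnings(discretize(tr, g))
  ro <- compute_neg(occ, g, "open")
  rc <- compute_neg(occ, g, "closed")
  # within two grid segments' worth of percent at every second
  expect_lt(max(abs(ro$neg[match(no$time, ro$time)] - no$neg)), 2 + 1e-9)
  expect_lt(max(abs(rc$neg[match(nc$time, rc$time)] - nc$neg)), 2 + 1e-9)
})

test_that("avoidant trajectories never enter the open arms", {
  g <- geom50()
  p <- phenotype_params("avoidant", noise = FALSE, sd_k = 0, sd_t0 = 0)
  s <- simulate_neg(p, g, 1, seed = 3)
  tr <- simulate_trajectory(s[s$scope == "open", c("time", "neg")],
                            s[s$scope == "closed", c("time", "neg")],
                            g, speed = 25)
  occ <- suppressWarnings(discretize(tr, g))
  cm <- compute_conventional(occ, g)
  expect_equal(cm$entries_open, 0L)
  expect_equal(cm$time_open, 0)
  expect_equal(cm$latency_open, occ$duration)
})

test_that("infeasible schedules raise a generation error", {
  g <- geom50()
  p <- phenotype_params("delayed", noise = FALSE, sd_k = 0, sd_t0 = 0)
  s <- simulate_neg(p, g, 1, seed = 2)
  expect_error(simulate_trajectory(s[s$scope == "open", c("time", "neg")],
                                   s[s$scope == "closed", c("time", "neg")],
                                   g, speed = 1),
               "infeasible")
  expect_error(simulate_trajectory(s[s$scope == "open", c("time", "neg")],
                                   s[s$scope == "closed", c("time", "neg")],
                                   g, speed = 0), "positive")
})
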