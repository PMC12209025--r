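test_that("ROPE construction follows the linear and growth rules", {
  r1 <- build_rope("linear", sd_y = 50)
  expect_equal(c(r1$low, r1$high), c(-5, 5))
  r2 <- build_rope("growth")
  expect_equal(c(r2$low, r2$high), c(-0.18, 0.18))
  expect_equal(r2$scale, "proportion")
  expect_error(build_rope("linear"), "sd_y")
  expect_error(build_rope("linear", sd_y = 0), "positive")
})

test_that("sexit decisions partition exactly at the 97.5/2.5 thresholds", {
  rope <- build_rope("growth")
  mk <- function(draws) list(times = 0, draws = matrix(draws, nrow = 1))

  # all-zero effect: equivalent, PD reported as 0.5 at exact symmetry
  d0 <- sexit(mk(rep(0, 1000)), rope)
  expect_equal(d0$decision, "equivalent")
  expect_equal(d0$pd, 0.5)
  expect_equal(d0$rope_frac, 1)

  # effect ten ROPE-widths away: not-equivalent, PD = 1
  d1 <- sexit(mk(rep(10 * 36, 1000)), rope)  # percent scale
  expect_equal(d1$decision, "not-equivalent")
  expect_equal(d1$pd, 1)
  expect_equal(d1$rope_frac, 0)

  # half the posterior inside: undecided
  d2 <- sexit(mk(c(rep(0, 500), rep(90, 500))), rope)
  expect_equal(d2$decision, "undecided")
  expect_equal(d2$rope_frac, 0.5)

  # the rule is an exact partition: every inside-fraction yields one state
  set.seed(2)
  for (frac in c(0, 0.02, 0.025, 0.5, 0.975, 0.98, 1)) {
    n_in <- round(1000 * frac)
    dd <- sexit(mk(c(rep(0, n_in), rep(50, 1000 - n_in))), rope)
    expected <- if (frac > 0.975) "equivalent"
                else if (frac < 0.025) "not-equivalent" else "undecided"
    expect_equal(dd$decision, expected)
  }
})

test_that("HDI mass and PD behave as posterior summaries", {
  set.seed(9)
  x <- rnorm(20000, 2, 1)
  h <- hdi(x, 0.95)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.95, tolerance = 0.01)
  expect_gte(pd_value <- negrowth:::pd_value(x), 0.5)
  expect_lte(pd_value, 1)
  expect_equal(negrowth:::pd_value(c(-1, 1)), 0.5)
})

test_that("identical groups give a centred contrast and few false alarms", {
  g <- geom50()
  p <- phenotype_params("exploratory")
  not_eq_frac <- vapply(1:3, function(r) {
    a <- simulate_neg(p, g, 6, seed = 100 + r, subject_prefix = "a")
    b <- simulate_neg(p, g, 6, seed = 200 + r, subject_prefix = "b")
    a$phenotype <- "groupA"; b$phenotype <- "groupB"
    sim <- rbind(a, b)
    dat <- neg_effects_data(sim, scope = "total")
    mod <- fit_neg_effects(dat, "multiphase", seed = r)
    eff <- contrast_over_time(mod, c("groupA", "groupB"),
                              times = seq(0, 300, 5), n_draws = 1000)
    expect_lt(max(abs(apply(eff$draws, 1, median))), 15)
    dec <- sexit(eff, build_rope("growth"))
    mean(dec$decision == "not-equivalent")
  }, numeric(1))
  expect_lte(mean(not_eq_frac), 0.05)
})

test_that("contrasts are linear draw-wise and self-contrasts vanish", {
  g <- geom50()
  sim <- do.call(rbind, lapply(c("exploratory", "delayed", "avoidant"),
    function(ph) simulate_neg(phenotype_params(ph), g, 5, seed = 31)))
  class(sim) <- c("neg_sim", "data.frame")
  dat <- neg_effects_data(sim, scope = "open")
  mod <- fit_neg_effects(dat, "multiphase", seed = 1)
  tt <- seq(0, 300, 25)
  ab <- contrast_over_time(mod, c("exploratory", "delayed"), tt, 500, seed = 5)
  bc <- contrast_over_time(mod, c("delayed", "avoidant"), tt, 500, seed = 5)
  ac <- contrast_over_time(mod, c("exploratory", "avoidant"), tt, 500, seed = 5)
  expect_equal(ab$draws + bc$draws, ac$draws, tolerance = 1e-9)

  aa <- contrast_over_time(mod, c("delayed", "delayed"), tt, 200, seed = 5)
  expect_true(all(aa$draws == 0))
  expect_error(contrast_over_time(mod, c("delayed", "bold")), "unknown")

  # exploratory - avoidant open-arm difference grows to the open asymptote
  med <- apply(ac$draws, 1, median)
  expect_gt(med[length(med)], 85)
})

test_that("arm-type contrast for an avoidant cohort approaches -100% of closed NEG", {
  g <- geom50()
  sim <- simulate_neg(phenotype_params("avoidant"), g, 8, seed = 41)
  dat <- neg_effects_data(sim, group = "scope")
  mod <- fit_neg_effects(dat, "single-phase", seed = 2)
  eff <- contrast_over_time(mod, c("open", "closed"), times = seq(0, 300, 10),
                            n_draws = 500)
  med <- apply(eff$draws, 1, median)
  expect_lt(med[length(med)], -95)
  dec <- sexit(eff, build_rope("growth"))
  # becomes and stays not-equivalent once closed NEG clears the ROPE
  lm_ <- decision_landmarks(dec)
  expect_lt(lm_$onset_not_equivalent, 60)
  expect_true(all(dec$decision[dec$time >= lm_$onset_not_equivalent] ==
                    "not-equivalent"))
})

test_that("decision landmarks are read off a hand-made step series", {
  mk <- function(states) {
    d <- data.frame(time = seq_along(states) - 1, median = 0, hdi_low = 0,
                    hdi_high = 0, pd = 1, rope_frac = 0.5, decision = states)
    class(d) <- c("neg_decisions", "data.frame")
    d
  }
  s <- mk(c(rep("equivalent", 5), rep("not-equivalent", 3),
            rep("equivalent", 2)))
  lm_ <- decision_landmarks(s)
  expect_equal(lm_$onset_not_equivalent, 5)
  expect_equal(lm_$return_to_equivalent, 8)
  expect_equal(unname(lm_$durations["equivalent"]), 7)
  expect_equal(unname(lm_$durations["not-equivalent"]), 3)

  s2 <- mk(rep("equivalent", 10))
  lm2 <- decision_landmarks(s2)
  expect_true(is.na(lm2$onset_not_equivalent))
  expect_true(is.na(lm2$return_to_equivalent))
})

test_that("conventional-measure regression needs two phenotypes and is seeded", {
  d <- simulate_conventional(n_reps = 200, seed = 5)
  expect_error(fit_conventional_effects(d[d$phenotype == "avoidant", ]),
               "two")
  r1 <- fit_conventional_effects(d, seed = 8)
  r2 <- fit_conventional_effects(d, seed = 8)
  expect_identical(r1, r2)
})
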