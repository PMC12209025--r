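test_that("a noise-free single sigmoid is recovered within the 95% HDI", {
  tt <- seq(0, 300, by = 5)
  mu <- sigmoid_mean(tt, 0.1, 50, 100)
  ser <- data.frame(time = tt, neg = mu)
  fit <- fit_phase_model(ser, phase_model_spec(1), chains = 4, warmup = 400,
                         iter = 600, seed = 2)
  dr <- fit$draws
  for (par in c("k", "t0")) {
    h <- hdi(dr[, par])
    truth <- c(k = 0.1, t0 = 50)[par]
    expect_gte(truth, h[[1]])
    expect_lte(truth, h[[2]])
  }
  expect_lt(abs(coef(fit)[["t0"]] - 50), 5)
  expect_lt(abs(coef(fit)[["k"]] - 0.1), 0.02)
})

test_that("a flat all-zero series concentrates the amplitude near zero", {
  ser <- data.frame(time = seq(0, 300, by = 10), neg = 0)
  fit <- fit_phase_model(ser, phase_model_spec(1), chains = 2, warmup = 300,
                         iter = 400, seed = 4)
  expect_lt(stats::quantile(fit$draws[, "A"], 0.9), 10)
})

test_that("non-monotone or out-of-range series are rejected", {
  expect_error(fit_phase_model(data.frame(time = 1:5, neg = c(1, 3, 2, 4, 5))),
               "monotone")
  expect_error(fit_phase_model(data.frame(time = 1:3, neg = c(0, 50, 120))),
               "within")
})

test_that("a dual-phase fit keeps ordered inflexions in every draw", {
  g <- geom50()
  sim <- simulate_neg(phenotype_params("delayed"), g, 10, seed = 8)
  fit <- light_fit(pool_neg(sim, "total"), 2, seed = 9)
  expect_true(all(fit$draws[, "t01"] < fit$draws[, "t02"]))
  # the two inflexions bracket the generating phases
  expect_lt(median(fit$draws[, "t01"]), 100)
  expect_gt(median(fit$draws[, "t02"]), 100)
})

test_that("diagnostics gate on Rhat, ESS and predictive coverage", {
  tt <- seq(0, 300, by = 5)
  set.seed(1)
  ser <- data.frame(time = tt,
                    neg = 100 * plogis(qlogis(pmax(pmin(
                      sigmoid_mean(tt, 0.08, 60, 95) / 100, 1 - 1e-4), 1e-4)) +
                      rnorm(length(tt), 0, 0.25)))
  ser$neg <- cummax(ser$neg)
  full <- fit_phase_model(ser, phase_model_spec(1), chains = 4,
                          warmup = 1000, iter = 1000, seed = 5)
  d_full <- diagnostics(full)
  expect_true(all(d_full$rhat >= 0.9 & d_full$rhat <= 1.1, na.rm = TRUE))
  expect_true(d_full$pass)

  # a 10-draw run cannot reach ESS > 1000
  tiny <- fit_phase_model(ser, phase_model_spec(1), chains = 2,
                          warmup = 50, iter = 5, seed = 6)
  d_tiny <- diagnostics(tiny)
  expect_false(d_tiny$pass)
  expect_true(any(grepl("ESS", d_tiny$failures)))

  # a deliberately unconverged run (no adaptation, dispersed chains) fails
  path <- fit_phase_model(ser, phase_model_spec(2), chains = 4,
                          warmup = 2, iter = 40, seed = 7)
  expect_false(diagnostics(path)$pass)
})

test_that("prior predictive curves are bounded and flag absurd priors", {
  pc <- predictive_check(phase_model_spec(1))
  expect_gte(pc$frac_inside, 0.99)
  expect_true(pc$ok)
  pc2 <- predictive_check(phase_model_spec(2))
  expect_gte(pc2$frac_inside, 0.99)
  # absurdly fast growth prior is flagged
  bad <- predictive_check(phase_model_spec(1, priors = list(logk_mean = log(50),
                                                            logk_sd = 0.1)))
  expect_false(bad$ok)
})

test_that("PSIS-LOO matches exact leave-one-out refitting on a short series", {
  # logit-normal family: observation factors are i.i.d., so dropping one
  # row is exactly leave-one-out for the remaining likelihood
  spec_ln <- phase_model_spec(1, noise = "logit-normal")
  tt <- seq(0, 300, by = 12)
  set.seed(3)
  mu <- sigmoid_mean(tt, 0.07, 80, 90)
  z <- qlogis(pmax(pmin(mu / 100, 1 - 1e-4), 1e-4)) + rnorm(length(tt), 0, 0.4)
  ser <- data.frame(time = tt, neg = cummax(100 * plogis(z)))
  fit <- fit_phase_model(ser, spec_ln, chains = 4, warmup = 500,
                         iter = 750, seed = 11)
  approx_loo <- psis_loo(fit$loglik)
  expect_lt(max(approx_loo$pareto_k, na.rm = TRUE), 0.7)

  exact <- vapply(seq_len(nrow(ser)), function(i) {
    f <- fit_phase_model(ser[-i, ], spec_ln, chains = 2,
                         warmup = 400, iter = 500, seed = 11 + i)
    mu_i <- apply(f$draws, 1, function(p)
      sigmoid_mean(ser$time[i], p[["k"]], p[["t0"]], p[["A"]]))
    zm <- qlogis(pmax(pmin(mu_i / 100, 1 - 1e-4), 1e-4))
    ll <- dnorm(qlogis(pmax(pmin(ser$neg[i] / 100, 1 - 1e-4), 1e-4)),
                zm, f$draws[, "sigma"], log = TRUE)
    log(mean(exp(ll - max(ll)))) + max(ll)
  }, numeric(1))
  expect_lt(abs(approx_loo$elpd_loo - sum(exact)), approx_loo$se)
})

test_that("model comparison applies the elpd rule and the parsimony tie-break", {
  g <- geom50()
  sim <- simulate_neg(phenotype_params("delayed"), g, 10, seed = 14)
  pooled <- pool_neg(sim, "total")
  f1 <- light_fit(pooled, 1, seed = 15)
  f2 <- light_fit(pooled, 2, seed = 16)
  cc <- compare_models(list(single = f1, dual = f2), check = FALSE)
  expect_equal(cc$selected, "dual")

  # identical fits tie exactly -> equal parsimony, first taken
  cc_same <- compare_models(list(a = f1, b = f1), check = FALSE)
  expect_equal(cc_same$selected, "a")

  # single-phase truth: elpd ties within the equivalence band -> parsimony picks single
  sim_e <- simulate_neg(phenotype_params("exploratory"), g, 10, seed = 17)
  pe <- pool_neg(sim_e, "total")
  ce <- compare_models(list(single = light_fit(pe, 1, seed = 18, thin = 10),
                            dual = light_fit(pe, 2, seed = 19, thin = 10)),
                       check = FALSE)
  expect_equal(ce$selected, "single")

  expect_error(compare_models(list(f1)), "2")
})
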