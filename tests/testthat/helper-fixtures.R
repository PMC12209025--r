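# Shared fixtures: all built in code at test time.

geom50 <- function() epm_geometry()  # 50-cm arms, 1-cm grid

# Constant-speed run from the centre down open arm 1 (along +x).
run_track <- function(speed = 1, duration = 50, frame_rate = 25,
                      geometry = geom50()) {
  t <- seq(0, duration, by = 1 / frame_rate)
  half <- geometry$centre_size / 2
  x <- pmin(half + speed * t, half + geometry$arm_length)
  tracking_series(t, x, rep(0, length(t)), subject_id = "runner")
}

# Independent brute-force NEG oracle: replays per-second segment sets with
# a naive accumulating set, no shared code with compute_neg internals.
oracle_neg <- function(records, geometry, scope) {
  ids <- scope_segments(geometry, scope)
  seen <- integer(0)
  out <- numeric(length(records))
  for (k in seq_along(records)) {
    seen <- unique(c(seen, records[[k]]))
    out[k] <- 100 * length(intersect(seen, ids)) / length(ids)
  }
  out
}

# Random occupancy sequence: each second visits a random handful of valid
# segment ids (sometimes none).
random_records <- function(geometry, duration = 60) {
  total <- n_segments(geometry)
  lapply(seq_len(duration), function(k) {
    m <- sample(0:5, 1)
    if (m == 0) integer(0) else sample.int(total, m)
  })
}

# Light sampler settings for fits whose purpose is structure selection or
# point recovery rather than full-precision posteriors.
light_fit <- function(series, n_phases, seed, chains = 4, warmup = 300,
                      iter = 500, thin = 5) {
  fit_phase_model(series, phase_model_spec(n_phases), chains = chains,
                  warmup = warmup, iter = iter, thin = thin, seed = seed)
}

# Memoised replicate study shared by the model-selection and classifier
# acceptance checks: per replicate, simulate the three phenotype cohorts,
# select the total-maze phase model per cohort, and classify.
.acc_cache <- new.env(parent = emptyenv())
acceptance_replicates <- function(n_rep = 20) {
  key <- paste0("reps", n_rep)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  geom <- geom50()
  phenos <- c("exploratory", "delayed", "avoidant")
  res <- lapply(seq_len(n_rep), function(r) {
    per <- lapply(phenos, function(ph) {
      sim <- simulate_neg(phenotype_params(ph), geom, n_subjects = 10,
                          seed = 1000 + 17 * r + match(ph, phenos))
      pooled <- pool_neg(sim, "total")
      f1 <- light_fit(pooled, 1, seed = 31 * r + 1, thin = 10)
      f2 <- light_fit(pooled, 2, seed = 31 * r + 2, thin = 10)
      cc <- compare_models(list(single = f1, dual = f2), check = FALSE)
      fin <- sim[sim$time == max(sim$time), ]
      call <- classify_phenotype(
        cc, final_open = mean(fin$neg[fin$scope == "open"]),
        final_closed = mean(fin$neg[fin$scope == "closed"]))
      list(phenotype = ph, selected = cc$selected_n_phases,
           label = call$label, grade = call$alb_grade, dual_fit = f2)
    })
    names(per) <- phenos
    per
  })
  .acc_cache[[key]] <- res
  res
}
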