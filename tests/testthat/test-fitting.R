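test_that("default initialization encodes the absorption prior and constraints", {
  m <- catechin_model()
  p <- default_parameters(m)
  pv <- parameter_values(p)
  expect_equal(pv[["small_intestine -> liver"]], 0.30)
  expect_equal(pv[["small_intestine -> large_intestine"]], 0.60)
  fec <- p[p$from == "small_intestine" & p$to == "large_intestine", ]
  expect_identical(fec$status, "linked")
  expect_equal(fec$link_mult, 2)
  adj <- p[p$status == "adjustable", ]
  expect_true(all(adj$value >= adj$lower & adj$value <= adj$upper))
  # colonic emptying is fixed: it cannot influence plasma or urine
  expect_identical(p$status[p$from == "large_intestine"], "fixed")
})

test_that("weighted SSR reduces to hand-computable cases", {
  m <- catechin_model()
  p <- truth_parameters("EGC")
  obs <- noise_free_series("EGC")
  # observed == predicted
  expect_lt(weighted_ssr(p, obs, m), 1e-10)
  # a single perturbed residual contributes w * r^2
  w <- proportional_weights(obs$fraction_of_dose)
  obs2 <- obs
  i <- which.max(obs2$fraction_of_dose)
  r <- 0.01 * obs2$fraction_of_dose[i]
  obs2$fraction_of_dose[i] <- obs2$fraction_of_dose[i] + r
  w2 <- proportional_weights(obs2$fraction_of_dose)
  expect_equal(weighted_ssr(p, obs2, m), w2[i] * r^2, tolerance = 1e-6)
})

test_that("noise-free refits recover the generating parameters within 1%", {
  m <- catechin_model()
  for (cc in c("EGC", "ECG")) {
    f <- fit_series(noise_free_series(cc), m)
    tv <- parameter_values(truth_parameters(cc))[names(f$estimates)]
    expect_lt(max(abs(f$estimates - tv) / tv), 0.01)
    expect_lt(f$weighted_ssr, 1e-5)
    expect_true(f$identifiable)
  }
})

test_that("every fit preserves the 1:2 absorption:fecal constraint exactly", {
  m <- catechin_model()
  f <- fit_series(add_measurement_noise(noise_free_series("EC"), seed = 4), m)
  pv <- parameter_values(f$parameters)
  expect_identical(pv[["small_intestine -> large_intestine"]],
                   2 * pv[["small_intestine -> liver"]])
})

test_that("reported weighted SSR equals an independent recomputation", {
  m <- catechin_model()
  obs <- add_measurement_noise(noise_free_series("EGC"), seed = 9)
  f <- fit_series(obs, m)
  expect_equal(f$weighted_ssr, weighted_ssr(f$parameters, obs, m),
               tolerance = 1e-12)
})

test_that("rescaling all weights leaves the estimates unchanged", {
  # a well-conditioned two-compartment instance of the same estimator
  m <- catekin:::new_catekin_model(
    name = "chain", compartments = c("gut", "plasma"), sinks = "urine",
    edges = tibble::tibble(from = c("gut", "plasma"),
                           to = c("plasma", "urine")),
    dose_compartment = "gut", plasma_compartment = "plasma",
    urine_sink = "urine"
  )
  p <- tibble::tibble(from = c("gut", "plasma"), to = c("plasma", "urine"),
                      value = c(1.5, 0.6), status = "adjustable",
                      link_to = NA_character_, link_mult = NA_real_,
                      lower = 1e-6, upper = 100)
  s <- sampling_schedule()
  traj <- simulate_kinetics(m, p, schedule_times())
  obs <- add_measurement_noise(
    observe_kinetics(traj, m, s$plasma_times, s$urine_interval_ends),
    seed = 14)
  init <- p
  init$value <- 1
  obs$weight <- proportional_weights(obs$fraction_of_dose)
  f1 <- fit_series(obs, m, init = init, multistart = 1, prune = FALSE)
  obs$weight <- obs$weight * 37
  f2 <- fit_series(obs, m, init = init, multistart = 1, prune = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  expect_equal(f1$weighted_ssr * 37, f2$weighted_ssr, tolerance = 1e-8)
  # residual-variance scaling makes the covariance invariant to the rescale
  expect_equal(f1$covariance, f2$covariance, tolerance = 1e-4)
})

test_that("an all-zero series yields a flagged result, not a crash", {
  m <- catechin_model()
  s <- sampling_schedule()
  obs <- tibble::tibble(
    observable = rep(c("plasma", "urine_cum"), c(10, 4)),
    time_h = c(s$plasma_times, s$urine_interval_ends),
    fraction_of_dose = 0
  )
  f <- fit_series(obs, m)
  expect_s3_class(f, "catekin_fit")
  expect_false(f$identifiable)
})

test_that("parameter recovery over noisy replicates is unbiased with honest intervals", {
  m <- catechin_model()
  clean <- noise_free_series("EGC")
  tv <- parameter_values(truth_parameters("EGC"))
  rows <- list()
  for (s in 1:20) {
    f <- fit_series(add_measurement_noise(clean, seed = s), m,
                    prune = FALSE)
    td <- tidy(f)
    td$truth <- tv[td$term]
    rows[[s]] <- td
  }
  d <- dplyr::bind_rows(rows)
  d$bias <- (d$estimate - d$truth) / d$truth
  med <- tapply(d$bias, d$term, stats::median)
  expect_true(all(abs(med) < 0.15))
  cover <- abs(d$estimate - d$truth) <= 1.96 * d$std_error
  expect_gte(mean(cover, na.rm = TRUE), 0.80)
})

test_that("pooled-mean fitting matches a single series for identical subjects", {
  m <- catechin_model()
  coh1 <- generate_cohort(default_truth(inter_subject_cv = 0,
                                        measurement_cv = 0),
                          n_subjects = 1, seed = 1)
  coh19 <- generate_cohort(default_truth(inter_subject_cv = 0,
                                         measurement_cv = 0),
                           n_subjects = 19, seed = 1)
  f1 <- fit_mean_pooled(coh1, m)
  f19 <- fit_mean_pooled(coh19, m)
  expect_equal(f1$estimates, f19$estimates, tolerance = 1e-6)

  expect_error(fit_mean_pooled(coh1[0, ], m), "empty")
  bad <- coh1
  bad$time_h[3] <- 7.77
  expect_error(fit_mean_pooled(bad, m), "grid")
})

test_that("pooled fit of the default noisy cohort passes the reporting screens", {
  cc <- cached_cohort_fits(1)
  f <- fit_mean_pooled(cc$cohort, catechin_model())
  expect_true(f$converged)
  expect_true(f$reportable)
})

test_that("structure comparison justifies the extravascular compartment only when the data demand it", {
  m7 <- catechin_model()
  m6 <- catechin_model_variant("no_extravascular")
  expect_error(compare_structures(noise_free_series("EGC"), list(m7)),
               "at least two")

  # regeneration: data from the 7-compartment truth
  s7 <- add_measurement_noise(noise_free_series("EGC"), seed = 11)
  r7 <- compare_structures(s7, list(six = m6, seven = m7))
  expect_identical(r7$variant[r7$rank == 1], "seven")
  expect_true(r7$justified[r7$variant == "seven"])

  # negative control: data without extravascular exchange
  p6 <- set_parameters(default_parameters(m6), c(
    "upper_GI -> small_intestine" = 2.8, "small_intestine -> liver" = 0.32,
    "liver -> plasma" = 1.9, "plasma -> kidneys" = 1.0,
    "kidneys -> urine" = 1.2))
  tr6 <- simulate_kinetics(m6, p6, schedule_times())
  s <- sampling_schedule()
  s6 <- add_measurement_noise(
    observe_kinetics(tr6, m6, s$plasma_times, s$urine_interval_ends),
    seed = 12)
  r6 <- compare_structures(s6, list(six = m6, seven = m7))
  expect_false(isTRUE(r6$justified[r6$variant == "seven"]))
})

test_that("tidy and glance expose broom-style summaries", {
  f <- fit_series(noise_free_series("EGC"), catechin_model())
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std_error", "fsd", "held") %in%
                    names(td)))
  expect_equal(nrow(td), 7)
  g <- glance(f)
  expect_equal(nrow(g), 1)
  expect_true(g$converged)
})
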