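test_that("truth fixture values are admissible and reproduce the structural contrasts", {
  tr <- default_truth()
  expect_s3_class(tr, "catekin_truth")
  expect_true(all(tr$parameters$value > 0))
  p <- default_parameters(catechin_model())
  adj_rng <- range(p$lower, p$upper, na.rm = TRUE)
  expect_true(all(tr$parameters$value >= adj_rng[1] &
                    tr$parameters$value <= adj_rng[2]))
  expect_equal(unname(tr$dose_mg[c("EGCG", "EGC", "EC", "ECG")]),
               c(290, 87, 39, 28))

  kp <- tr$parameters[tr$parameters$to == "kidneys", ]
  kpv <- stats::setNames(kp$value, kp$catechin)
  expect_equal(mean(kpv[c("EGC", "EC")]) / mean(kpv[c("EGCG", "ECG")]),
               150, tolerance = 1e-9)

  ks <- kinetic_summary(tr$parameters)
  f <- stats::setNames(ks$fcr_per_min, ks$catechin)
  # FCR ordering: EGC highest, ECG lowest, EGCG and EC near-equal between
  expect_gt(f[["EGC"]], f[["EGCG"]])
  expect_gt(f[["EGC"]], f[["EC"]])
  expect_gt(f[["EGCG"]], f[["ECG"]])
  expect_gt(f[["EC"]], f[["ECG"]])
  expect_lt(abs(f[["EGCG"]] - f[["EC"]]) / mean(f[c("EGCG", "EC")]), 0.1)
  # residence time ordering is the exact reverse
  r <- stats::setNames(ks$rt_h, ks$catechin)
  expect_true(r[["ECG"]] > r[["EC"]] && r[["ECG"]] > r[["EGCG"]] &&
                r[["EC"]] > r[["EGC"]] && r[["EGCG"]] > r[["EGC"]])
})

test_that("cohort generation is seed-deterministic with the study design", {
  c1 <- generate_cohort(n_subjects = 19, seed = 42)
  c2 <- generate_cohort(n_subjects = 19, seed = 42)
  expect_identical(tibble::as_tibble(c1), tibble::as_tibble(c2))
  c3 <- generate_cohort(n_subjects = 19, seed = 43)
  expect_false(identical(c1$fraction_of_dose, c3$fraction_of_dose))

  expect_equal(nrow(dplyr::distinct(c1[, c("subject_id", "catechin")])), 76)
  expect_equal(sort(unique(c1$time_h[c1$observable == "plasma"])),
               c(0, 0.25, 0.5, 1, 2, 3, 5, 8, 10, 12))
  expect_equal(sort(unique(c1$time_h[c1$observable == "urine_cum"])),
               c(4, 8, 12, 24))
  sexes <- dplyr::distinct(c1[, c("subject_id", "sex")])
  expect_equal(sum(sexes$sex == "M"), 10)
  expect_equal(sum(sexes$sex == "F"), 9)
  # per-series urine is monotone after the running-maximum restoration
  mono <- c1 |>
    dplyr::filter(.data$observable == "urine_cum") |>
    dplyr::group_by(.data$subject_id, .data$catechin) |>
    dplyr::summarise(ok = !is.unsorted(.data$fraction_of_dose),
                     .groups = "drop")
  expect_true(all(mono$ok))
})

test_that("the zero-noise limit reproduces the truth curves and refits to truth", {
  tr0 <- default_truth(inter_subject_cv = 0, measurement_cv = 0)
  coh <- generate_cohort(tr0, n_subjects = 2, seed = 1)
  s1 <- coh[coh$subject_id == "S01" & coh$catechin == "EGC", ]
  s2 <- coh[coh$subject_id == "S02" & coh$catechin == "EGC", ]
  expect_equal(s1$fraction_of_dose, s2$fraction_of_dose)
  expect_equal(s1$fraction_of_dose,
               noise_free_series("EGC")$fraction_of_dose, tolerance = 1e-12)

  f <- fit_series(s1, catechin_model())
  tv <- parameter_values(truth_parameters("EGC"))[names(f$estimates)]
  expect_lt(max(abs(f$estimates - tv) / tv), 0.01)

  expect_error(default_truth(inter_subject_cv = -1), "non-negative")
})

test_that("realized parameters are stored for recovery scoring", {
  coh <- generate_cohort(n_subjects = 3, seed = 8)
  rp <- realized_parameters(coh)
  expect_equal(nrow(rp), 3 * 4 * 10)
  # the linked fecal coefficient follows its anchor in every draw
  wide <- rp |>
    tidyr::pivot_wider(names_from = c("from", "to"), values_from = "value",
                       names_sep = ">")
  expect_equal(wide[["small_intestine>large_intestine"]],
               2 * wide[["small_intestine>liver"]])
  expect_error(realized_parameters(tibble::tibble(a = 1)), "provenance")
})

test_that("raw-form export inverts the fraction-of-dose transform exactly", {
  coh <- generate_cohort(n_subjects = 3, seed = 5)
  bio <- default_biometrics(dplyr::distinct(coh[, c("subject_id", "sex")]),
                            seed = 2)
  raw <- raw_form(coh, bio)
  back <- dplyr::bind_rows(
    to_fraction_of_dose(raw$plasma, bio),
    urine_fraction_of_dose(raw$urine)
  )
  key <- c("subject_id", "catechin", "observable", "time_h")
  orig <- dplyr::arrange(tibble::as_tibble(coh)[, c(key, "fraction_of_dose")],
                         dplyr::across(dplyr::all_of(key)))
  back <- dplyr::arrange(back, dplyr::across(dplyr::all_of(key)))
  expect_equal(back$fraction_of_dose, orig$fraction_of_dose,
               tolerance = 1e-12)

  # doubling plasma volume (via hematocrit -> 1 - 2*(1-hct)) halves conc
  raw2 <- raw_form(coh, bio, hematocrit = 1 - 2 * (1 - 0.45))
  expect_equal(raw2$plasma$conc_mg_per_l, raw$plasma$conc_mg_per_l / 2,
               tolerance = 1e-12)

  bad <- bio
  bad$height_m[1] <- -1
  expect_error(raw_form(coh, bad), "positive")
})

test_that("default biometrics draws give positive plasma volumes", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", 1:1000),
    sex = rep(c("M", "F"), 500)
  )
  bio <- default_biometrics(subjects, seed = 99)
  pv <- plasma_volume(bio$height_m, bio$weight_kg, bio$sex)
  expect_true(all(pv > 0))
  expect_true(all(bio$height_m > 1.3 & bio$height_m < 2.2))
  expect_true(all(bio$weight_kg > 35 & bio$weight_kg < 160))
})
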