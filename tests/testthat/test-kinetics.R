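test_that("isolated plasma pool has residence time 1/k", {
  m <- catekin:::new_catekin_model(
    name = "pool", compartments = "plasma", sinks = "urine",
    edges = tibble::tibble(from = "plasma", to = "urine"),
    dose_compartment = "plasma", plasma_compartment = "plasma",
    urine_sink = "urine"
  )
  p <- tibble::tibble(from = "plasma", to = "urine", value = 0.8,
                      status = "adjustable", link_to = NA_character_,
                      link_mult = NA_real_, lower = 1e-6, upper = 100)
  expect_equal(residence_time_plasma(m, p), 1 / 0.8, tolerance = 1e-12)
})

test_that("recirculation through a tissue pool strictly extends residence time", {
  # plasma <-> tissue, terminal loss only from tissue
  m <- catekin:::new_catekin_model(
    name = "recirc", compartments = c("plasma", "tissue"), sinks = "loss",
    edges = tibble::tibble(from = c("plasma", "tissue", "tissue"),
                           to = c("tissue", "plasma", "loss")),
    dose_compartment = "plasma", plasma_compartment = "plasma",
    urine_sink = "loss"
  )
  k_out <- 1.3; k_back <- 0.9; k_loss <- 0.6
  p <- tibble::tibble(from = c("plasma", "tissue", "tissue"),
                      to = c("tissue", "plasma", "loss"),
                      value = c(k_out, k_back, k_loss),
                      status = "adjustable", link_to = NA_character_,
                      link_mult = NA_real_, lower = 1e-6, upper = 100)
  rt <- residence_time_plasma(m, p)
  expect_gt(rt, 1 / k_out)
  # closed form: per-visit time 1/k_out, return probability
  # k_back/(k_back+k_loss), geometric number of visits
  p_ret <- k_back / (k_back + k_loss)
  expect_equal(rt, (1 / k_out) / (1 - p_ret), tolerance = 1e-10)
  # against the stochastic oracle
  po <- residence_time_particle_oracle(m, p, n_particles = 2e4, seed = 11)
  expect_lt(abs(po$mean - rt), 3 * po$se)
})

test_that("FCR is the reciprocal residence time in per-minute units", {
  expect_equal(fcr(1), 1 / 60)
  expect_equal(fcr(2), 1 / 120)
  for (rt in c(0.05, 0.7, 1, 3.3, 24)) {
    expect_equal(fcr(rt) * rt * 60, 1, tolerance = 1e-12)
  }
  expect_error(fcr(0), "positive")
  expect_error(fcr(-1), "positive")
})

test_that("matrix residence time agrees with the particle oracle on the full model", {
  m <- catechin_model()
  p <- truth_parameters("EGC")
  rt <- residence_time_plasma(m, p)
  po <- residence_time_particle_oracle(m, p, n_particles = 1e5, seed = 7)
  expect_lt(abs(po$mean - rt), 3 * po$se)
  # and on random admissible parameter sets
  for (s in 1:5) {
    pr <- random_admissible_params(m, seed = 100 + s)
    rt <- residence_time_plasma(m, pr)
    po <- residence_time_particle_oracle(m, pr, n_particles = 2e4,
                                         seed = 200 + s)
    expect_lt(abs(po$mean - rt), 3 * po$se)
  }
})

test_that("single-pool oracle recovers the exponential mean and rejects tiny n", {
  m <- catekin:::new_catekin_model(
    name = "pool", compartments = "plasma", sinks = "urine",
    edges = tibble::tibble(from = "plasma", to = "urine"),
    dose_compartment = "plasma", plasma_compartment = "plasma",
    urine_sink = "urine"
  )
  p <- tibble::tibble(from = "plasma", to = "urine", value = 1,
                      status = "adjustable", link_to = NA_character_,
                      link_mult = NA_real_, lower = 1e-6, upper = 100)
  po <- residence_time_particle_oracle(m, p, n_particles = 1e5, seed = 3)
  expect_lt(abs(po$mean - 1), 3 * po$se)
  expect_error(residence_time_particle_oracle(m, p, n_particles = 0),
               "at least 1000")
})

test_that("faster renal uptake strictly shortens plasma residence time", {
  m <- catechin_model()
  p <- truth_parameters("EC")
  rts <- vapply(c(0.2, 0.4, 0.8, 1.6), function(k) {
    residence_time_plasma(m, set_parameters(p, c("plasma -> kidneys" = k)))
  }, numeric(1))
  expect_true(all(diff(rts) < 0))
})

test_that("a trap compartment is reported by name", {
  m <- catechin_model()
  p <- default_parameters(m)
  # cutting both kidney and extravascular exits leaves no route to a sink
  p <- set_parameters(p, c("kidneys -> urine" = 0))
  expect_error(residence_time_plasma(m, p), "kidneys")
})

test_that("kinetic summaries carry structural attributes and exact reciprocals", {
  tr <- default_truth()
  ks <- kinetic_summary(tr$parameters)
  expect_equal(nrow(ks), 4)
  expect_true(all(abs(ks$fcr_per_min * ks$rt_h * 60 - 1) < 1e-9))
  expect_setequal(ks$catechin[ks$gallated], c("EGCG", "ECG"))
  expect_setequal(ks$catechin[ks$b_ring_hydroxyls == 3], c("EGCG", "EGC"))
})
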