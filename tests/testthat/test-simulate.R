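one_pool_model <- function() {
  catekin:::new_catekin_model(
    name = "one_pool",
    compartments = "pool", sinks = "sink",
    edges = tibble::tibble(from = "pool", to = "sink"),
    dose_compartment = "pool", plasma_compartment = "pool",
    urine_sink = "sink"
  )
}

one_pool_params <- function(k) {
  tibble::tibble(from = "pool", to = "sink", value = k,
                 status = "adjustable", link_to = NA_character_,
                 link_mult = NA_real_, lower = 1e-6, upper = 100)
}

test_that("single-compartment decay matches the closed form", {
  m <- one_pool_model()
  tr <- simulate_kinetics(m, one_pool_params(1), times = c(0, 0.5, 1, 2))
  pool <- tr$fraction_of_dose[tr$compartment == "pool"]
  expect_equal(pool, exp(-c(0, 0.5, 1, 2)), tolerance = 1e-10)
  sink <- tr$fraction_of_dose[tr$compartment == "sink"]
  expect_equal(sink, 1 - exp(-c(0, 0.5, 1, 2)), tolerance = 1e-10)
})

test_that("two-compartment chain matches the Bateman solution", {
  k1 <- 0.7; k2 <- 1.9
  m <- catekin:::new_catekin_model(
    name = "chain",
    compartments = c("A", "B"), sinks = "sink",
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "sink")),
    dose_compartment = "A", plasma_compartment = "B", urine_sink = "sink"
  )
  p <- tibble::tibble(from = c("A", "B"), to = c("B", "sink"),
                      value = c(k1, k2), status = "adjustable",
                      link_to = NA_character_, link_mult = NA_real_,
                      lower = 1e-6, upper = 100)
  times <- c(0.25, 0.5, 1, 2, 4, 8)
  bateman <- k1 * (exp(-k1 * times) - exp(-k2 * times)) / (k2 - k1)
  for (backend in c("matrix", "ode")) {
    tr <- simulate_kinetics(m, p, times, backend = backend)
    B <- tr$fraction_of_dose[tr$compartment == "B"]
    expect_equal(B, bateman, tolerance = 1e-8)
  }
})

test_that("bolus initial condition puts the full dose in the dosing site", {
  m <- catechin_model()
  tr <- simulate_kinetics(m, default_parameters(m), times = c(0, 1))
  at0 <- tr[tr$time_h == 0, ]
  expect_equal(at0$fraction_of_dose[at0$compartment == "upper_GI"], 1)
  expect_true(all(at0$fraction_of_dose[at0$compartment != "upper_GI"] == 0))
})

test_that("mass conservation, sink monotonicity and backend agreement hold on random systems", {
  m <- catechin_model()
  times <- c(0, 0.25, 0.5, 1, 2, 4, 8, 12, 24)
  for (s in 1:20) {
    p <- random_admissible_params(m, seed = s)
    st <- catekin:::sim_states(m, p, times)
    expect_true(all(abs(rowSums(st) - 1) < 1e-6), label = paste("mass, seed", s))
    expect_true(all(st >= -1e-9))
    for (sk in m$sinks) {
      expect_true(all(diff(st[, sk]) >= -1e-9),
                  label = paste("monotone", sk, "seed", s))
    }
    so <- catekin:::sim_states_ode(m, p, times)
    expect_lt(max(abs(st - so)), 1e-6)
  }
})

test_that("fraction-of-dose normalization makes dose scaling exact linearity", {
  m <- catechin_model()
  p <- truth_parameters("EGC")
  st <- catekin:::sim_states(m, p, c(1, 6, 12))
  # states are per unit dose; any dose is the same trajectory scaled
  expect_equal(290 * st, 290 * st)  # identity by construction
  # linear system: doubling the initial mass doubles every state, so the
  # normalized trajectory is invariant; verify via superposition A(2x)=2Ax
  A <- rate_matrix(m, p)
  x <- runif(nrow(A))
  expect_equal(A %*% (2 * x), 2 * (A %*% x))
})

test_that("observables are read off the simulated grid without extrapolation", {
  m <- catechin_model()
  s <- sampling_schedule()
  tr <- simulate_kinetics(m, truth_parameters("EGCG"), schedule_times())
  obs <- observe_kinetics(tr, m, s$plasma_times, s$urine_interval_ends)
  expect_equal(sum(obs$observable == "plasma"), 10)
  expect_equal(sum(obs$observable == "urine_cum"), 4)
  ur <- obs$fraction_of_dose[obs$observable == "urine_cum"]
  expect_true(all(diff(ur) >= 0))
  expect_error(observe_kinetics(tr, m, c(0, 7.5), s$urine_interval_ends),
               "not on the simulated grid")

  # zero transfer coefficients leave everything in the dosing compartment
  p0 <- default_parameters(m)
  p0$value[] <- 0
  p0 <- resolve_parameters(p0)
  tr0 <- simulate_kinetics(m, p0, schedule_times())
  obs0 <- observe_kinetics(tr0, m, s$plasma_times, s$urine_interval_ends)
  expect_true(all(obs0$fraction_of_dose == 0))
  expect_true(all(tr0$fraction_of_dose[tr0$compartment == "upper_GI"] == 1))
})

test_that("simulation rejects unsorted times and negative coefficients", {
  m <- catechin_model()
  p <- default_parameters(m)
  expect_error(simulate_kinetics(m, p, c(2, 1)), "increasing")
  expect_error(simulate_kinetics(m, p, c(-1, 1)), "non-negative")
})
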