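# shared fixtures and memoized expensive computations

the_cache <- new.env(parent = emptyenv())

schedule_times <- function() {
  s <- sampling_schedule()
  sort(unique(c(s$plasma_times, s$urine_interval_ends)))
}

truth_parameters <- function(catechin, model = catechin_model()) {
  tr <- default_truth()
  df <- tr$parameters[tr$parameters$catechin == catechin, ]
  set_parameters(default_parameters(model),
                 stats::setNames(df$value, paste0(df$from, " -> ", df$to)))
}

noise_free_series <- function(catechin, model = catechin_model()) {
  s <- sampling_schedule()
  traj <- simulate_kinetics(model, truth_parameters(catechin, model),
                            schedule_times())
  observe_kinetics(traj, model, s$plasma_times, s$urine_interval_ends)
}

# multiplicative lognormal measurement noise + monotone urine restoration,
# matching the cohort generator's error model
add_measurement_noise <- function(obs, seed, cv = 0.2) {
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  obs$fraction_of_dose <- obs$fraction_of_dose *
    exp(stats::rnorm(nrow(obs), -sdl^2 / 2, sdl))
  u <- obs$observable == "urine_cum"
  obs$fraction_of_dose[u] <- cummax(obs$fraction_of_dose[u])
  obs
}

cached_cohort_fits <- function(seed = 1) {
  key <- paste0("fits_seed_", seed)
  if (is.null(the_cache[[key]])) {
    coh <- generate_cohort(n_subjects = 19, seed = seed)
    the_cache[[key]] <- list(cohort = coh, fits = fit_cohort(coh))
  }
  the_cache[[key]]
}

random_admissible_params <- function(model, seed) {
  set.seed(seed)
  p <- default_parameters(model)
  adj <- p$status == "adjustable"
  p$value[adj] <- exp(stats::runif(sum(adj), log(1e-3), log(10)))
  resolve_parameters(p)
}

cohort_fcr <- function(seed = 1, n_subjects = 19) {
  coh <- generate_cohort(n_subjects = n_subjects, seed = seed)
  ks <- kinetic_summary(realized_parameters(coh))
  sx <- dplyr::distinct(tibble::as_tibble(coh)[, c("subject_id", "sex")])
  dplyr::left_join(dplyr::rename(ks, value = "fcr_per_min"), sx,
                   by = "subject_id")
}

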