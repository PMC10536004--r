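#' Compartmental rate matrix
#'
#' Assembles the generator of the linear, donor-controlled system over all
#' compartments and sinks. Off-diagonal entry (I, J) is the fractional
#' transfer coefficient from J to I; each diagonal entry is the negative
#' total outflow of that compartment; sink rows receive inflow only and
#' sink columns are zero, so every column of the full matrix sums to zero
#' (mass conservation).
#'
#' @param model A `catekin_model`.
#' @param params A parameter tibble covering every edge of `model`.
#' @return A square numeric matrix with dimnames
#'   `c(compartments, sinks)`.
#' @export
#' @examples
#' m <- catechin_model()
#' A <- rate_matrix(m, default_parameters(m))
#' colSums(A)  # all zero
rate_matrix <- function(model, params) {
  params <- resolve_parameters(params)
  nodes <- c(model$compartments, model$sinks)
  want <- edge_label(model$edges$from, model$edges$to)
  have <- edge_label(params$from, params$to)
  missing <- setdiff(want, have)
  if (length(missing)) {
    abort(paste0("missing coefficient(s) for edge(s): ",
                 paste(missing, collapse = ", ")))
  }
  M <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  idx <- match(want, have)
  for (k in seq_along(want)) {
    fr <- model$edges$from[k]
    to <- model$edges$to[k]
    v <- params$value[idx[k]]
    M[to, fr] <- M[to, fr] + v
    M[fr, fr] <- M[fr, fr] - v
  }
  M
}

## Fast state solution of dx/dt = A x (compartments) with sink accumulation
## s(t) = S * integral_0^t x. Primary path: eigendecomposition of A (exact
## matrix exponential for the constant-coefficient system); falls back to
## Matrix::expm on the augmented generator when A is defective or near
## singular.
sim_states <- function(model, params, times) {
  n <- length(model$compartments)
  s <- length(model$sinks)
  M <- rate_matrix(model, params)
  solve_states_core(M, n, s, match(model$dose_compartment, model$compartments),
                    times, dimnames(M)[[1]])
}

## Core solver on the assembled generator M (compartments first, then sink
## rows); returns a length(times) x (n+s) state matrix.
solve_states_core <- function(M, n, s, dose_i, times, node_names = NULL) {
  A <- M[seq_len(n), seq_len(n), drop = FALSE]
  S <- M[n + seq_len(s), seq_len(n), drop = FALSE]
  x0 <- numeric(n)
  x0[dose_i] <- 1

  out <- matrix(NA_real_, length(times), n + s,
                dimnames = list(NULL, node_names))

  eg <- tryCatch(eigen(A), error = function(e) NULL)
  use_eigen <- FALSE
  Vi <- NULL
  if (!is.null(eg) && all(Mod(eg$values) > 1e-10)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi) &&
        max(Mod(eg$vectors)) * max(Mod(Vi)) < 1e12) {
      use_eigen <- TRUE
    }
  }

  if (use_eigen) {
    d <- eg$values
    V <- eg$vectors
    c0 <- drop(Vi %*% x0)
    E <- exp(outer(times, d))                       # T x n, possibly complex
    Cm <- matrix(c0, length(times), n, byrow = TRUE)
    out[, seq_len(n)] <- Re((E * Cm) %*% t(V))
    IE <- (E - 1) / matrix(d, length(times), n, byrow = TRUE)
    out[, n + seq_len(s)] <- Re((IE * Cm) %*% t(S %*% V))
  } else {
    x0f <- c(x0, numeric(s))
    for (i in seq_along(times)) {
      if (times[i] == 0) {
        out[i, ] <- x0f
      } else {
        out[i, ] <- as.numeric(Matrix::expm(M * times[i]) %*% x0f)
      }
    }
  }
  # clamp numerical round-off: states are non-negative by construction and
  # eigen-basis round-off leaves O(1e-16) debris where the exact state is 0
  out[abs(out) < 1e-12] <- 0
  out[out < 0 & out > -1e-9] <- 0
  out
}

sim_states_ode <- function(model, params, times) {
  n <- length(model$compartments)
  s <- length(model$sinks)
  M <- rate_matrix(model, params)
  x0 <- setNames(numeric(n + s), c(model$compartments, model$sinks))
  x0[model$dose_compartment] <- 1
  tgrid <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(
    y = x0, times = tgrid,
    func = function(t, y, p) list(as.numeric(M %*% y)),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  sol[match(times, tgrid), -1, drop = FALSE]
}

#' Simulate fraction-of-dose trajectories after an oral bolus
#'
#' Solves the linear kinetic system for a unit bolus introduced into the
#' dosing compartment at time zero (no continuous input; dietary catechin
#' intake is restricted during the trial). All states are fractions of the
#' ingested dose, so the compartment and sink contents sum to one at every
#' time.
#'
#' @param model A `catekin_model`.
#' @param params Parameter tibble covering every edge.
#' @param times Sorted non-negative times in hours.
#' @param backend `"matrix"` (matrix exponential, exact for the
#'   constant-coefficient system; the default) or `"ode"` (stiff
#'   integration with `deSolve::lsoda`, retained as an independent
#'   cross-check).
#' @return A tibble with columns `time_h`, `compartment` (compartments and
#'   sinks) and `fraction_of_dose`.
#' @export
#' @examples
#' m <- catechin_model()
#' traj <- simulate_kinetics(m, default_parameters(m), times = 0:12)
simulate_kinetics <- function(model, params, times,
                              backend = c("matrix", "ode")) {
  backend <- match.arg(backend)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    abort("`times` must be strictly increasing and non-negative")
  }
  params <- resolve_parameters(params)
  st <- switch(backend,
    matrix = sim_states(model, params, times),
    ode = sim_states_ode(model, params, times)
  )
  tibble::tibble(
    time_h = rep(times, times = ncol(st)),
    compartment = rep(colnames(st), each = length(times)),
    fraction_of_dose = as.vector(st)
  )
}

#' Extract the sampled observables from a simulated trajectory
#'
#' The plasma observable is the plasma compartment's fraction of dose at
#' each sampling instant; the urine observable is the cumulative content of
#' the urine sink at the end of each collection interval. Requested times
#' must lie on the simulated grid; no interpolation or extrapolation is
#' performed.
#'
#' @param traj A tidy trajectory from [simulate_kinetics()].
#' @param model The `catekin_model` that produced it.
#' @param plasma_times Plasma sampling instants (hours).
#' @param urine_interval_ends Ends of the cumulative urine collection
#'   intervals (hours).
#' @return A tibble with columns `observable` (`"plasma"` or
#'   `"urine_cum"`), `time_h` and `fraction_of_dose`.
#' @export
observe_kinetics <- function(traj, model, plasma_times, urine_interval_ends) {
  pick <- function(comp, at, label) {
    sub <- traj[traj$compartment == comp, ]
    i <- match(round(at, 9), round(sub$time_h, 9))
    if (anyNA(i)) {
      abort(paste0(label, " time(s) not on the simulated grid: ",
                   paste(at[is.na(i)], collapse = ", ")))
    }
    tibble::tibble(observable = label, time_h = at,
                   fraction_of_dose = sub$fraction_of_dose[i])
  }
  dplyr::bind_rows(
    pick(model$plasma_compartment, plasma_times, "plasma"),
    dplyr::mutate(
      pick(model$urine_sink, urine_interval_ends, "urine"),
      observable = "urine_cum"
    )
  )
}

## Fast observable prediction used inside the fitting objective: returns the
## plasma fractions then cumulative urine fractions as one numeric vector.
predict_observables <- function(model, params, plasma_times,
                                urine_interval_ends) {
  times <- sort(unique(c(plasma_times, urine_interval_ends)))
  st <- sim_states(model, params, times)
  c(st[match(plasma_times, times), model$plasma_compartment],
    st[match(urine_interval_ends, times), model$urine_sink])
}

#' Standard sampling schedule of the kinetic study
#'
#' Ten plasma draws between 0 and 12 h post-ingestion and four timed urine
#' collection intervals covering 0-24 h.
#'
#' @return A list with `plasma_times` (h) and `urine_interval_ends` (h).
#' @export
sampling_schedule <- function() {
  list(
    plasma_times = c(0, 0.25, 0.5, 1, 2, 3, 5, 8, 10, 12),
    urine_interval_ends = c(4, 8, 12, 24)
  )
}
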