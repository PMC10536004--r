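#' Plasma residence time from the rate-matrix inverse
#'
#' The mean total time a molecule spends in plasma (counting re-entries
#' from the extravascular pool) per unit introduced into plasma, computed
#' as the plasma diagonal element of the negative inverse of the
#' compartment-only rate matrix. For the final topology all plasma input
#' arrives via the liver, so this diagonal element is exactly the
#' per-plasma-entry occupancy time and its reciprocal is the fractional
#' catabolic rate.
#'
#' @param model A `catekin_model`.
#' @param params Parameter tibble covering every edge.
#' @return Residence time in hours.
#' @export
#' @examples
#' m <- catechin_model()
#' residence_time_plasma(m, default_parameters(m))
residence_time_plasma <- function(model, params) {
  n <- length(model$compartments)
  M <- rate_matrix(model, params)
  A <- M[seq_len(n), seq_len(n), drop = FALSE]
  # a compartment that cannot reach any sink makes A singular; name it
  out_rate <- -diag(A)
  traps <- model$compartments[out_rate <= 0]
  if (length(traps) == 0) {
    # reachability of a sink through positive-rate edges
    pos <- model$edges[parameter_values(resolve_parameters(params))[
      edge_label(model$edges$from, model$edges$to)] > 0, ]
    reaches_sink <- function(comp) {
      seen <- comp
      repeat {
        nxt <- unique(c(seen, pos$to[pos$from %in% seen]))
        if (any(nxt %in% model$sinks)) return(TRUE)
        if (length(nxt) == length(seen)) return(FALSE)
        seen <- nxt
      }
    }
    traps <- model$compartments[!vapply(model$compartments, reaches_sink,
                                        logical(1))]
  }
  if (length(traps)) {
    abort(paste0("rate matrix is singular: no route to a sink from ",
                 paste(traps, collapse = ", ")))
  }
  Theta <- -solve(A)
  Theta[model$plasma_compartment, model$plasma_compartment]
}

#' Fractional catabolic rate
#'
#' The fraction of the plasma pool lost irreversibly per minute, the
#' reciprocal of plasma residence time. Transfer coefficients are kept per
#' hour throughout the package; the factor of 60 is applied exactly once,
#' here, to report FCR in the conventional per-minute unit.
#'
#' @param residence_time_plasma_h Plasma residence time in hours.
#' @return FCR in fraction per minute.
#' @export
#' @examples
#' fcr(1)  # 1/60
fcr <- function(residence_time_plasma_h) {
  if (any(residence_time_plasma_h <= 0)) {
    abort("residence time must be positive")
  }
  1 / (residence_time_plasma_h * 60)
}

#' Stochastic particle oracle for plasma residence time
#'
#' Simulates independent memoryless jump processes for particles introduced
#' into plasma: each particle waits an exponential time in its current
#' compartment, jumps to a neighbour (or sink) with probability
#' proportional to the corresponding transfer coefficient, and total plasma
#' occupancy time is accumulated until absorption. The Monte Carlo mean and
#' its standard error provide an independent check of the matrix-inverse
#' residence time.
#'
#' @param model A `catekin_model`.
#' @param params Parameter tibble.
#' @param n_particles Number of particles (at least 1000).
#' @param seed Integer seed for reproducibility.
#' @return A list with `mean` (hours), `se` and `n_particles`.
#' @export
residence_time_particle_oracle <- function(model, params, n_particles = 1e4,
                                           seed = 1) {
  if (n_particles < 1000) {
    abort("`n_particles` must be at least 1000 for a usable standard error")
  }
  params <- resolve_parameters(params)
  nodes <- c(model$compartments, model$sinks)
  n <- length(model$compartments)
  vals <- parameter_values(params)[edge_label(model$edges$from,
                                              model$edges$to)]
  out_rate <- vapply(model$compartments, function(cp) {
    sum(vals[model$edges$from == cp])
  }, numeric(1))
  if (any(out_rate <= 0)) {
    abort(paste0("compartment with zero outflow traps particles: ",
                 paste(model$compartments[out_rate <= 0], collapse = ", ")))
  }
  # per-compartment cumulative jump probabilities
  jumps <- lapply(model$compartments, function(cp) {
    e <- model$edges[model$edges$from == cp, ]
    w <- vals[edge_label(e$from, e$to)]
    list(to = match(e$to, nodes), p = cumsum(w) / sum(w))
  })
  plasma_i <- match(model$plasma_compartment, nodes)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  state <- rep.int(plasma_i, n_particles)
  ptime <- numeric(n_particles)
  active <- seq_len(n_particles)
  while (length(active)) {
    st <- state[active]
    dwell <- rexp(length(active), rate = out_rate[st])
    in_plasma <- st == plasma_i
    ptime[active[in_plasma]] <- ptime[active[in_plasma]] + dwell[in_plasma]
    u <- runif(length(active))
    nxt <- integer(length(active))
    for (cp in unique(st)) {
      sel <- st == cp
      jp <- jumps[[cp]]
      nxt[sel] <- jp$to[findInterval(u[sel], jp$p) + 1L]
    }
    state[active] <- nxt
    active <- active[nxt <= n]
  }
  list(mean = mean(ptime), se = sd(ptime) / sqrt(n_particles),
       n_particles = n_particles)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) return(invisible())
  assign(".Random.seed", seed, envir = globalenv())
}

#' Kinetic summary (residence time and FCR) per subject and catechin
#'
#' Computes the plasma residence time and fractional catabolic rate for
#' each subject-by-catechin parameter set and attaches the structural
#' attributes used in the factorial analysis.
#'
#' @param parameters A tibble of coefficients with columns `catechin`,
#'   `from`, `to`, `value` and optionally `subject_id` (e.g. the realized
#'   parameters stored with a synthetic cohort, or estimates gathered from
#'   fits).
#' @param model A `catekin_model` (default: the final structure).
#' @return A tibble with one row per (subject, catechin): `rt_h`,
#'   `fcr_per_min`, `gallated`, `b_ring_hydroxyls`.
#' @export
kinetic_summary <- function(parameters, model = catechin_model()) {
  stopifnot(all(c("catechin", "from", "to", "value") %in% names(parameters)))
  has_subject <- "subject_id" %in% names(parameters)
  keys <- if (has_subject) c("subject_id", "catechin") else "catechin"
  base <- default_parameters(model)
  lab_all <- edge_label(base$from, base$to)
  base_vals <- base$value
  linked_idx <- which(base$status == "linked")
  anchor_idx <- match(base$link_to[linked_idx], lab_all)
  link_mult <- base$link_mult[linked_idx]
  n <- length(model$compartments)
  nodes <- c(model$compartments, model$sinks)
  want <- edge_label(model$edges$from, model$edges$to)
  pidx <- match(want, lab_all)
  from_i <- match(model$edges$from, nodes)
  to_i <- match(model$edges$to, nodes)
  p_i <- match(model$plasma_compartment, model$compartments)

  row_idx <- match(edge_label(parameters$from, parameters$to), lab_all)
  if (anyNA(row_idx)) {
    abort("parameter table contains edges not present in the model")
  }
  key_f <- if (has_subject) {
    paste(parameters$subject_id, parameters$catechin, sep = "\r")
  } else parameters$catechin
  groups <- split(seq_len(nrow(parameters)), key_f)

  res <- lapply(groups, function(ii) {
    v <- base_vals
    v[row_idx[ii]] <- parameters$value[ii]
    v[linked_idx] <- link_mult * v[anchor_idx]
    A <- matrix(0, n, n)
    k <- v[pidx]
    in_comp <- to_i <= n
    A[cbind(to_i[in_comp], from_i[in_comp])] <- k[in_comp]
    tot <- vapply(split(k, from_i), sum, numeric(1))
    fi <- as.integer(names(tot))
    A[cbind(fi, fi)] <- A[cbind(fi, fi)] - tot
    Theta <- tryCatch(-solve(A), error = function(e) {
      abort("rate matrix is singular: some compartment cannot reach a sink")
    })
    rt <- Theta[p_i, p_i]
    c(rt, 1 / (rt * 60))
  })
  km <- do.call(rbind, res)
  keys_df <- unique(parameters[, keys, drop = FALSE])
  keys_df <- keys_df[match(names(groups), if (has_subject) {
    paste(keys_df$subject_id, keys_df$catechin, sep = "\r")
  } else keys_df$catechin), , drop = FALSE]
  out <- tibble::as_tibble(keys_df)
  out$rt_h <- km[, 1]
  out$fcr_per_min <- km[, 2]
  dplyr::left_join(out, catechin_attributes(), by = "catechin")
}
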