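#' The four green tea catechins and their structural attributes
#'
#' Gallation (esterification with gallic acid) and the number of hydroxyl
#' groups on the B ring are the two structural attributes whose factorial
#' combination defines the four catechins: EGCG (gallated, 3 OH),
#' EGC (non-gallated, 3 OH), EC (non-gallated, 2 OH) and
#' ECG (gallated, 2 OH).
#'
#' @return A tibble with columns `catechin`, `gallated` (logical) and
#'   `b_ring_hydroxyls` (2 or 3).
#' @export
#' @examples
#' catechin_attributes()
catechin_attributes <- function() {
  tibble::tibble(
    catechin         = c("EGCG", "EGC", "EC", "ECG"),
    gallated         = c(TRUE, FALSE, FALSE, TRUE),
    b_ring_hydroxyls = c(3L, 3L, 2L, 2L)
  )
}

#' Ingested catechin doses
#'
#' The catechin content of the green tea extract confection used as the
#' oral bolus: 445 mg total catechins split as 290 mg EGCG, 87 mg EGC,
#' 39 mg EC and 28 mg ECG.
#'
#' @return Named numeric vector of doses in mg.
#' @export
catechin_doses <- function() {
  c(EGCG = 290, EGC = 87, EC = 39, ECG = 28)
}

new_catekin_model <- function(name, compartments, sinks, edges,
                              dose_compartment, plasma_compartment,
                              urine_sink) {
  m <- structure(
    list(
      name = name,
      compartments = compartments,
      sinks = sinks,
      edges = tibble::as_tibble(edges),
      dose_compartment = dose_compartment,
      plasma_compartment = plasma_compartment,
      urine_sink = urine_sink
    ),
    class = "catekin_model"
  )
  validate_catekin_model(m)
  m
}

validate_catekin_model <- function(m) {
  nodes <- c(m$compartments, m$sinks)
  if (!all(m$edges$from %in% m$compartments)) {
    abort("every edge must originate in a compartment (sinks have no outgoing edges)")
  }
  if (!all(m$edges$to %in% nodes)) {
    abort("edge destination not a known compartment or sink")
  }
  if (!m$dose_compartment %in% m$compartments) {
    abort("dose compartment must be a compartment")
  }
  no_out <- setdiff(m$compartments, unique(m$edges$from))
  if (length(no_out)) {
    abort(paste0("compartment(s) without outgoing edge: ",
                 paste(no_out, collapse = ", ")))
  }
  # connectivity from the dosing site
  reach <- m$dose_compartment
  repeat {
    nxt <- unique(c(reach, m$edges$to[m$edges$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!all(nodes %in% reach)) {
    abort(paste0("graph not connected from dose compartment; unreachable: ",
                 paste(setdiff(nodes, reach), collapse = ", ")))
  }
  invisible(m)
}

#' Final seven-compartment model of catechin trafficking
#'
#' Builds the whole-body model retained after structure selection: upper GI
#' tract (stomach), small intestine, large intestine, liver, plasma, kidneys
#' and extravascular tissues, with terminal sinks for feces, urine and
#' irreversible extravascular loss. The oral bolus enters the upper GI
#' tract; plasma is the sampled compartment and cumulative urine the
#' sampled sink.
#'
#' @return A `catekin_model` object.
#' @export
#' @examples
#' m <- catechin_model()
#' length(m$compartments)  # 7
catechin_model <- function() {
  new_catekin_model(
    name = "final",
    compartments = c("upper_GI", "small_intestine", "large_intestine",
                     "liver", "plasma", "kidneys", "extravascular"),
    sinks = c("feces", "urine", "extravascular_loss"),
    edges = tibble::tribble(
      ~from,             ~to,
      "upper_GI",        "small_intestine",
      "small_intestine", "large_intestine",
      "small_intestine", "liver",
      "large_intestine", "feces",
      "liver",           "plasma",
      "plasma",          "kidneys",
      "plasma",          "extravascular",
      "extravascular",   "plasma",
      "extravascular",   "extravascular_loss",
      "kidneys",         "urine"
    ),
    dose_compartment = "upper_GI",
    plasma_compartment = "plasma",
    urine_sink = "urine"
  )
}

#' Structural variants considered during model development
#'
#' The simpler six-compartment starting structure and the three rejected
#' elaborations tested against it: a portal-vein compartment between the
#' small intestine and the liver, biliary excretion from the liver into the
#' large intestine, and enterohepatic recirculation from the liver back to
#' the small intestine. `"no_extravascular"` removes the extravascular
#' compartment (and its loss sink) from the final model, recovering the
#' initial six-compartment structure.
#'
#' @param variant One of `"portal_vein"`, `"biliary_excretion"`,
#'   `"enterohepatic"`, `"no_extravascular"`.
#' @return A `catekin_model` object.
#' @export
#' @examples
#' length(catechin_model_variant("no_extravascular")$compartments)  # 6
catechin_model_variant <- function(variant) {
  base <- catechin_model()
  variant <- match.arg(variant, c("portal_vein", "biliary_excretion",
                                  "enterohepatic", "no_extravascular"))
  if (variant == "no_extravascular") {
    edges <- dplyr::filter(base$edges,
                           .data$from != "extravascular",
                           .data$to != "extravascular")
    return(new_catekin_model(
      name = variant,
      compartments = setdiff(base$compartments, "extravascular"),
      sinks = setdiff(base$sinks, "extravascular_loss"),
      edges = edges,
      dose_compartment = base$dose_compartment,
      plasma_compartment = base$plasma_compartment,
      urine_sink = base$urine_sink
    ))
  }
  if (variant == "portal_vein") {
    edges <- base$edges
    edges$to[edges$from == "small_intestine" & edges$to == "liver"] <- "portal_vein"
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(from = "portal_vein", to = "liver"))
    return(new_catekin_model(
      name = variant,
      compartments = append(base$compartments, "portal_vein",
                            after = match("small_intestine", base$compartments)),
      sinks = base$sinks,
      edges = edges,
      dose_compartment = base$dose_compartment,
      plasma_compartment = base$plasma_compartment,
      urine_sink = base$urine_sink
    ))
  }
  extra <- switch(variant,
    biliary_excretion = tibble::tibble(from = "liver", to = "large_intestine"),
    enterohepatic     = tibble::tibble(from = "liver", to = "small_intestine")
  )
  new_catekin_model(
    name = variant,
    compartments = base$compartments,
    sinks = base$sinks,
    edges = dplyr::bind_rows(base$edges, extra),
    dose_compartment = base$dose_compartment,
    plasma_compartment = base$plasma_compartment,
    urine_sink = base$urine_sink
  )
}

#' @export
print.catekin_model <- function(x, ...) {
  cat("<catekin_model: ", x$name, ">\n", sep = "")
  cat("  compartments (", length(x$compartments), "): ",
      paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  sinks: ", paste(x$sinks, collapse = ", "), "\n", sep = "")
  cat("  dose into: ", x$dose_compartment,
      "; observed: ", x$plasma_compartment, " + cumulative ", x$urine_sink,
      "\n", sep = "")
  cat("  transfers:\n")
  for (i in seq_len(nrow(x$edges))) {
    cat("    ", x$edges$from[i], " -> ", x$edges$to[i], "\n", sep = "")
  }
  invisible(x)
}

edge_label <- function(from, to) paste0(from, " -> ", to)
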