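## Compact letter display from a matrix of pairwise adjusted p-values:
## groups sharing a letter are not significantly different. Implemented as
## maximal cliques of the "not significantly different" graph, enumerated
## exhaustively (the factorial designs here have 4 cells).
compact_letters <- function(p_adj, alpha = 0.05, order_by = NULL) {
  g <- rownames(p_adj)
  k <- length(g)
  if (k > 12) abort("compact letter display supports up to 12 groups")
  nsd <- p_adj > alpha | is.na(p_adj)
  diag(nsd) <- TRUE
  subsets <- lapply(seq_len(2^k) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) > 0 && all(nsd[s, s])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o)
    }, logical(1)))
  }, logical(1))]
  if (!is.null(order_by)) {
    maximal <- maximal[order(-vapply(maximal, function(s) max(order_by[s]),
                                     numeric(1)))]
  }
  letters_out <- setNames(rep("", k), g)
  for (i in seq_along(maximal)) {
    letters_out[maximal[[i]]] <- paste0(letters_out[maximal[[i]]],
                                        letters[i])
  }
  letters_out
}

#' Two-way factorial ANOVA of a kinetic parameter
#'
#' Fixed-effects two-way ANOVA with interaction of gallation and B-ring
#' hydroxylation on subject-level values (one value per subject per
#' catechin; each catechin is one cell of the 2 x 2 layout), followed by
#' Tukey's HSD across the four catechin cell means and a compact letter
#' display at `alpha`. Subjects are treated as independent observations
#' per catechin (no repeated-measures term), matching the original
#' analysis.
#'
#' @param data Tibble with columns `catechin`, `value` and (recommended)
#'   `subject_id`.
#' @param response_name Label for the response (reporting only).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `catekin_anova` object: list with `response`, `anova`
#'   (term, df, sumsq, meansq, statistic, p_value), `means` (per-catechin
#'   n, mean, sem, letters), `tukey` (pairwise diffs and adjusted p),
#'   `degenerate` flag (zero-variance response).
#' @export
factorial_anova <- function(data, response_name = "value", alpha = 0.05) {
  stopifnot(all(c("catechin", "value") %in% names(data)))
  attrs <- catechin_attributes()
  missing_cells <- setdiff(attrs$catechin, unique(data$catechin))
  if (length(missing_cells)) {
    abort(paste0("incomplete factorial layout; missing catechin cell(s): ",
                 paste(missing_cells, collapse = ", ")))
  }
  n_cell <- table(data$catechin)
  if (any(n_cell < 2)) {
    abort("need at least 2 subjects per catechin cell")
  }
  data <- data[, setdiff(names(data), c("gallated", "b_ring_hydroxyls"))]
  d <- dplyr::left_join(data, attrs, by = "catechin") |>
    dplyr::mutate(
      gallation = factor(ifelse(.data$gallated, "gallated", "non_gallated")),
      hydroxylation = factor(paste0("OH", .data$b_ring_hydroxyls)),
      catechin = factor(.data$catechin, levels = attrs$catechin)
    )
  degenerate <- sd(d$value) == 0
  if (degenerate) {
    warn("zero-variance response; ANOVA is degenerate")
  }
  maybe_quiet <- if (degenerate) suppressWarnings else identity
  fit <- aov(value ~ gallation * hydroxylation, data = d)
  tab <- maybe_quiet(as.data.frame(anova(fit)))
  anova_tbl <- tibble::tibble(
    term = rownames(tab),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`
  )
  cell_fit <- aov(value ~ catechin, data = d)
  tk <- maybe_quiet(TukeyHSD(cell_fit))$catechin
  pm <- matrix(NA_real_, 4, 4, dimnames = list(attrs$catechin,
                                               attrs$catechin))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  means <- d |>
    dplyr::group_by(.data$catechin) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  mv <- setNames(means$mean, as.character(means$catechin))
  lets <- compact_letters(pm, alpha = alpha,
                          order_by = mv[rownames(pm)])
  means$letters <- unname(lets[as.character(means$catechin)])
  structure(
    list(
      response = response_name,
      anova = anova_tbl,
      means = means,
      tukey = tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                             p_adj = tk[, "p adj"]),
      alpha = alpha,
      degenerate = degenerate
    ),
    class = "catekin_anova"
  )
}

#' @export
print.catekin_anova <- function(x, ...) {
  cat("<catekin_anova> response: ", x$response,
      if (x$degenerate) " (degenerate: zero variance)", "\n", sep = "")
  print(x$anova)
  cat("cell means (letters: groups sharing a letter do not differ at alpha = ",
      x$alpha, "):\n", sep = "")
  print(x$means)
  invisible(x)
}

#' @export
tidy.catekin_anova <- function(x, ...) x$anova

#' @export
glance.catekin_anova <- function(x, ...) {
  p <- setNames(x$anova$p_value, x$anova$term)
  tibble::tibble(
    p_gallation = unname(p["gallation"]),
    p_hydroxylation = unname(p["hydroxylation"]),
    p_interaction = unname(p["gallation:hydroxylation"]),
    degenerate = x$degenerate
  )
}

#' Exploratory three-way ANOVA including sex
#'
#' Adds sex as a third fixed factor to the factorial model to check
#' whether any sex term reaches the significance level; used as the
#' preliminary screen before collapsing to the two-way analysis.
#'
#' @param data Tibble with `catechin`, `value` and `sex` columns.
#' @param response_name Label for the response.
#' @param alpha Significance level.
#' @return A list with `anova` (tidy table), `sex_terms` (subset involving
#'   sex) and `sex_significant` (any sex term with p <= alpha).
#' @export
exploratory_sex_anova <- function(data, response_name = "value",
                                  alpha = 0.05) {
  stopifnot(all(c("catechin", "value", "sex") %in% names(data)))
  if (dplyr::n_distinct(data$sex) < 2) {
    abort("sex ANOVA needs both sexes in the cohort")
  }
  n_cell <- table(data$catechin)
  if (any(n_cell < 2) || length(n_cell) < 4) {
    abort("need the full 2 x 2 catechin layout with >= 2 values per cell")
  }
  data <- data[, setdiff(names(data), c("gallated", "b_ring_hydroxyls"))]
  d <- dplyr::left_join(data, catechin_attributes(), by = "catechin") |>
    dplyr::mutate(
      gallation = factor(ifelse(.data$gallated, "gallated", "non_gallated")),
      hydroxylation = factor(paste0("OH", .data$b_ring_hydroxyls)),
      sex = factor(.data$sex)
    )
  fit <- aov(value ~ sex * gallation * hydroxylation, data = d)
  tab <- as.data.frame(anova(fit))
  anova_tbl <- tibble::tibble(
    term = rownames(tab),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`
  )
  sex_terms <- anova_tbl[grepl("sex", anova_tbl$term), ]
  list(
    response = response_name,
    anova = anova_tbl,
    sex_terms = sex_terms,
    sex_significant = any(sex_terms$p_value <= alpha, na.rm = TRUE)
  )
}
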