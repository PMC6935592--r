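#' Cumulative weevil-attack count from survey flags
#'
#' Combines the presence/absence flags of two surveys (ages 10 and 15) into
#' the ordinal cumulative attack count
#' `CWA = WA_previous10 + WA_current10 + WA_11_14 + WA_current15`, where the
#' derived flag `WA_11_14` is 1 only when an attack was recorded prior to the
#' age-15 survey but none at or prior to age 10 (this avoids double-counting
#' earlier attacks). The result is always in \{0, 1, 2, 3\}.
#'
#' @param data Tibble with binary columns `wa_previous10`, `wa_current10`,
#'   `attack_prior15`, `wa_current15`.
#' @return `data` with an added ordinal `cwa` column.
#' @export
compute_cwa <- function(data) {
  cols <- c("wa_previous10", "wa_current10", "attack_prior15", "wa_current15")
  stopifnot(all(cols %in% names(data)))
  flags <- as.matrix(data[, cols])
  if (!all(flags %in% c(0, 1))) stop("attack flags must be binary 0/1",
                                     call. = FALSE)
  wa_11_14 <- as.integer(data$attack_prior15 == 1 &
                           data$wa_previous10 == 0 & data$wa_current10 == 0)
  dplyr::mutate(data, cwa = .data$wa_previous10 + .data$wa_current10 +
                  wa_11_14 + .data$wa_current15)
}

#' Enumerate the selection-index weight grid
#'
#' All weight 4-tuples `(w1, w2, w3, w4)` on the `step` lattice with
#' `0 <= w_i <= 1` and `w1 + w2 + w3 + w4 = 1`, each exactly once, in
#' lexicographic order. With `step = 0.05` this yields 1,771 indices
#' (`choose(1/step + 3, 3)` in general).
#'
#' @param step Lattice step; `1/step` must be an integer.
#' @return Tibble with columns `w1`..`w4`.
#' @export
enumerate_weight_grid <- function(step = 0.05) {
  if (step <= 0 || step > 1) stop("step must be in (0, 1]", call. = FALSE)
  N <- 1 / step
  if (abs(N - round(N)) > 1e-9) stop("1/step must be an integer", call. = FALSE)
  N <- as.integer(round(N))
  g <- expand.grid(k = 0:N, j = 0:N, i = 0:N)
  g <- g[g$i + g$j + g$k <= N, c("i", "j", "k")]
  g$l <- N - g$i - g$j - g$k
  g <- g[order(g$i, g$j, g$k), ]
  tibble::tibble(w1 = g$i * step, w2 = g$j * step,
                 w3 = g$k * step, w4 = g$l * step)
}

#' Selection-index values from per-trait breeding values
#'
#' Each trait's breeding values are scaled to unit variance (they are
#' already centred), then combined as a weighted sum; traits listed in
#' `negate` enter with a negative sign because a decrease in their value is
#' an improvement (e.g. an attack count).
#'
#' @param ebvs Tibble with `tree_id` and one breeding-value column per trait.
#' @param weights Named numeric vector of non-negative weights summing to 1,
#'   names matching trait columns of `ebvs`.
#' @param negate Character vector of traits entering with a negative sign.
#' @return Tibble `tree_id`, `si`.
#' @export
compute_si <- function(ebvs, weights, negate = character(0)) {
  stopifnot("tree_id" %in% names(ebvs), all(names(weights) %in% names(ebvs)))
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  si <- numeric(nrow(ebvs))
  for (tr in names(weights)) {
    v <- ebvs[[tr]]
    s <- sd(v)
    if (s == 0) stop("zero-variance breeding values for trait ", tr,
                     call. = FALSE)
    sgn <- if (tr %in% negate) -1 else 1
    si <- si + sgn * weights[[tr]] * (v / s)
  }
  tibble::tibble(tree_id = ebvs$tree_id, si = si)
}

#' Expected genetic gains from top-fraction selection
#'
#' Selects the top `fraction` of trees by a selection index (when `weights`
#' is given) or by a single trait's breeding value, and reports for every
#' trait the absolute expected gain - the mean raw-scale breeding value of
#' the selected trees expressed as a percentage of the trait's phenotypic
#' mean - and the relative gain, the ratio of that gain to the maximum
#' possible gain from selecting on the trait itself. For traits in `negate`
#' a reduction is the improvement, so their gains are sign-flipped and
#' single-trait selection takes the lowest breeding values. Ties are broken
#' by tree id for a deterministic selection.
#'
#' @inheritParams compute_si
#' @param phenotype_means Named vector of across-site phenotypic means (the
#'   denominators of the percentage gains).
#' @param fraction Selected proportion (default 0.05).
#' @param trait Single trait to select on (ignored when `weights` is given).
#' @return A `gain_report` tibble: `trait`, `abs_gain`, `rel_gain`, with the
#'   selected ids in attribute `"selected"`.
#' @export
genetic_gain <- function(ebvs, phenotype_means, fraction = 0.05,
                         weights = NULL, trait = NULL,
                         negate = character(0)) {
  traits <- setdiff(names(ebvs), "tree_id")
  stopifnot(all(traits %in% names(phenotype_means)),
            fraction > 0, fraction < 1)
  n_sel <- ceiling(fraction * nrow(ebvs))
  if (n_sel < 1) stop("fraction selects no tree", call. = FALSE)
  rank_by <- function(crit) {
    ord <- order(-crit, ebvs$tree_id)
    ebvs$tree_id[ord[seq_len(n_sel)]]
  }
  gain_for <- function(selected) {
    vapply(traits, function(tr) {
      g <- mean(ebvs[[tr]][ebvs$tree_id %in% selected]) /
        phenotype_means[[tr]] * 100
      if (tr %in% negate) -g else g
    }, 0)
  }
  # single-trait maxima define 100% relative gain
  max_gain <- vapply(traits, function(tr) {
    crit <- if (tr %in% negate) -ebvs[[tr]] else ebvs[[tr]]
    gain_for(rank_by(crit))[tr]
  }, 0)
  selected <- if (!is.null(weights)) {
    rank_by(compute_si(ebvs, weights, negate)$si)
  } else {
    stopifnot(!is.null(trait), trait %in% traits)
    crit <- if (trait %in% negate) -ebvs[[trait]] else ebvs[[trait]]
    rank_by(crit)
  }
  g <- gain_for(selected)
  out <- tibble::tibble(trait = traits, abs_gain = unname(g),
                        rel_gain = unname(100 * g / max_gain))
  attr(out, "selected") <- selected
  class(out) <- c("gain_report", class(out))
  out
}

#' Search the weight grid for the index maximising total relative gain
#'
#' Evaluates every selection index on the `step` lattice and returns the one
#' maximising the sum of relative gains over `traits_to_max` (the plainest
#' reading of "maximise the total relative gain"). Ties resolve to the first
#' index in lexicographic order.
#'
#' @inheritParams genetic_gain
#' @param index_traits Traits the four weights apply to, in `w1..w4` order.
#' @param traits_to_max Traits whose relative gains are summed.
#' @param step Weight lattice step.
#' @return A list with `weights`, the winning `gain_report` and the
#'   evaluated `grid` (weights plus total relative gain).
#' @export
optimize_si <- function(ebvs, phenotype_means, index_traits, traits_to_max,
                        step = 0.05, fraction = 0.05,
                        negate = character(0)) {
  stopifnot(length(index_traits) == 4)
  grid <- enumerate_weight_grid(step)
  total <- numeric(nrow(grid))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- setNames(as.numeric(grid[i, ]), index_traits)
    rep_i <- genetic_gain(ebvs, phenotype_means, fraction,
                          weights = w, negate = negate)
    reports[[i]] <- rep_i
    total[i] <- sum(rep_i$rel_gain[rep_i$trait %in% traits_to_max])
  }
  best <- which.max(total)
  list(weights = setNames(as.numeric(grid[best, ]), index_traits),
       report = reports[[best]],
       grid = dplyr::mutate(grid, total_rel_gain = total))
}
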