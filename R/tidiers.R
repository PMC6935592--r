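#' @describeIn fit_single_trait Tidy the variance components: one row per
#'   component with estimate and asymptotic SE.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.spruce_fit <- function(x, ...) {
  se <- setNames(rep(NA_real_, 4), names(x$varcomp))
  d <- suppressWarnings(sqrt(diag(x$vcov_varcomp)))
  se[names(d)] <- d
  tibble::tibble(component = names(x$varcomp),
                 estimate = unname(x$varcomp),
                 std.error = unname(se))
}

#' @describeIn fit_single_trait One-row model summary with heritability and
#'   type-B correlation.
#' @export
glance.spruce_fit <- function(x, ...) {
  gp <- estimate_genetic_params(x)
  tibble::tibble(trait = x$trait, n = x$n, logLik = x$loglik,
                 h2 = gp$h2, h2_se = gp$h2_se, rB = gp$rB, rB_se = gp$rB_se,
                 converged = x$converged, iterations = x$iterations)
}

#' @describeIn fit_bivariate Tidy the three correlations plus the derived
#'   phenotypic correlation, with SEs and LRT p-values where defined.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.spruce_bifit <- function(x, ...) {
  tibble::tibble(
    term = c("r_b", "r_a", "r_e", "r_p"),
    estimate = c(unname(x$correlations), x$r_p),
    std.error = c(unname(x$correlation_se), x$r_p_se),
    p.value = c(NA, x$p_ra, NA, x$p_rp))
}

#' @describeIn fit_bivariate One-row summary with single-site
#'   heritabilities.
#' @export
glance.spruce_bifit <- function(x, ...) {
  tibble::tibble(trait_i = x$traits[1], trait_j = x$traits[2], n = x$n,
                 r_a = unname(x$correlations["r_a"]), r_p = x$r_p,
                 h2_ss_i = unname(x$h2_ss[1]), h2_ss_j = unname(x$h2_ss[2]),
                 logLik = x$loglik, converged = x$converged,
                 pinned = x$pinned)
}

#' @describeIn cross_validate Per-cell predictive ability and accuracy.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.spruce_cv <- function(x, ...) x$cells

#' @describeIn cross_validate Means and standard errors over the
#'   fold x repeat cells.
#' @export
glance.spruce_cv <- function(x, ...) {
  ok <- x$cells[!x$cells$failed & !is.na(x$cells$pa), ]
  tibble::tibble(
    trait = x$trait, fitter = x$fitter, n_fits = x$n_fits,
    n_failed = sum(x$cells$failed),
    mean_pa = mean(ok$pa), se_pa = sd(ok$pa) / sqrt(nrow(ok)),
    mean_pacc = mean(ok$pacc), se_pacc = sd(ok$pacc) / sqrt(nrow(ok)),
    h2 = x$h2 %||% NA_real_)
}

#' @describeIn run_missing_data_experiment Per-replicate grid of PA/PACC.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.spruce_missing_experiment <- function(x, ...) x$grid

#' @describeIn run_missing_data_experiment Fraction x model means and SEs.
#' @export
glance.spruce_missing_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$grid, .data$model, .data$fraction),
    mean_pa = mean(.data$pa, na.rm = TRUE),
    se_pa = sd(.data$pa, na.rm = TRUE) / sqrt(sum(!is.na(.data$pa))),
    mean_pacc = mean(.data$pacc, na.rm = TRUE),
    se_pacc = sd(.data$pacc, na.rm = TRUE) / sqrt(sum(!is.na(.data$pacc))),
    .groups = "drop")
}

#' @describeIn run_missing_data_experiment Accuracy-versus-missingness
#'   curves, one line per model (the single-trait reference dashed).
#' @param object The experiment.
#' @param metric `"pacc"` or `"pa"`.
#' @export
autoplot.spruce_missing_experiment <- function(object, metric = c("pacc", "pa"),
                                               ...) {
  metric <- match.arg(metric)
  g <- glance(object)
  ycol <- paste0("mean_", metric)
  secol <- paste0("se_", metric)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$fraction, y = .data[[ycol]],
                                  colour = .data$model,
                                  linetype = .data$model == "single")) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[ycol]] - .data[[secol]],
      ymax = .data[[ycol]] + .data[[secol]])) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "dashed",
                                              `FALSE` = "solid"),
                                   guide = "none") +
    ggplot2::labs(x = "fraction of target-trait training phenotypes missing",
                  y = toupper(metric), colour = "model",
                  title = paste("Target trait:", object$target)) +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validate Distribution of within-fold predictive
#'   ability over cells.
#' @param object The cross-validation result.
#' @export
autoplot.spruce_cv <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(x = factor(.data$repeat_id),
                                             y = .data$pa)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "repeat", y = "predictive ability (PA)",
                  title = paste(object$fitter, "|", object$trait)) +
    ggplot2::theme_minimal()
}

#' Diagnostic scatter of genomic versus pedigree relationships
#'
#' Off-diagonal entries of G against A, the standard check that recorded
#' pedigrees agree with realised genomic relationships (mislabelled trees
#' show up as expected-0.5 pairs with realised ~0 relationship).
#'
#' @param A,G Relationship matrices sharing ids.
#' @param max_points Subsample cap on plotted pairs.
#' @param seed Seed for the subsample.
#' @return A ggplot.
#' @export
plot_relationship_check <- function(A, G, max_points = 20000L, seed = 1L) {
  ids <- intersect(rownames(A), rownames(G))
  A <- A[ids, ids]; G <- G[ids, ids]
  off <- which(upper.tri(A))
  if (length(off) > max_points) {
    off <- with_seed(seed, sample(off, max_points))
  }
  df <- tibble::tibble(a = A[off], g = G[off])
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$g)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "pedigree relationship (A)",
                  y = "genomic relationship (G)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
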