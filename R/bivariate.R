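#' Fit a bivariate animal model for a pair of traits (single site)
#'
#' REML fit of the stacked two-trait model with fixed trait means, random
#' block-within-trait effects `b(t) ~ N(0, I (x) V_B)`, additive effects
#' `a(t) ~ N(0, K (x) V_A)` and residuals `e ~ N(0, I (x) V_R)`, each 2 x 2
#' covariance parameterised as a unique variance per trait plus a correlation
#' (a CORGH structure). Intended for single-site subsets, mirroring the
#' practice of fitting per site when multi-site bivariate models will not
#' converge. Starting values default to single-trait fits with correlations
#' started at zero.
#'
#' The genetic correlation is the fitted `r_a`; the phenotypic correlation is
#' derived from the components as
#' `r_p = (r_b s_bi s_bj + r_a s_ai s_aj + r_e s_ei s_ej) /
#'   sqrt((s2_bi + s2_ai + s2_ei)(s2_bj + s2_aj + s2_ej))`
#' and single-site heritabilities as `h2_ss = s2_a / (s2_a + s2_e)`.
#' Significance: likelihood-ratio tests against the model with `r_a = 0`
#' (1 df) and against all correlations zero (3 df).
#'
#' @param data Single-site tibble with `tree_id`, `block` and both traits.
#' @param kernel Relationship matrix covering the trees.
#' @param trait_i,trait_j Names of the two trait columns.
#' @param start Optional list of starting values:
#'   `list(B = list(var =), A = list(var =), R = list(var =))`.
#' @param lrt Compute the two likelihood-ratio tests (two additional REML
#'   fits); set `FALSE` to skip.
#' @return A `spruce_bifit` with correlation estimates and SEs, `r_p`,
#'   per-trait `h2_ss`, LRT p-values and the component matrices.
#' @export
fit_bivariate <- function(data, kernel, trait_i, trait_j, start = NULL,
                          lrt = TRUE) {
  stopifnot(all(c("tree_id", "block", trait_i, trait_j) %in% names(data)))
  if ("site" %in% names(data) && length(unique(data$site)) > 1)
    stop("fit_bivariate expects a single-site subset", call. = FALSE)
  ids <- data$tree_id
  K <- kernel[ids, ids]
  blk <- factor(data$block)
  Zb <- model.matrix(~ 0 + blk)
  comps <- list(B = tcrossprod(Zb), A = K, R = diag(length(ids)))
  Y <- cbind(data[[trait_i]], data[[trait_j]])
  if (is.null(start)) {
    start <- bi_start(Y, comps)
  }
  fit <- mt_reml(Y, comps, start = start)
  raw <- fit$raw
  vars <- list(
    b = raw[c("B_var_1", "B_var_2")], a = raw[c("A_var_1", "A_var_2")],
    e = raw[c("R_var_1", "R_var_2")])
  r <- c(r_b = unname(raw["B_cor_1.2"]), r_a = unname(raw["A_cor_1.2"]),
         r_e = unname(raw["R_cor_1.2"]))
  ses <- sqrt(pmax(diag(fit$vcov_raw), 0))
  r_se <- c(r_b = unname(ses["B_cor_1.2"]), r_a = unname(ses["A_cor_1.2"]),
            r_e = unname(ses["R_cor_1.2"]))
  r_p <- bi_rp(raw)
  # delta-method SE of r_p over all nine raw parameters
  gr <- vapply(seq_along(raw), function(i) {
    h <- max(abs(raw[i]), 0.1) * 1e-5
    x1 <- raw; x2 <- raw
    x1[i] <- x1[i] + h; x2[i] <- x2[i] - h
    (bi_rp(x1) - bi_rp(x2)) / (2 * h)
  }, 0)
  ord <- match(names(raw), colnames(fit$vcov_raw))
  r_p_se <- if (!anyNA(ord) && all(is.finite(fit$vcov_raw))) {
    sqrt(max(drop(gr %*% fit$vcov_raw[ord, ord] %*% gr), 0))
  } else NA_real_
  h2_ss <- vars$a / (vars$a + vars$e)
  names(h2_ss) <- c(trait_i, trait_j)

  p_ra <- p_rp <- NA_real_
  if (lrt) {
    fit_ra0 <- mt_reml(Y, comps, start = start, fix_cor = list(A = 0))
    fit_all0 <- mt_reml(Y, comps, start = start,
                        fix_cor = list(A = 0, B = 0, R = 0))
    p_ra <- pchisq(max(0, 2 * (fit$loglik - fit_ra0$loglik)), 1,
                   lower.tail = FALSE)
    p_rp <- pchisq(max(0, 2 * (fit$loglik - fit_all0$loglik)), 3,
                   lower.tail = FALSE)
  }
  structure(list(
    traits = c(trait_i, trait_j), correlations = r, correlation_se = r_se,
    r_p = r_p, r_p_se = r_p_se, h2_ss = h2_ss,
    p_ra = p_ra, p_rp = p_rp, Vg = fit$Vg, loglik = fit$loglik,
    converged = fit$converged, pinned = fit$pinned, raw = raw,
    n = nrow(data)), class = "spruce_bifit")
}

# starting values from single-trait REML fits of the same structure, r = 0
bi_start <- function(Y, comps) {
  sv <- lapply(seq_len(ncol(Y)), function(t) {
    obs <- which(!is.na(Y[, t]))
    y <- Y[obs, t]
    res <- reml_vc(y, matrix(1, length(obs), 1),
                   lapply(comps, function(M) M[obs, obs, drop = FALSE]),
                   max_iter = 50L)
    pmax(res$theta, 1e-4 * var(y))
  })
  lapply(setNames(seq_along(comps), names(comps)), function(g) {
    list(var = vapply(sv, `[`, 0, g), cor = 0)
  })
}

bi_rp <- function(raw) {
  num <- raw["B_cor_1.2"] * sqrt(raw["B_var_1"] * raw["B_var_2"]) +
    raw["A_cor_1.2"] * sqrt(raw["A_var_1"] * raw["A_var_2"]) +
    raw["R_cor_1.2"] * sqrt(raw["R_var_1"] * raw["R_var_2"])
  den <- sqrt((raw["B_var_1"] + raw["A_var_1"] + raw["R_var_1"]) *
                (raw["B_var_2"] + raw["A_var_2"] + raw["R_var_2"]))
  unname(num / den)
}

#' @export
print.spruce_bifit <- function(x, ...) {
  cat("<spruce_bifit>", paste(x$traits, collapse = " ~ "), "| n =", x$n, "\n")
  cat(sprintf("  r_a = %.3f (%.3f), p = %.3g | r_p = %.3f (%.3f), p = %.3g\n",
              x$correlations["r_a"], x$correlation_se["r_a"], x$p_ra,
              x$r_p, x$r_p_se, x$p_rp))
  cat(sprintf("  h2_ss: %s = %.3f, %s = %.3f\n", x$traits[1], x$h2_ss[1],
              x$traits[2], x$h2_ss[2]))
  invisible(x)
}

#' Fit a multi-trait GBLUP on adjusted phenotypes
#'
#' The two-step multi-trait model: phenotypes pre-adjusted for site and block
#' effects ([adjust_phenotypes()]) are modelled as
#' `y* = trait mean + a(t) + e` with `a ~ N(0, K (x) V_A)` and
#' `e ~ N(0, I (x) V_R)`, both unstructured (CORGH-parameterised) across
#' traits; the genotype-by-environment rank-change interaction is not fitted.
#' Missing phenotypes are allowed in any trait: the equations are built over
#' observed cells only, and breeding values are returned for every kernel
#' individual and every trait, including trees missing the target trait.
#'
#' @param adjusted Tibble of adjusted phenotypes (`tree_id` plus trait
#'   columns; `NA` = missing record).
#' @param kernel Relationship matrix (usually G).
#' @param traits Character vector of 1-3 trait columns.
#' @param start Optional starting values as in [fit_bivariate()].
#' @param varcomp Optional fixed components `list(A = V_A, R = V_R)`; skips
#'   REML and solves the prediction equations at these values.
#' @return A `spruce_mtfit` with `VA`, `VR`, `gebv` (tibble of per-trait
#'   breeding values for all kernel ids) and fit diagnostics.
#' @export
fit_multitrait_gblup <- function(adjusted, kernel, traits, start = NULL,
                                 varcomp = NULL) {
  stopifnot(all(c("tree_id", traits) %in% names(adjusted)))
  if (length(traits) > 3)
    stop("at most three traits are supported", call. = FALSE)
  ids <- adjusted$tree_id
  K <- kernel[ids, ids]
  comps <- list(A = K, R = diag(length(ids)))
  Y <- as.matrix(adjusted[, traits])
  miss_all <- colSums(!is.na(Y)) == 0
  if (any(miss_all)) stop("trait 100% missing: ",
                          paste(traits[miss_all], collapse = ", "),
                          call. = FALSE)
  if (is.null(varcomp)) {
    fit <- mt_reml(Y, comps, start = start)
    if (fit$pinned) warning("trait pair close to collinear in V_A or V_R",
                            call. = FALSE)
  } else {
    fit <- mt_eval(Y, comps, list(A = varcomp$A, R = varcomp$R))
    fit$pinned <- FALSE
  }
  gebv_m <- mt_gebv(fit, kernel, rownames(kernel), data_ids = ids)
  colnames(gebv_m) <- traits
  gebv <- tibble::as_tibble(gebv_m, rownames = "tree_id")
  p <- length(traits)
  VA <- fit$Vg$A; VR <- fit$Vg$R
  dimnames(VA) <- dimnames(VR) <- list(traits, traits)
  structure(list(traits = traits, VA = VA, VR = VR, gebv = gebv,
                 loglik = fit$loglik, converged = fit$converged,
                 fixed_varcomp = !is.null(varcomp), n_obs = fit$n_obs),
            class = "spruce_mtfit")
}

#' @export
print.spruce_mtfit <- function(x, ...) {
  cat("<spruce_mtfit>", paste(x$traits, collapse = ", "),
      "| observed cells =", x$n_obs,
      if (x$fixed_varcomp) "| fixed components", "\n")
  cat("V_A:\n"); print(round(x$VA, 4))
  invisible(x)
}
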