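#' Fit the single-trait individual-tree ("animal") mixed model by REML
#'
#' Fits `y = mu + site + block(site) + a + site:a + e` where the additive
#' effect has covariance `s2_a * K` for a pedigree (A) or genomic (G) kernel
#' `K`, the site-by-additive interaction has covariance `s2_sa * (I_s (x) K)`
#' (equivalently `s2_sa * (K o S)` over observed trees, `S` the same-site
#' indicator), blocks within sites are i.i.d., and residuals are homogeneous
#' across sites. Trees with `NA` phenotypes stay in the kernel and receive
#' breeding-value predictions, which is how cross-validation masks its
#' validation folds.
#'
#' @param data Tibble with `tree_id`, `site`, `block` and the trait column.
#' @param kernel Relationship matrix (A or G) covering at least all
#'   phenotyped trees; ids on dimnames.
#' @param trait Name of the trait column.
#' @param drop_terms Character subset of `c("block", "additive",
#'   "site_additive")` to omit (reduced models for likelihood-ratio tests).
#'   The site-by-additive term is dropped automatically for single-site data.
#' @param varcomp Optional named vector of fixed variance components
#'   (`s2_b`, `s2_a`, `s2_sa`, `s2_e`); when given, no REML iteration is done
#'   and BLUPs are computed at these values.
#' @param algorithm,max_iter REML settings; `"hybrid"` runs monotone EM
#'   updates accelerated by average-information steps, `"em"` is the pure
#'   monotone path.
#' @return A `spruce_fit` object: variance components and their asymptotic
#'   covariance, REML log-likelihood, fixed-effect estimates, `blups` (a
#'   tibble of breeding values for every kernel id), convergence diagnostics.
#' @export
fit_single_trait <- function(data, kernel, trait,
                             drop_terms = NULL,
                             varcomp = NULL,
                             algorithm = c("hybrid", "em", "ai"),
                             max_iter = 200L) {
  algorithm <- match.arg(algorithm)
  stopifnot(all(c("tree_id", "site", "block", trait) %in% names(data)))
  bad <- setdiff(data$tree_id, rownames(kernel))
  if (length(bad)) stop("trees absent from the kernel: ",
                        paste(head(bad, 5), collapse = ", "), call. = FALSE)
  obs <- which(!is.na(data[[trait]]))
  if (length(obs) < 3) stop("fewer than 3 phenotyped trees", call. = FALSE)
  d <- data[obs, ]
  y <- d[[trait]]
  n_site <- length(unique(d$site))
  X <- if (n_site > 1) model.matrix(~ site, d) else
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)

  terms <- c("block", "additive", if (n_site > 1) "site_additive")
  terms <- setdiff(terms, drop_terms)
  K <- kernel[d$tree_id, d$tree_id]
  Vlist <- list()
  if ("block" %in% terms) {
    sb <- factor(paste(d$site, d$block, sep = ":"))
    Zb <- model.matrix(~ 0 + sb)
    Vlist$s2_b <- tcrossprod(Zb)
  }
  if ("additive" %in% terms) Vlist$s2_a <- K
  if ("site_additive" %in% terms) {
    S <- outer(d$site, d$site, `==`) * 1
    Vlist$s2_sa <- K * S
  }
  Vlist$s2_e <- diag(length(y))

  if (!is.null(varcomp)) {
    theta <- varcomp[names(Vlist)]
    if (anyNA(theta)) stop("varcomp must name: ",
                           paste(names(Vlist), collapse = ", "), call. = FALSE)
    res <- reml_eval(y, X, Vlist, theta)
    res$converged <- TRUE
  } else {
    res <- reml_vc(y, X, Vlist, algorithm = algorithm, max_iter = max_iter)
    if (!res$converged) warning("REML did not converge in ", max_iter,
                                " iterations", call. = FALSE)
  }
  theta <- res$theta
  names(theta) <- names(Vlist)

  beta <- drop(solve(res$XtViX, crossprod(res$ViX, y)))
  names(beta) <- colnames(X)
  ids_all <- rownames(kernel)
  a_all <- if ("additive" %in% terms) {
    drop(theta["s2_a"] * kernel[ids_all, d$tree_id] %*% res$Py)
  } else rep(0, length(ids_all))
  blups <- tibble::tibble(tree_id = ids_all, ebv = a_all)
  full <- setNames(rep(0, 4), c("s2_b", "s2_a", "s2_sa", "s2_e"))
  full[names(theta)] <- theta
  structure(list(
    varcomp = full, vcov_varcomp = res$vcov_theta, loglik = res$loglik,
    fixed = beta, blups = blups, trait = trait, terms = terms,
    converged = res$converged, iterations = res$iterations,
    trajectory = res$trajectory, n = length(y),
    data_ids = d$tree_id, algorithm = if (is.null(varcomp)) algorithm else "fixed"
  ), class = "spruce_fit")
}

#' @export
print.spruce_fit <- function(x, ...) {
  cat("<spruce_fit>", x$trait, "| n =", x$n, "| REML logLik =",
      formatC(x$loglik, digits = 6, format = "g"),
      if (!x$converged) "(NOT converged)", "\n")
  print(round(x$varcomp, 5))
  invisible(x)
}

#' Heritability and type-B genetic correlation with delta-method SEs
#'
#' From a converged [fit_single_trait()] computes the narrow-sense individual
#' heritability `h2 = s2_a / (s2_a + s2_sa + s2_e)` and the type-B genetic
#' correlation `rB = s2_a / (s2_a + s2_sa)` (values near 1 meaning little
#' genotype-by-environment rank change), with standard errors by the
#' first-order delta method using the asymptotic covariance of the variance
#' components.
#'
#' @param fit A `spruce_fit`.
#' @return A one-row tibble: `h2`, `h2_se`, `rB`, `rB_se`.
#' @export
estimate_genetic_params <- function(fit) {
  stopifnot(inherits(fit, "spruce_fit"))
  th <- fit$varcomp
  Vc <- matrix(0, 4, 4, dimnames = list(names(th), names(th)))
  ok <- rownames(fit$vcov_varcomp)
  if (!is.null(ok) && all(is.finite(fit$vcov_varcomp)))
    Vc[ok, ok] <- fit$vcov_varcomp
  D <- th["s2_a"] + th["s2_sa"] + th["s2_e"]
  Da <- th["s2_a"] + th["s2_sa"]
  if (D <= 0) {
    return(tibble::tibble(h2 = NA_real_, h2_se = NA_real_,
                          rB = NA_real_, rB_se = NA_real_))
  }
  h2 <- unname(th["s2_a"] / D)
  g_h2 <- c(s2_b = 0, s2_a = unname((D - th["s2_a"]) / D^2),
            s2_sa = unname(-th["s2_a"] / D^2), s2_e = unname(-th["s2_a"] / D^2))
  h2_se <- sqrt(max(drop(g_h2 %*% Vc %*% g_h2), 0))
  if (Da <= 0) {
    rB <- NA_real_; rB_se <- NA_real_
  } else {
    rB <- unname(th["s2_a"] / Da)
    g_rB <- c(s2_b = 0, s2_a = unname(th["s2_sa"] / Da^2),
              s2_sa = unname(-th["s2_a"] / Da^2), s2_e = 0)
    rB_se <- sqrt(max(drop(g_rB %*% Vc %*% g_rB), 0))
  }
  tibble::tibble(h2 = h2, h2_se = h2_se, rB = rB, rB_se = rB_se)
}

#' Likelihood-ratio test for a variance component
#'
#' `p = P(chi2_df >= 2 * (ll_full - ll_reduced))`; a negative statistic (the
#' reduced model fitting better by numerical noise) is truncated to zero. The
#' test uses the plain chi-square reference even when the component sits on
#' the boundary, which is conservative.
#'
#' @param fit_full,fit_reduced Fits of nested models with the same fixed
#'   effects and response.
#' @param df Degrees of freedom (number of parameters dropped).
#' @return The p-value.
#' @export
lrt_variance <- function(fit_full, fit_reduced, df = 1L) {
  stopifnot(inherits(fit_full, "spruce_fit") | !is.null(fit_full$loglik),
            df >= 1)
  if (!is.null(fit_full$trait) && !is.null(fit_reduced$trait) &&
      !identical(fit_full$trait, fit_reduced$trait))
    stop("models fit different responses; not nested", call. = FALSE)
  if (!is.null(fit_full$terms) && !is.null(fit_reduced$terms) &&
      !all(fit_reduced$terms %in% fit_full$terms))
    stop("reduced model is not nested in the full model", call. = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  pchisq(stat, df, lower.tail = FALSE)
}

#' Adjust phenotypes for site and block effects
#'
#' Computes `y* = y - X beta - Z b`, the conditional residuals of the model
#' with fixed site effects and random block-within-site effects (block
#' variance estimated by REML). By the first block of Henderson's equations
#' the residuals sum exactly to zero. Missing phenotypes propagate as `NA`.
#' These adjusted phenotypes are the response of the two-step multi-trait
#' models and the comparator used for predictive ability.
#'
#' @param data Tibble with `tree_id`, `site`, `block` and trait columns.
#' @param traits Character vector of trait columns to adjust; defaults to all
#'   numeric non-design columns.
#' @return `data` with each trait column replaced by its adjusted version.
#' @export
adjust_phenotypes <- function(data, traits = NULL) {
  stopifnot(all(c("tree_id", "site", "block") %in% names(data)))
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                      c("tree_id", "site", "block", "family"))
  }
  if (any(table(data$site) == 0)) stop("empty site", call. = FALSE)
  out <- data
  for (tr in traits) {
    obs <- which(!is.na(data[[tr]]))
    d <- data[obs, ]
    y <- d[[tr]]
    n_site <- length(unique(d$site))
    X <- if (n_site > 1) model.matrix(~ site, d) else
      matrix(1, nrow(d), 1)
    sb <- factor(paste(d$site, d$block, sep = ":"))
    if (nlevels(sb) > 1) {
      Zb <- model.matrix(~ 0 + sb)
      Vlist <- list(s2_b = tcrossprod(Zb), s2_e = diag(length(y)))
      res <- reml_vc(y, X, Vlist)
      beta <- drop(solve(res$XtViX, crossprod(res$ViX, y)))
      bblup <- drop(res$theta["s2_b"] * crossprod(Zb, res$Py))
      ystar <- y - drop(X %*% beta) - drop(Zb %*% bblup)
    } else {
      ystar <- unname(drop(residuals(lm(y ~ X - 1))))
    }
    out[[tr]] <- NA_real_
    out[[tr]][obs] <- ystar
  }
  out
}
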