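#' MCMC settings for the Bayesian whole-genome regressions
#'
#' Chain defaults follow common practice for these models on array-scale
#' panels: 50,000 iterations, 15,000 burn-in, thinning interval 20. Priors
#' are scaled-inverse-chi-square with `df0 = 5` and scales set so that a
#' proportion `R2` (default 0.5) of the phenotypic variance is attributed a
#' priori to the genomic term and the rest to the residual; the inclusion
#' proportion of BayesC-pi gets a uniform Beta(1, 1) prior.
#'
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning interval.
#' @param df0 Prior degrees of freedom for all variance components.
#' @param R2 Prior share of phenotypic variance assigned to markers.
#' @param seed Integer seed for the chain.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 50000L, burn_in = 15000L, thin = 20L,
                        df0 = 5, R2 = 0.5, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df0 = df0, R2 = R2,
                 seed = as.integer(seed)), class = "mcmc_config")
}

bayes_design <- function(data) {
  n_site <- length(unique(data$site))
  Xs <- if (n_site > 1) model.matrix(~ site, data) else
    matrix(1, nrow(data), 1)
  sb <- factor(paste(data$site, data$block, sep = ":"))
  W <- cbind(Xs, if (nlevels(sb) > 1) model.matrix(~ 0 + sb))
  w_group <- c(rep(0L, ncol(Xs)),
               if (nlevels(sb) > 1) rep(1L, nlevels(sb)))
  list(W = W, w_group = w_group)
}

fit_marker_model <- function(data, genotypes, trait, config, bayescpi,
                             response = c("gaussian", "ordinal"),
                             fix_var = FALSE, sigma2_m_fix = NA,
                             sigma2_e_fix = NA, store_effects = FALSE) {
  response <- match.arg(response)
  stopifnot(inherits(config, "mcmc_config"),
            all(c("tree_id", "site", "block", trait) %in% names(data)))
  if (anyNA(genotypes)) stop("genotypes contain missing calls; impute first",
                             call. = FALSE)
  obs <- which(!is.na(data[[trait]]))
  d <- data[obs, ]
  y <- d[[trait]]
  if (any(!is.finite(y))) stop("non-finite phenotype", call. = FALSE)
  centers <- colMeans(genotypes)
  Z <- sweep(genotypes[d$tree_id, , drop = FALSE], 2L, centers)
  des <- bayes_design(d)
  vy <- max(var(y), 1e-6) # guard degenerate constant responses
  msx <- sum(apply(Z, 2, var))
  S0_m <- vy * config$R2 / msx * (config$df0 + 2) / config$df0
  S0_e <- vy * (1 - config$R2) * (config$df0 + 2) / config$df0
  S0_b <- vy * 0.1 * (config$df0 + 2) / config$df0
  ordinal <- response == "ordinal"
  cats <- integer(0)
  tau_init <- numeric(0)
  if (ordinal) {
    cats <- as.integer(round(y))
    lev <- sort(unique(cats))
    if (length(lev) < 2) stop("all observations in one category", call. = FALSE)
    if (!all(diff(lev) == 1) || min(lev) != 0)
      stop("ordinal categories must be consecutive integers starting at 0; ",
           "merge absent categories first", call. = FALSE)
    K <- length(lev)
    tau_init <- c(0, seq_len(K - 2) * 0.8)
    S0_m <- config$R2 / msx * (config$df0 + 2) / config$df0
  }
  res <- with_seed(config$seed,
    brr_gibbs_cpp(as.numeric(y), cats, ordinal, des$W, des$w_group, Z,
                  config$n_iter, config$burn_in, config$thin, bayescpi,
                  config$df0, S0_m, S0_e, S0_b,
                  fix_var, sigma2_m_fix, sigma2_e_fix,
                  tau_init, store_effects))
  gebv <- tibble::tibble(tree_id = d$tree_id, gebv = res$gebv_mean)
  structure(list(
    method = if (bayescpi) "BayesCpi" else "BRR",
    trait = trait, response = response,
    effects = setNames(res$a_mean, colnames(genotypes)),
    inclusion = if (bayescpi) setNames(res$inclusion, colnames(genotypes)),
    pi_mean = if (bayescpi) mean(res$pi),
    centers = centers, theta = res$theta_mean, gebv = gebv,
    traces = list(sigma2_m = res$sigma2_m, sigma2_e = res$sigma2_e,
                  sigma2_b = res$sigma2_b, pi = res$pi),
    tau = if (ordinal) res$tau_mean,
    effect_draws = if (store_effects) res$effects,
    n_keep = res$n_keep, config = config), class = "marker_effect_model")
}

#' Bayesian ridge regression on markers
#'
#' Gibbs-sampled whole-genome regression `y = mu + site + block(site) +
#' Z a_m + e` with a common normal prior on all marker effects (every marker
#' has a nonzero effect, the polygenic assumption). Ordinal responses use a
#' probit latent liability with estimated thresholds. No
#' genotype-by-environment term is fitted, i.e. marker effects are assumed
#' stable across sites.
#'
#' @param data Tibble with `tree_id`, `site`, `block` and the trait.
#' @param genotypes Complete dosage matrix covering the phenotyped trees.
#' @param trait Trait column name.
#' @param config An [mcmc_config()].
#' @param response `"gaussian"` or `"ordinal"` (categories 0..K).
#' @param fix_var Fix `sigma2_m` and `sigma2_e` at the supplied values
#'   instead of sampling them (used for conjugate closed-form checks).
#' @param sigma2_m_fix,sigma2_e_fix The fixed values when `fix_var = TRUE`.
#' @param store_effects Keep the thinned marker-effect draws.
#' @return A `marker_effect_model` with posterior-mean effects, training
#'   GEBVs, variance traces and (ordinal) thresholds.
#' @export
fit_brr <- function(data, genotypes, trait, config = mcmc_config(),
                    response = c("gaussian", "ordinal"),
                    fix_var = FALSE, sigma2_m_fix = NA, sigma2_e_fix = NA,
                    store_effects = FALSE) {
  fit_marker_model(data, genotypes, trait, config, bayescpi = FALSE,
                   response = response, fix_var = fix_var,
                   sigma2_m_fix = sigma2_m_fix, sigma2_e_fix = sigma2_e_fix,
                   store_effects = store_effects)
}

#' BayesC-pi whole-genome regression
#'
#' As [fit_brr()] but marker effects follow a spike-slab prior: each marker
#' is included with probability `pi` (uniform prior, sampled by Gibbs), and
#' excluded effects are exactly zero, which suits oligogenic architectures.
#' Reports the posterior mean of `pi` and per-marker inclusion
#' probabilities.
#'
#' @inheritParams fit_brr
#' @return A `marker_effect_model` with `pi_mean` and `inclusion`.
#' @export
fit_bayescpi <- function(data, genotypes, trait, config = mcmc_config(),
                         response = c("gaussian", "ordinal"),
                         store_effects = FALSE) {
  fit_marker_model(data, genotypes, trait, config, bayescpi = TRUE,
                   response = response, store_effects = store_effects)
}

#' @export
print.marker_effect_model <- function(x, ...) {
  cat("<marker_effect_model>", x$method, "|", x$trait, "(", x$response, ") |",
      length(x$effects), "markers |", x$n_keep, "kept draws\n")
  if (!is.null(x$pi_mean)) cat("posterior mean pi =", round(x$pi_mean, 3), "\n")
  invisible(x)
}

#' Threshold GBLUP for ordinal traits
#'
#' Probit animal model on a latent liability: `l = mu + site + block(site) +
#' a + e`, `a ~ N(0, sigma2_a K)`, residual liability variance fixed at 1 and
#' first threshold at 0 for identification; liabilities, thresholds and
#' `sigma2_a` are sampled by Gibbs on the eigenbasis of the kernel. Breeding
#' values are posterior means of `a`; trees in the kernel without phenotypes
#' get projected predictions `K[miss, obs] K[obs, obs]^-1 a_obs`.
#'
#' @inheritParams fit_brr
#' @param kernel Relationship matrix (usually G) covering the trees.
#' @return A `tgblup_fit` with `gebv` for every kernel id, the liability
#'   heritability posterior (`h2_liab`, mean and SD of
#'   `sigma2_a / (sigma2_a + 1)`), thresholds and traces.
#' @export
fit_tgblup <- function(data, kernel, trait, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"),
            all(c("tree_id", "site", "block", trait) %in% names(data)))
  obs <- which(!is.na(data[[trait]]))
  d <- data[obs, ]
  cats <- as.integer(round(d[[trait]]))
  lev <- sort(unique(cats))
  if (length(lev) < 2) stop("all observations in one category", call. = FALSE)
  if (!all(diff(lev) == 1) || min(lev) != 0)
    stop("ordinal categories must be consecutive integers starting at 0; ",
         "merge absent categories first", call. = FALSE)
  K <- kernel[d$tree_id, d$tree_id]
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  U <- eg$vectors[, keep, drop = FALSE]
  dvals <- eg$values[keep]
  des <- bayes_design(d)
  nc <- length(lev)
  tau_init <- c(0, seq_len(nc - 2) * 0.8)
  S0_a <- 0.5 * (config$df0 + 2) / config$df0
  S0_b <- 0.1 * (config$df0 + 2) / config$df0
  res <- with_seed(config$seed,
    tgblup_gibbs_cpp(cats, U, dvals, des$W, des$w_group,
                     config$n_iter, config$burn_in, config$thin,
                     config$df0, S0_a, S0_b, tau_init))
  a_obs <- res$a_mean
  ids_all <- rownames(kernel)
  miss <- setdiff(ids_all, d$tree_id)
  a_all <- setNames(numeric(length(ids_all)), ids_all)
  a_all[d$tree_id] <- a_obs
  if (length(miss)) {
    Koo <- K + diag(1e-6, nrow(K))
    a_all[miss] <- drop(kernel[miss, d$tree_id, drop = FALSE] %*%
                          solve(Koo, a_obs))
  }
  h2_draws <- res$sigma2_a / (res$sigma2_a + 1)
  structure(list(
    trait = trait, gebv = tibble::tibble(tree_id = ids_all,
                                         gebv = unname(a_all)),
    h2_liab = c(mean = mean(h2_draws), sd = sd(h2_draws)),
    sigma2_a = res$sigma2_a, tau = res$tau_mean,
    n_keep = res$n_keep, config = config), class = "tgblup_fit")
}

#' @export
print.tgblup_fit <- function(x, ...) {
  cat("<tgblup_fit>", x$trait, "| liability h2 =",
      round(x$h2_liab["mean"], 3), "(posterior SD",
      paste0(round(x$h2_liab["sd"], 3), ")"), "\n")
  invisible(x)
}

#' Genomic breeding values from posterior-mean marker effects
#'
#' `GEBV_i = sum_j Z'_ij a_hat_j` over the model's markers, with dosages
#' centred exactly as in training.
#'
#' @param model A `marker_effect_model`.
#' @param genotypes Dosage matrix whose columns cover the model's markers.
#' @return A tibble `tree_id`, `gebv`.
#' @export
gebv_from_markers <- function(model, genotypes) {
  stopifnot(inherits(model, "marker_effect_model"))
  mk <- names(model$effects)
  missing_mk <- setdiff(mk, colnames(genotypes))
  if (length(missing_mk))
    stop("marker mismatch; absent from genotypes: ",
         paste(head(missing_mk, 5), collapse = ", "), call. = FALSE)
  Z <- sweep(genotypes[, mk, drop = FALSE], 2L, model$centers[mk])
  tibble::tibble(tree_id = rownames(genotypes),
                 gebv = unname(drop(Z %*% model$effects)))
}
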