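#' Cross-validation scheme
#'
#' Family-stratified tenfold cross-validation repeated ten times: within
#' each family, trees are randomly permuted and dealt round-robin into
#' folds, so each fold holds roughly 10% of every family (fold sizes within
#' a family differ by at most one tree).
#'
#' @param n_folds,n_repeats Number of folds and repeats.
#' @param seed Integer seed; repeats use derived sub-seeds.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 10L, n_repeats = 10L, seed = 1L) {
  stopifnot(n_folds >= 1, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)), class = "cv_scheme")
}

#' Assign trees to cross-validation folds, stratified by family
#'
#' @param data Tibble with `tree_id` and `family`.
#' @param scheme A [cv_scheme()].
#' @return Tibble `repeat_id`, `fold`, `tree_id`, `family`; within every
#'   repeat the folds partition the trees.
#' @export
make_folds <- function(data, scheme = cv_scheme()) {
  stopifnot(all(c("tree_id", "family") %in% names(data)))
  seeds <- derive_seeds(scheme$seed, scheme$n_repeats)
  small <- table(data$family) < scheme$n_folds
  if (any(small)) {
    message(sum(small), " families are smaller than n_folds; ",
            "some folds receive no tree from them")
  }
  purrr::map_dfr(seq_len(scheme$n_repeats), function(r) {
    with_seed(seeds[r], {
      parts <- lapply(split(seq_len(nrow(data)), data$family), function(idx) {
        idx <- sample(idx)
        start <- sample(scheme$n_folds, 1L)
        fold <- ((start + seq_along(idx) - 2L) %% scheme$n_folds) + 1L
        tibble::tibble(row = idx, fold = fold)
      })
      asg <- dplyr::bind_rows(parts)
      tibble::tibble(repeat_id = r, fold = asg$fold,
                     tree_id = data$tree_id[asg$row],
                     family = data$family[asg$row])
    })
  })
}

#' Predictive ability: correlation of predictions with adjusted phenotypes
#'
#' @param predicted,ystar Numeric vectors over the validation trees.
#' @return Pearson correlation, or `NA` if fewer than 3 complete pairs or
#'   either vector has zero variance.
#' @export
compute_pa <- function(predicted, ystar) {
  ok <- is.finite(predicted) & is.finite(ystar)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(predicted[ok]) == 0 || sd(ystar[ok]) == 0) return(NA_real_)
  cor(predicted[ok], ystar[ok])
}

#' Predictive accuracy: PA standardised by the square root of heritability
#'
#' `PACC = PA / sqrt(h2)`, the usual approximation of the correlation with
#' true breeding values; `h2` should be the full-data single-trait GBLUP
#' estimate for all model types. Returns `NA` when `h2` is zero or missing;
#' values above 1 are returned as-is.
#'
#' @param pa Predictive ability.
#' @param h2 Narrow-sense heritability estimate.
#' @return The predictive accuracy.
#' @export
compute_pacc <- function(pa, h2) {
  ifelse(is.na(h2) | h2 <= 0, NA_real_, pa / sqrt(h2))
}

#' Cross-validate a genomic (or pedigree) prediction model
#'
#' For every fold x repeat cell, validation phenotypes are masked (rows are
#' kept so design factors stay intact), the model is fitted on the training
#' trees, breeding values are predicted for the validation trees, and the
#' predictive ability is the within-fold correlation with the adjusted
#' phenotypes y*. Exactly `n_folds * n_repeats` fits are performed.
#'
#' @param data Tibble with `tree_id`, `site`, `block`, `family` and the
#'   trait.
#' @param trait Trait column name.
#' @param fitter `"gblup"`, `"ablup"` (a kernel fit with A), `"tgblup"`,
#'   `"brr"`, `"bayescpi"`, or a function `f(train_data, valid_ids)`
#'   returning a tibble `tree_id`, `pred` (used for stubs and custom
#'   models).
#' @param kernel Relationship matrix for kernel-based fitters.
#' @param genotypes Complete dosage matrix for marker-based fitters.
#' @param scheme A [cv_scheme()].
#' @param h2 Heritability used for PACC (the full-data single-trait GBLUP
#'   estimate); if `NULL` and a kernel is supplied it is estimated once from
#'   the full data.
#' @param mcmc [mcmc_config()] for the Bayesian fitters.
#' @return A `spruce_cv` object; `tidy()` gives per-cell PA/PACC, `glance()`
#'   the means and standard errors over cells.
#' @export
cross_validate <- function(data, trait, fitter = "gblup", kernel = NULL,
                           genotypes = NULL, scheme = cv_scheme(),
                           h2 = NULL, mcmc = NULL) {
  stopifnot(all(c("tree_id", "family", trait) %in% names(data)))
  is_fun <- is.function(fitter)
  if (!is_fun) fitter <- match.arg(fitter,
                                   c("gblup", "ablup", "tgblup", "brr", "bayescpi"))
  ystar <- adjust_phenotypes(data, traits = trait)[[trait]]
  names(ystar) <- data$tree_id
  if (is.null(h2) && !is_fun && !is.null(kernel)) {
    h2 <- estimate_genetic_params(fit_single_trait(data, kernel, trait))$h2
  }
  folds <- make_folds(data, scheme)
  if (is.null(mcmc)) mcmc <- mcmc_config(n_iter = 4000L, burn_in = 1000L,
                                         thin = 5L, seed = scheme$seed)
  cells <- purrr::map_dfr(seq_len(scheme$n_repeats), function(r) {
    purrr::map_dfr(seq_len(scheme$n_folds), function(f) {
      valid_ids <- folds$tree_id[folds$repeat_id == r & folds$fold == f]
      masked <- data
      masked[[trait]][masked$tree_id %in% valid_ids] <- NA
      pred <- tryCatch({
        if (is_fun) {
          pr <- fitter(masked, valid_ids)
          setNames(pr$pred, pr$tree_id)[valid_ids]
        } else if (fitter %in% c("gblup", "ablup")) {
          fit <- fit_single_trait(masked, kernel, trait)
          setNames(fit$blups$ebv, fit$blups$tree_id)[valid_ids]
        } else if (fitter == "tgblup") {
          cfg <- mcmc; cfg$seed <- derive_seeds(mcmc$seed + r, f)[f]
          fit <- fit_tgblup(masked, kernel, trait, cfg)
          setNames(fit$gebv$gebv, fit$gebv$tree_id)[valid_ids]
        } else {
          cfg <- mcmc; cfg$seed <- derive_seeds(mcmc$seed + r, f)[f]
          fit <- if (fitter == "brr")
            fit_brr(masked, genotypes, trait, cfg,
                    response = if (is_ordinal(data[[trait]])) "ordinal" else "gaussian")
          else fit_bayescpi(masked, genotypes, trait, cfg,
                            response = if (is_ordinal(data[[trait]])) "ordinal" else "gaussian")
          g <- gebv_from_markers(fit, genotypes)
          setNames(g$gebv, g$tree_id)[valid_ids]
        }
      }, error = function(e) NULL)
      if (is.null(pred)) {
        return(tibble::tibble(repeat_id = r, fold = f, n_valid = length(valid_ids),
                              pa = NA_real_, pacc = NA_real_, failed = TRUE))
      }
      pa <- compute_pa(pred, ystar[valid_ids])
      tibble::tibble(repeat_id = r, fold = f, n_valid = length(valid_ids),
                     pa = pa, pacc = compute_pacc(pa, h2 %||% NA_real_),
                     failed = FALSE)
    })
  })
  structure(list(cells = cells, trait = trait,
                 fitter = if (is_fun) "custom" else fitter, h2 = h2,
                 scheme = scheme, n_fits = nrow(cells)),
            class = "spruce_cv")
}

is_ordinal <- function(y) {
  y <- y[!is.na(y)]
  length(y) > 0 && all(y == round(y)) && length(unique(y)) <= 6
}

#' @export
print.spruce_cv <- function(x, ...) {
  g <- glance(x)
  cat("<spruce_cv>", x$fitter, "|", x$trait, "|", x$n_fits, "fits | mean PA =",
      round(g$mean_pa, 3), "| mean PACC =", round(g$mean_pacc, 3), "\n")
  invisible(x)
}

#' Multi-trait missing-data experiment
#'
#' Measures how much genetically correlated indicator traits rescue the
#' prediction of a target trait whose phenotypes are increasingly missing.
#' The trees are first partitioned into family-stratified validation folds;
#' each replicate holds out one fold (cycling over folds) for all traits and
#' then masks a fraction of the remaining training trees' target records at
#' random. Single-trait GBLUP and each multi-trait GBLUP variant (target
#' plus the given indicator sets) are solved on the observed cells and the
#' target's PA/PACC is computed on the held-out trees. Variance components
#' are estimated per model per fold on that fold's training trees only
#' (warm-started from a full-data fit), so the validation trees never
#' influence the estimated genetic correlations, and are then held fixed
#' across masking fractions and replicates of that fold: masking is
#' completely at random, so the components are unchanged in expectation and
#' each replicate re-solves the prediction equations only.
#'
#' @param adjusted Tibble of adjusted phenotypes with `tree_id`, `family`
#'   and trait columns (from [adjust_phenotypes()]).
#' @param kernel Relationship matrix (usually G).
#' @param target Target trait column.
#' @param indicator_sets Named list of character vectors of indicator
#'   traits; each defines one multi-trait model.
#' @param fractions Missing-data fractions in `[0, 1)`.
#' @param n_replicates Replicates per fraction.
#' @param h2 Heritability for PACC (full-data single-trait GBLUP estimate).
#' @param validation_fraction Held-out share per replicate.
#' @param seed Integer seed.
#' @return A `spruce_missing_experiment`; `tidy()` gives the per-replicate
#'   grid, `glance()` fraction x model means and SEs, `autoplot()` the
#'   accuracy-versus-missingness curves.
#' @export
run_missing_data_experiment <- function(adjusted, kernel, target,
                                        indicator_sets,
                                        fractions = c(0, 0.4, 0.9),
                                        n_replicates = 20L,
                                        h2 = NULL,
                                        validation_fraction = 0.1,
                                        seed = 1L) {
  stopifnot(all(fractions >= 0), all(c("tree_id", "family", target) %in%
                                       names(adjusted)))
  if (any(fractions >= 1)) stop("missing fraction must be < 1", call. = FALSE)
  for (s in indicator_sets) {
    if (anyNA(adjusted[, s])) stop("indicator traits must be fully observed",
                                   call. = FALSE)
  }
  ids <- adjusted$tree_id
  K <- kernel
  models <- c(list(single = character(0)), indicator_sets)
  # full-data fits provide starting values for the per-fold REML refits
  start_of <- lapply(models, function(ind) {
    trs <- c(target, ind)
    f <- suppressWarnings(fit_multitrait_gblup(adjusted, K, trs))
    p <- length(trs)
    mean_cor <- function(M) if (p > 1) mean(cov2cor(M)[upper.tri(M)]) else 0
    list(A = list(var = diag(f$VA), cor = max(min(mean_cor(f$VA), 0.98), -0.98)),
         R = list(var = diag(f$VR), cor = max(min(mean_cor(f$VR), 0.98), -0.98)))
  })
  ystar_target <- setNames(adjusted[[target]], ids)
  n_folds_v <- max(2L, round(1 / validation_fraction))
  folds <- make_folds(adjusted, cv_scheme(n_folds = n_folds_v, n_repeats = 1L,
                                          seed = seed))
  used_folds <- ((seq_len(n_replicates) - 1L) %% n_folds_v) + 1L
  # per-fold, per-model components estimated on the training trees only
  comp <- list()
  for (f in unique(used_folds)) {
    valid_ids <- folds$tree_id[folds$fold == f]
    Ytr <- adjusted
    for (tr in unique(unlist(c(target, indicator_sets)))) {
      Ytr[[tr]][Ytr$tree_id %in% valid_ids] <- NA
    }
    comp[[f]] <- lapply(names(models), function(mn) {
      trs <- c(target, models[[mn]])
      ft <- suppressWarnings(
        fit_multitrait_gblup(Ytr, K, trs, start = start_of[[mn]]))
      list(A = ft$VA, R = ft$VR, traits = trs)
    })
    names(comp[[f]]) <- names(models)
  }
  seeds <- derive_seeds(seed, n_replicates)
  grid <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    f <- used_folds[rep_i]
    valid_ids <- folds$tree_id[folds$fold == f]
    train_ids <- setdiff(ids, valid_ids)
    purrr::map_dfr(fractions, function(fr) {
      mask_ids <- with_seed((seeds[rep_i] + round(fr * 1000)) %% 2147483629, {
        sample(train_ids, floor(fr * length(train_ids)))
      })
      purrr::map_dfr(names(models), function(mn) {
        cm <- comp[[f]][[mn]]
        trs <- cm$traits
        Y <- adjusted
        Y[[target]][Y$tree_id %in% c(valid_ids, mask_ids)] <- NA
        for (tr in setdiff(trs, target)) {
          Y[[tr]][Y$tree_id %in% valid_ids] <- NA
        }
        fit <- fit_multitrait_gblup(Y, K, trs,
                                    varcomp = list(A = cm$A, R = cm$R))
        pred <- setNames(fit$gebv[[target]], fit$gebv$tree_id)[valid_ids]
        pa <- compute_pa(pred, ystar_target[valid_ids])
        tibble::tibble(model = mn, fraction = fr, replicate = rep_i,
                       fold = f, pa = pa,
                       pacc = compute_pacc(pa, h2 %||% NA_real_))
      })
    })
  })
  structure(list(grid = grid, target = target, h2 = h2,
                 models = names(models), fractions = fractions),
            class = "spruce_missing_experiment")
}

#' @export
print.spruce_missing_experiment <- function(x, ...) {
  cat("<spruce_missing_experiment> target:", x$target, "| models:",
      paste(x$models, collapse = ", "), "\n")
  print(glance(x), n = 50)
  invisible(x)
}
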