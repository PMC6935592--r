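test_that("genetic-parameter arithmetic follows the heritability and type-B definitions", {
  fit <- structure(list(
    varcomp = c(s2_b = 2, s2_a = 3, s2_sa = 1, s2_e = 6),
    vcov_varcomp = matrix(0, 4, 4,
                          dimnames = list(c("s2_b", "s2_a", "s2_sa", "s2_e"),
                                          c("s2_b", "s2_a", "s2_sa", "s2_e")))),
    class = "spruce_fit")
  gp <- estimate_genetic_params(fit)
  expect_equal(gp$h2, 0.3)
  expect_equal(gp$rB, 0.75)
  fit$varcomp["s2_sa"] <- 0
  expect_equal(estimate_genetic_params(fit)$rB, 1)
  fit$varcomp[] <- 0
  expect_true(is.na(estimate_genetic_params(fit)$h2))
})

test_that("BLUPs at fixed components equal an independent dense MME solve", {
  cfg <- tiny_config(n_parents = 6, n_families = 8, offspring_per_family = 4,
                     n_markers = 80)
  pop <- simulate_population(cfg, seed = 21)
  ph <- pop$phenotypes
  A <- compute_A(pop$pedigree)[ph$tree_id, ph$tree_id]
  theta <- c(s2_b = 0.1, s2_a = 0.35, s2_sa = 0.1, s2_e = 0.6)
  fit <- fit_single_trait(ph, A, "t", varcomp = theta)

  X <- model.matrix(~ site, ph)
  Zb <- model.matrix(~ 0 + factor(paste(ph$site, ph$block)))
  oracle <- mme_oracle(ph$t, X, Zb, A, ph$site, theta)
  ours <- setNames(fit$blups$ebv, fit$blups$tree_id)[ph$tree_id]
  expect_lt(max(abs(ours - oracle$a)), 1e-8)
  expect_lt(max(abs(unname(fit$fixed) - oracle$beta)), 1e-8)
})

test_that("EM-REML log-likelihood is monotone non-decreasing", {
  for (s in c(31, 32)) {
    cfg <- tiny_config(n_parents = 8, n_families = 10, offspring_per_family = 6,
                       n_markers = 100)
    pop <- simulate_population(cfg, seed = s)
    ph <- pop$phenotypes
    A <- compute_A(pop$pedigree)[ph$tree_id, ph$tree_id]
    # EM may legitimately still be crawling after 40 iterations; only the
    # monotone trajectory is under test here
    fit <- suppressWarnings(
      fit_single_trait(ph, A, "t", algorithm = "em", max_iter = 40))
    expect_true(all(diff(fit$trajectory) > -1e-8))
  }
})

test_that("REML recovers a zero additive variance at the boundary", {
  cfg <- tiny_config(h2 = 0, rB = 1, n_parents = 12, n_families = 16,
                     offspring_per_family = 12, n_markers = 150)
  pop <- simulate_population(cfg, seed = 33)
  ph <- pop$phenotypes
  G <- genomic_kernel(pop)
  fit <- fit_single_trait(ph, G, "t")
  v <- fit$varcomp
  expect_lte(v["s2_a"] / sum(v[c("s2_a", "s2_sa", "s2_e")]), 0.05)
})

test_that("heritability and type-B correlation are scale invariant", {
  cfg <- tiny_config(h2 = 0.35, rB = 0.8, n_markers = 150)
  pop <- simulate_population(cfg, seed = 34)
  ph <- pop$phenotypes
  G <- genomic_kernel(pop)
  f1 <- fit_single_trait(ph, G, "t")
  ph2 <- ph; ph2$t <- ph2$t * 37.3
  f2 <- fit_single_trait(ph2, G, "t")
  g1 <- estimate_genetic_params(f1); g2 <- estimate_genetic_params(f2)
  expect_equal(g1$h2, g2$h2, tolerance = 1e-6)
  expect_equal(g1$rB, g2$rB, tolerance = 1e-6)
})

test_that("likelihood-ratio tests truncate at the boundary and check nesting", {
  f_full <- list(loglik = -100, trait = "t", terms = c("block", "additive"))
  f_red <- list(loglik = -100, trait = "t", terms = "block")
  expect_equal(lrt_variance(f_full, f_red, df = 1), 1)
  f_red$loglik <- -100 - 3.841 / 2
  expect_equal(lrt_variance(f_full, f_red, df = 1), 0.05, tolerance = 1e-3)
  # reduced fitting better than full -> statistic truncated to zero
  f_red$loglik <- -99
  expect_equal(lrt_variance(f_full, f_red, df = 1), 1)
  f_other <- list(loglik = -90, trait = "u", terms = "block")
  expect_error(lrt_variance(f_full, f_other), "not nested")
  f_bigger <- list(loglik = -90, trait = "t",
                   terms = c("block", "additive", "site_additive"))
  expect_error(lrt_variance(f_full, f_bigger), "not nested")
})

test_that("site-by-additive LRT is conservative under the null", {
  rej <- vapply(1:20, function(s) {
    cfg <- tiny_config(h2 = 0.3, rB = 1, n_parents = 10, n_families = 14,
                       offspring_per_family = 8, n_markers = 120)
    pop <- simulate_population(cfg, seed = 100 + s)
    ph <- pop$phenotypes
    A <- compute_A(pop$pedigree)[ph$tree_id, ph$tree_id]
    full <- fit_single_trait(ph, A, "t")
    red <- fit_single_trait(ph, A, "t", drop_terms = "site_additive")
    lrt_variance(full, red, df = 1) < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.15) # 0.05 nominal; small-sample slack
})

test_that("phenotype adjustment removes site and block effects exactly", {
  cfg <- tiny_config(h2 = 0.3, rB = 0.8,
                     block_variance_fraction = 0.2)
  pop <- simulate_population(cfg, seed = 35)
  ph <- pop$phenotypes
  adj <- adjust_phenotypes(ph, "t")
  expect_lt(abs(mean(adj$t)), 1e-8)
  # single site with a single block reduces to centering
  one <- ph[ph$site == "S1" & ph$block == "B1", ]
  a1 <- adjust_phenotypes(one, "t")
  expect_equal(a1$t, one$t - mean(one$t))
  # missing phenotypes propagate
  ph$t[3] <- NA
  expect_true(is.na(adjust_phenotypes(ph, "t")$t[3]))
})

test_that("phenotype adjustment matches lme4 conditional residuals", {
  skip_if_not_installed("lme4")
  cfg <- tiny_config(h2 = 0, rB = 1, block_variance_fraction = 0.3)
  pop <- simulate_population(cfg, seed = 36)
  ph <- pop$phenotypes
  adj <- adjust_phenotypes(ph, "t")$t
  lf <- lme4::lmer(t ~ site + (1 | site:block), data = ph, REML = TRUE)
  expect_gt(cor(adj, residuals(lf)), 0.999)
  expect_lt(max(abs(adj - residuals(lf))), 0.02)
})

test_that("masked phenotypes get kernel-propagated breeding values", {
  cfg <- tiny_config(h2 = 0.5, rB = 1, n_parents = 12, n_families = 16,
                     offspring_per_family = 10, n_markers = 400)
  pop <- simulate_population(cfg, seed = 37)
  ph <- pop$phenotypes
  G <- genomic_kernel(pop)
  masked <- ph
  hide <- ph$tree_id[1:30]
  masked$t[masked$tree_id %in% hide] <- NA
  fit <- fit_single_trait(masked, G, "t")
  pred <- setNames(fit$blups$ebv, fit$blups$tree_id)[hide]
  truth <- rowMeans(pop$bv[hide, 1, ])
  expect_gt(cor(pred, truth), 0.3)
})
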