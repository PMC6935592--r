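test_that("the cumulative attack count applies the double-counting rule", {
  d <- tibble::tibble(
    wa_previous10 = c(1, 0, 0, 0, 1),
    wa_current10  = c(1, 0, 0, 1, 0),
    attack_prior15 = c(1, 0, 1, 1, 0),
    wa_current15  = c(1, 0, 1, 0, 1))
  out <- compute_cwa(d)
  # (1,1,1,1): attack before 15 already counted at age 10 -> CWA = 3
  # (0,0,1,1): new attack in the 11-14 window -> CWA = 2
  # (0,1,1,0): the prior-15 attack is the age-10 one, not re-counted -> CWA = 1
  expect_equal(out$cwa, c(3, 0, 2, 1, 2))
  expect_true(all(out$cwa %in% 0:3))
  d$wa_current10[1] <- 2
  expect_error(compute_cwa(d), "binary")
})

test_that("exhaustive CWA range stays within 0..3", {
  flags <- expand.grid(wa_previous10 = 0:1, wa_current10 = 0:1,
                       attack_prior15 = 0:1, wa_current15 = 0:1)
  out <- compute_cwa(tibble::as_tibble(flags))
  expect_true(all(out$cwa %in% 0:3))
})

test_that("the weight grid enumerates the 0.05 simplex lattice exactly once", {
  g <- enumerate_weight_grid(0.05)
  expect_equal(nrow(g), 1771)
  expect_true(all(abs(rowSums(as.matrix(g)) - 1) < 1e-12))
  expect_false(any(duplicated(g)))
  expect_equal(nrow(enumerate_weight_grid(0.5)), 10)
  expect_equal(nrow(enumerate_weight_grid(1)), 4)
  # closed form C(1/step + 3, 3) for several steps
  for (s in c(1, 0.5, 0.25, 0.2, 0.1)) {
    expect_equal(nrow(enumerate_weight_grid(s)), choose(1 / s + 3, 3))
  }
  # deterministic lexicographic order
  expect_identical(enumerate_weight_grid(0.25), enumerate_weight_grid(0.25))
  expect_equal(unlist(g[1, ]), c(w1 = 0, w2 = 0, w3 = 0, w4 = 1))
  expect_error(enumerate_weight_grid(0.3), "integer")
  expect_error(enumerate_weight_grid(0), "step")
})

test_that("selection-index values scale, sign and rank correctly", {
  set.seed(7)
  ebvs <- tibble::tibble(tree_id = sprintf("T%03d", 1:50),
                         h = rnorm(50), c = rnorm(50),
                         v = rnorm(50), d = rnorm(50))
  si_h <- compute_si(ebvs, c(h = 1, c = 0, v = 0, d = 0), negate = "c")
  expect_equal(order(-si_h$si), order(-ebvs$h))
  si_c <- compute_si(ebvs, c(h = 0, c = 1, v = 0, d = 0), negate = "c")
  expect_equal(order(-si_c$si), order(ebvs$c))  # reversed attack ranking
  # invariant to affine rescaling of the raw breeding values
  ebvs2 <- ebvs; ebvs2$h <- ebvs2$h * 12
  w <- c(h = 0.3, c = 0.6, v = 0.1, d = 0)
  expect_equal(compute_si(ebvs2, w, negate = "c")$si,
               compute_si(ebvs, w, negate = "c")$si, tolerance = 1e-12)
  expect_error(compute_si(ebvs, c(h = 0.5, c = 0.4, v = 0, d = 0)), "sum to 1")
  ebvs$v[] <- 0
  expect_error(compute_si(ebvs, w, negate = "c"), "zero-variance")
})

test_that("genetic gains honour their definitions and bounds", {
  set.seed(8)
  n <- 200
  ebvs <- tibble::tibble(tree_id = sprintf("T%03d", 1:n),
                         h = rnorm(n, 0, 2), c = rnorm(n, 0, 1))
  pm <- c(h = 100, c = 0.8)
  # selecting on a trait itself gives 100% relative gain for that trait
  g_h <- genetic_gain(ebvs, pm, trait = "h", negate = "c")
  expect_equal(g_h$rel_gain[g_h$trait == "h"], 100)
  g_c <- genetic_gain(ebvs, pm, weights = c(h = 0, c = 1), negate = "c")
  expect_equal(g_c$rel_gain[g_c$trait == "c"], 100)
  # relative gains never exceed the single-trait maximum
  for (w1 in c(0.25, 0.5, 0.75)) {
    g <- genetic_gain(ebvs, pm, weights = c(h = w1, c = 1 - w1), negate = "c")
    expect_true(all(g$rel_gain <= 100 + 1e-8))
  }
  # gains are monotone in the selected fraction
  g05 <- genetic_gain(ebvs, pm, fraction = 0.05, trait = "h", negate = "c")
  g10 <- genetic_gain(ebvs, pm, fraction = 0.10, trait = "h", negate = "c")
  expect_gte(g05$abs_gain[g05$trait == "h"], g10$abs_gain[g10$trait == "h"])
  expect_error(genetic_gain(ebvs, pm, fraction = 1.2, trait = "h"), "fraction")
})

test_that("correlated selection response follows the genetic correlations", {
  cfg <- pair_config(r_a = -0.8, h2 = c(0.4, 0.4), n_markers = 500,
                     n_parents = 14, n_families = 20, offspring_per_family = 10)
  pop <- simulate_population(cfg, seed = 65)
  ids <- offspring_ids(pop)
  ebvs <- tibble::tibble(tree_id = ids,
                         t1 = rowMeans(pop$bv[ids, 1, ]),
                         t2 = rowMeans(pop$bv[ids, 2, ]))
  pm <- c(t1 = 10, t2 = 10)
  g <- genetic_gain(ebvs, pm, weights = c(t1 = 1, t2 = 0))
  # selecting up on t1 drags t2 down through the negative correlation
  expect_gt(g$abs_gain[g$trait == "t1"], 0)
  expect_lt(g$abs_gain[g$trait == "t2"], 0)
})

test_that("the grid search finds a compromise index with positive gains", {
  cfg <- pair_config(r_a = -0.65, h2 = c(0.4, 0.4), n_markers = 400,
                     n_parents = 12, n_families = 16, offspring_per_family = 8)
  pop <- simulate_population(cfg, seed = 66)
  ids <- offspring_ids(pop)
  set.seed(9)
  ebvs <- tibble::tibble(tree_id = ids,
                         t1 = rowMeans(pop$bv[ids, 1, ]),
                         t2 = rowMeans(pop$bv[ids, 2, ]),
                         t3 = rnorm(length(ids), 0, 0.5),
                         t4 = rnorm(length(ids), 0, 0.5))
  pm <- c(t1 = 10, t2 = 5, t3 = 10, t4 = 10)
  res <- optimize_si(ebvs, pm, index_traits = c("t1", "t2", "t3", "t4"),
                     traits_to_max = c("t1", "t2"), step = 0.25,
                     negate = "t2")
  expect_equal(sum(res$weights), 1)
  best <- res$report
  expect_gt(best$rel_gain[best$trait == "t1"] +
              best$rel_gain[best$trait == "t2"], 100)
})
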