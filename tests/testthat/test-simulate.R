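test_that("partial diallel pedigree has the right shape and cross counts", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 1)
  founders <- ped[is.na(ped$sire), ]
  off <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(founders), 35)
  expect_equal(nrow(off), 40 * 18)
  expect_false(any(off$sire == off$dam))            # no selfing
  crosses <- unique(off[, c("sire", "dam")])
  expect_equal(nrow(crosses), 40)
  usage <- table(c(crosses$sire, crosses$dam))
  expect_true(all(usage >= 1))                      # every parent used
  expect_equal(mean(usage), 2 * 40 / 35, tolerance = 1e-12)
  # determinism under a fixed seed
  expect_identical(ped, simulate_pedigree(cfg, seed = 1))
  expect_false(identical(ped, simulate_pedigree(cfg, seed = 2)))
})

test_that("minimal one-family design gives full sibs; infeasible designs error", {
  cfg <- sim_config(n_parents = 4, n_families = 1, offspring_per_family = 2,
                    traits = trait_specs(name = "t", h2 = 0.3, rB = 1,
                                         site_means = list(c(0, 0)),
                                         type = "gaussian"),
                    genetic_correlation = diag(1))
  ped <- simulate_pedigree(cfg, seed = 3)
  off <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(off), 2)
  expect_equal(off$sire[1], off$sire[2])
  expect_equal(off$dam[1], off$dam[2])
  expect_error(sim_config(n_parents = 4, n_families = 7),
               "infeasible")
})

test_that("gene drop obeys Mendelian transmission", {
  # fixed parents: both dosage 2 -> offspring dosage 2; both het -> 1/4,1/2,1/4
  ped <- tibble::tibble(
    id = c("P1", "P2", sprintf("O%03d", 1:400)),
    sire = c(NA, NA, rep("P1", 400)),
    dam = c(NA, NA, rep("P2", 400)),
    family = c(NA, NA, rep("F1", 400)))
  cfg <- tiny_config(n_markers = 50)
  geno <- gene_drop_genotypes(ped, cfg, seed = 5)
  # engineer parental genotypes and re-drop deterministically through many loci
  hom <- which(geno["P1", ] == 2 & geno["P2", ] == 2)
  if (length(hom)) {
    expect_true(all(geno[-(1:2), hom] == 2))
  }
  het <- geno["P1", ] == 1 & geno["P2", ] == 1
  draws <- as.vector(geno[-(1:2), het])
  # exhaustive gamete enumeration gives {0: 1/4, 1: 1/2, 2: 1/4}
  frq <- tabulate(draws + 1L, 3L) / length(draws)
  expect_equal(frq, c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("founder allele frequencies follow the configured MAF and HWE", {
  ped <- tibble::tibble(id = sprintf("P%04d", 1:2000),
                        sire = NA_character_, dam = NA_character_,
                        family = NA_character_)
  cfg <- tiny_config(n_markers = 30, maf_range = c(0.3, 0.3))
  geno <- gene_drop_genotypes(ped, cfg, seed = 6)
  p_hat <- colMeans(geno) / 2
  # binomial sampling: se = sqrt(0.3*0.7/(2*2000)) ~ 0.0072
  expect_true(all(abs(p_hat - 0.3) < 5 * sqrt(0.3 * 0.7 / 4000)))
  h_obs <- colMeans(geno == 1)
  expect_equal(mean(h_obs), 2 * 0.3 * 0.7, tolerance = 0.02)
  expect_error(gene_drop_genotypes(ped[0, ], cfg, 1))
})

test_that("trait effects hit the target additive variance and correlations", {
  cfg <- pair_config(r_a = 0, n_markers = 400)
  pop <- simulate_population(cfg, seed = 9)
  ids <- offspring_ids(pop)
  a <- pop$bv[ids, , 1]
  # identity genetic correlation: realised BV correlation near zero
  expect_lt(abs(cor(a[, 1], a[, 2])), 0.25)
  # realised additive variance is calibrated exactly to h2
  expect_equal(unname(apply(a, 2, var)), c(0.3, 0.3), tolerance = 1e-10)
  # rB = 1 means identical breeding values at both sites
  expect_equal(pop$bv[, , 1], pop$bv[, , 2])
  expect_error(simulate_trait_effects(pop$genotypes,
                                      tiny_config(n_markers = 10, n_qtl = 50)),
               "n_qtl")
})

test_that("strong negative genetic correlations are realised across seeds", {
  devs <- vapply(1:20, function(s) {
    cfg <- pair_config(r_a = -0.9, n_markers = 600)
    pop <- simulate_population(cfg, seed = s)
    a <- pop$bv[offspring_ids(pop), , 1]
    cor(a[, 1], a[, 2])
  }, 0)
  expect_lt(abs(mean(devs) - (-0.9)), 0.05)
  expect_true(mean(abs(devs - (-0.9)) < 0.1) >= 0.9)
})

test_that("phenotype assembly respects the variance partition and thresholds", {
  # degenerate architecture: no genetics, no blocks -> phenotypic var = s2_e = 1
  cfg0 <- tiny_config(h2 = 0, rB = 1, n_parents = 20, n_families = 30,
                      offspring_per_family = 20,
                      block_variance_fraction = 0)
  pop0 <- simulate_population(cfg0, seed = 11)
  expect_equal(var(pop0$phenotypes$t), 1, tolerance = 0.15)

  # ordinal categories match the normal-CDF probabilities of the thresholds
  thr <- c(qnorm(0.45), 0.9, 1.8)
  cfg <- sim_config(n_parents = 20, n_families = 30, offspring_per_family = 25,
                    n_markers = 100,
                    traits = trait_specs(name = "cwa", h2 = 0.3, rB = 1,
                                         site_means = list(c(0, 0)),
                                         type = "ordinal"),
                    genetic_correlation = diag(1),
                    block_variance_fraction = 0,
                    ordinal_thresholds = thr)
  pop <- simulate_population(cfg, seed = 12)
  k <- pop$phenotypes$cwa
  expect_true(all(k %in% 0:3))
  p0 <- mean(k == 0)
  expect_equal(p0, 0.45, tolerance = 3 * sqrt(0.45 * 0.55 / length(k)) + 0.02)
})

test_that("realised heritability converges to the target at large n", {
  cfg <- tiny_config(h2 = 0.3, rB = 1, n_parents = 24, n_families = 40,
                     offspring_per_family = 50, n_markers = 300)
  pop <- simulate_population(cfg, seed = 13)
  ph <- pop$phenotypes
  v_bv <- var(pop$bv[ph$tree_id, 1, 1])
  # h2 denominator excludes block variance by construction
  blk <- paste(ph$site, ph$block)
  v_ph <- mean(tapply(ph$t, blk, var))
  expect_equal(v_bv / v_ph, 0.3, tolerance = 0.05)
})

test_that("pedigree-error injection corrupts records but not genotypes", {
  cfg <- tiny_config()
  pop <- simulate_population(cfg, seed = 14)
  same <- inject_pedigree_errors(pop, k = 0, seed = 1)
  expect_identical(same$pedigree, pop$pedigree)

  bad <- inject_pedigree_errors(pop, k = 5, seed = 2)
  expect_equal(nrow(bad$injected_errors), 5)
  moved <- bad$injected_errors
  expect_true(all(moved$old_family != moved$new_family))
  rows <- match(moved$tree_id, bad$pedigree$id)
  expect_equal(bad$pedigree$family[rows], moved$new_family)
  expect_identical(bad$genotypes, pop$genotypes)   # genotypes untouched
  # deterministic under the same seed
  bad2 <- inject_pedigree_errors(pop, k = 5, seed = 2)
  expect_identical(bad$injected_errors, bad2$injected_errors)
  expect_error(inject_pedigree_errors(pop, k = -1), "k")
})
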