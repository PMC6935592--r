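test_that("QC drops markers by call rate, MAF and fixation index", {
  # marker 1: call rate 3/5; marker 2: monomorphic; marker 3: all het at p=0.5
  # (F_IS = 1 - 1/0.5 = -1); marker 4: clean
  g <- cbind(m1 = c(0, 1, NA, NA, 2),
             m2 = c(0, 0, 0, 0, 0),
             m3 = c(1, 1, 1, 1, 1),
             m4 = c(0, 1, 2, 1, 0))
  rownames(g) <- paste0("i", 1:5)
  res <- qc_filter(g, call_rate_min = 0.9, maf_min = 0.005, fis_max_abs = 0.5)
  expect_equal(colnames(res$genotypes), "m4")
  rep <- res$report
  expect_equal(rep$reason[rep$marker == "m1"], "call_rate")
  expect_equal(rep$reason[rep$marker == "m2"], "maf")
  expect_equal(rep$reason[rep$marker == "m3"], "fis")
  expect_equal(rep$fis[rep$marker == "m3"], -1)
  expect_warning(qc_filter(g[, 1:2, drop = FALSE]), "all markers removed")
})

test_that("LD-kNN imputation recovers masked calls on an LD panel", {
  cfg <- tiny_config(n_parents = 16, n_families = 20, offspring_per_family = 10,
                     n_markers = 300, maf_range = c(0.1, 0.5),
                     ld_blocks = list(size = 10, flip_rate = 0.02))
  ped <- simulate_pedigree(cfg, 1)
  truth <- gene_drop_genotypes(ped, cfg, 2)
  expect_identical(impute_ld_knn(truth), truth)  # complete data untouched

  set.seed(3)
  mask <- matrix(runif(length(truth)) < 0.01, nrow(truth))
  g <- truth; g[mask] <- NA
  imp <- impute_ld_knn(g, k = 5, n_linked = 20)
  expect_false(anyNA(imp))
  acc <- mean(imp[mask] == truth[mask])
  expect_gte(acc, 0.75)

  # degenerate single-marker panel falls back to the rounded mean dosage
  g1 <- matrix(c(0, 0, 2, NA), ncol = 1,
               dimnames = list(paste0("i", 1:4), "m1"))
  expect_equal(impute_ld_knn(g1)[4, 1], 1)
})

test_that("the tabular A matrix reproduces textbook kinship values", {
  ped <- tibble::tibble(
    id = c("s", "d", "d2", "fs1", "fs2", "hs", "inb"),
    sire = c(NA, NA, NA, "s", "s", "s", "fs1"),
    dam = c(NA, NA, NA, "d", "d", "d2", "fs2"),
    family = c(NA, NA, NA, "F1", "F1", "F2", "F3"))
  A <- compute_A(ped)
  expect_equal(A["s", "fs1"], 0.5)     # parent-offspring
  expect_equal(A["fs1", "fs2"], 0.5)   # full sibs
  expect_equal(A["fs1", "hs"], 0.25)   # half sibs
  expect_equal(A["inb", "inb"], 1.25)  # offspring of a full-sib mating
  expect_true(isSymmetric(A))
  # founders only -> identity
  expect_equal(unname(compute_A(ped[1:3, ])), diag(3))
  # cycles are rejected with the ids named
  bad <- tibble::tibble(id = c("a", "b"), sire = c("b", "a"),
                        dam = c(NA, NA), family = NA_character_)
  expect_error(compute_A(bad), "cycle.*a.*b")
})

test_that("A is PSD for random valid pedigrees", {
  for (s in 1:5) {
    cfg <- tiny_config(n_parents = 8, n_families = 10, offspring_per_family = 4)
    ped <- simulate_pedigree(cfg, seed = s)
    A <- compute_A(ped)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("VanRaden G matches the hand computation and its invariances", {
  g <- matrix(c(2, 0), nrow = 1, dimnames = list("i1", c("m1", "m2")))
  G <- compute_G(g, p = c(0.5, 0.5))
  expect_equal(G[1, 1], 2)   # z = (1, -1), denominator 2 * (0.25 + 0.25) = 1

  cfg <- tiny_config(n_markers = 400)
  pop <- simulate_population(cfg, seed = 4)
  M <- pop$genotypes[offspring_ids(pop), ]
  G <- compute_G(M)
  # duplicated individual rows give identical relationship entries
  M2 <- rbind(M, dup = M[1, ])
  rownames(M2) <- c(rownames(M), "dup")
  G2 <- compute_G(M2)
  expect_equal(G2["dup", "dup"], G2[1, 1])
  expect_equal(G2["dup", 1], G2[1, 1])
  # invariance to marker order and individual permutation
  perm_m <- sample(ncol(M)); perm_i <- sample(nrow(M))
  expect_equal(compute_G(M[, perm_m]), G)
  expect_equal(compute_G(M[perm_i, ])[rownames(M), rownames(M)], G)
  expect_error(compute_G(matrix(2, 3, 4)), "monomorphic")
  expect_error(compute_G(cbind(c(0, NA, 1))), "missing")
})

test_that("G centred at sample frequencies has unit mean diagonal on unrelated individuals", {
  ped <- tibble::tibble(id = sprintf("P%03d", 1:300),
                        sire = NA_character_, dam = NA_character_,
                        family = NA_character_)
  cfg <- tiny_config(n_markers = 2000, maf_range = c(0.05, 0.5))
  geno <- gene_drop_genotypes(ped, cfg, seed = 7)
  G <- compute_G(geno)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_equal(mean(G[upper.tri(G)]), 0, tolerance = 0.01)
})

test_that("G regresses on A with slope near one for gene-dropped data", {
  cfg <- tiny_config(n_parents = 20, n_families = 28, offspring_per_family = 10,
                     n_markers = 3000)
  pop <- simulate_population(cfg, seed = 8)
  ids <- offspring_ids(pop)
  A <- compute_A(pop$pedigree)[ids, ids]
  G <- compute_G(pop$genotypes[ids, ])
  off <- upper.tri(A)
  slope <- coef(lm(G[off] ~ A[off]))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("pedigree verification flags mislabelled trees and not clean ones", {
  cfg <- tiny_config(n_parents = 20, n_families = 28, offspring_per_family = 10,
                     n_markers = 1500)
  pop <- simulate_population(cfg, seed = 9)
  ids <- offspring_ids(pop)
  A <- compute_A(pop$pedigree)[ids, ids]
  G <- compute_G(pop$genotypes[ids, ])
  # G = A exactly: perfect agreement
  v0 <- verify_pedigree(A, A)
  expect_equal(v0$pearson_r, 1)
  expect_length(v0$flagged, 0)
  # clean simulation: high correlation, no flags
  v1 <- verify_pedigree(A, G)
  expect_gte(v1$pearson_r, 0.9)
  expect_lte(length(v1$flagged), 1)
  # injected misassignments are recovered
  bad <- inject_pedigree_errors(pop, k = 6, seed = 10)
  A_bad <- compute_A(bad$pedigree)[ids, ids]
  v2 <- verify_pedigree(A_bad, G)
  expect_gte(length(intersect(v2$flagged, bad$injected_errors$tree_id)), 5)
  expect_error(verify_pedigree(A[1:2, 1:2] * NA, G[3:4, 3:4]), "fewer than two")
})
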