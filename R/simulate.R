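#' Simulate a partial-diallel pedigree
#'
#' Draws `n_families` distinct parent pairs (no selfing) from `n_parents`
#' founders such that every parent contributes to at least one cross, then
#' attaches `offspring_per_family` full-sib offspring to each family. With the
#' default design (35 parents, 40 families) each parent is crossed on average
#' 2 * 40 / 35 ~ 2.3 times, as in a typical partial diallel progeny trial.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; every stochastic operation in the package takes
#'   an explicit seed and never touches global state outside `withr`-style
#'   save/restore.
#' @return A tibble with columns `id`, `sire`, `dam`, `family` (founders have
#'   `NA` parents and family), in topological order (parents first).
#' @export
simulate_pedigree <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    np <- config$n_parents
    nf <- config$n_families
    parents <- sprintf("P%02d", seq_len(np))
    # cover every parent: random pairing of a shuffled parent list
    ord <- sample(parents)
    base <- list()
    i <- 1L
    while (i < length(ord)) {
      base[[length(base) + 1L]] <- sort(c(ord[i], ord[i + 1L]))
      i <- i + 2L
    }
    if (i == length(ord)) { # odd parent count: cross the leftover with a random mate
      mate <- sample(setdiff(parents, ord[length(ord)]), 1L)
      base[[length(base) + 1L]] <- sort(c(ord[length(ord)], mate))
    }
    crosses <- unique(do.call(rbind, base))
    if (nrow(crosses) > nf) {
      # too few families to use every parent: keep a random subset of crosses
      crosses <- crosses[seq_len(nf), , drop = FALSE]
    }
    all_pairs <- t(combn(parents, 2L))
    key <- function(m) paste(m[, 1], m[, 2], sep = "|")
    avail <- all_pairs[!(key(all_pairs) %in% key(crosses)), , drop = FALSE]
    extra <- nf - nrow(crosses)
    if (extra > 0) {
      take <- sample(nrow(avail), extra)
      crosses <- rbind(crosses, avail[take, , drop = FALSE])
    }
    crosses <- crosses[sample(nrow(crosses)), , drop = FALSE]
    fam <- sprintf("F%02d", seq_len(nf))
    off <- tibble::tibble(
      family = rep(fam, each = config$offspring_per_family),
      sire = rep(crosses[, 1], each = config$offspring_per_family),
      dam = rep(crosses[, 2], each = config$offspring_per_family)
    )
    off$id <- sprintf("T%04d", seq_len(nrow(off)))
    dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_,
                     family = NA_character_),
      off[, c("id", "sire", "dam", "family")]
    )
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder genotypes are drawn from Hardy-Weinberg proportions at each locus
#' with minor-allele frequencies uniform on `config$maf_range`; each offspring
#' then receives one uniformly sampled allele per parent per locus (loci are
#' unlinked). Optionally masks calls to `NA` at `config$missing_rate`, and can
#' generate block-LD panels (groups of near-duplicate markers) to exercise
#' LD-based imputation.
#'
#' @inheritParams simulate_pedigree
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @return Integer matrix of allele dosages in \{0, 1, 2\} (or `NA`), rows
#'   named by individual id, columns by marker id.
#' @export
gene_drop_genotypes <- function(pedigree, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), nrow(pedigree) > 0)
  with_seed(seed, {
    m <- config$n_markers
    founders <- pedigree$id[is.na(pedigree$sire)]
    offspring <- pedigree[!is.na(pedigree$sire), ]
    geno <- if (is.null(config$ld_blocks)) {
      gene_drop_unlinked(pedigree, founders, offspring, m, config$maf_range)
    } else {
      gene_drop_blocks(pedigree, founders, offspring, m, config$maf_range,
                       config$ld_blocks)
    }
    if (config$missing_rate > 0) {
      geno[matrix(runif(length(geno)) < config$missing_rate,
                  nrow = nrow(geno))] <- NA_integer_
    }
    geno
  })
}

# unlinked loci: founders from Hardy-Weinberg, one uniformly chosen allele
# per parent per locus
gene_drop_unlinked <- function(pedigree, founders, offspring, m, maf_range) {
  p <- runif(m, maf_range[1], maf_range[2])
  G_f <- matrix(rbinom(length(founders) * m, 2L, rep(p, each = length(founders))),
                nrow = length(founders), ncol = m)
  geno <- matrix(NA_integer_, nrow = nrow(pedigree), ncol = m,
                 dimnames = list(pedigree$id, sprintf("M%04d", seq_len(m))))
  geno[founders, ] <- G_f
  gamete <- function(dosage) {
    het <- dosage == 1L
    out <- as.integer(dosage == 2L)
    out[het] <- rbinom(sum(het), 1L, 0.5)
    out
  }
  for (i in seq_len(nrow(offspring))) {
    s <- geno[offspring$sire[i], ]
    d <- geno[offspring$dam[i], ]
    geno[offspring$id[i], ] <- gamete(s) + gamete(d)
  }
  geno
}

# block-LD mode: markers come in haplotype blocks of near-copies (per-locus
# copy error flip_rate) and whole blocks are transmitted without
# recombination, so strong local LD persists in the offspring; exists to
# exercise LD-based imputation
gene_drop_blocks <- function(pedigree, founders, offspring, m, maf_range, blk) {
  n_blocks <- ceiling(m / blk$size)
  block_of <- rep(seq_len(n_blocks), each = blk$size)[seq_len(m)]
  p <- runif(n_blocks, maf_range[1], maf_range[2])
  n_all <- nrow(pedigree)
  haplo <- function(base_alleles) {
    # expand per-block alleles to loci, then apply copy error
    h <- base_alleles[block_of]
    flip <- runif(m) < blk$flip_rate
    h[flip] <- 1L - h[flip]
    h
  }
  H1 <- matrix(0L, n_all, m, dimnames = list(pedigree$id, NULL))
  H2 <- H1
  for (f in founders) {
    H1[f, ] <- haplo(rbinom(n_blocks, 1L, p))
    H2[f, ] <- haplo(rbinom(n_blocks, 1L, p))
  }
  for (i in seq_len(nrow(offspring))) {
    for (hp in 1:2) {
      par <- if (hp == 1) offspring$sire[i] else offspring$dam[i]
      pick <- rbinom(n_blocks, 1L, 0.5)[block_of] == 1L
      h <- ifelse(pick, H1[par, ], H2[par, ])
      if (hp == 1) H1[offspring$id[i], ] <- h else H2[offspring$id[i], ] <- h
    }
  }
  geno <- H1 + H2
  dimnames(geno) <- list(pedigree$id, sprintf("M%04d", seq_len(m)))
  geno
}

#' Simulate correlated additive trait effects and per-site breeding values
#'
#' Per-locus effect vectors across traits are drawn from a zero-mean
#' multivariate normal with covariance proportional to the configured genetic
#' correlation matrix (all loci for the polygenic architecture, `n_qtl` loci
#' otherwise). Breeding values are dosage-weighted sums of effects, scaled so
#' the realised additive variance among offspring equals the target implied by
#' `h2`. Genotype-by-environment interaction is induced as independent
#' site-specific marker-effect deviations scaled so that
#' `s2_a / (s2_a + s2_sa)` equals the target type-B correlation, giving a
#' compound-symmetry structure of additive effects across sites.
#'
#' @inheritParams gene_drop_genotypes
#' @param genotypes Dosage matrix from [gene_drop_genotypes()] (no missing
#'   calls are needed; `NA`s are mean-imputed for the true-value bookkeeping).
#' @param offspring Character ids over which realised variances are
#'   calibrated; defaults to all rows.
#' @return A list with `bv`, an individuals x traits x sites array of true
#'   breeding values, `effects`, the scaled common marker effects, and
#'   `variances`, the realised per-trait variance partition.
#' @export
simulate_trait_effects <- function(genotypes, config, seed = 1L,
                                   offspring = rownames(genotypes)) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    m <- ncol(genotypes)
    traits <- config$traits
    p <- nrow(traits)
    vars <- sim_variances(config)
    M <- genotypes
    if (anyNA(M)) {
      mu <- colMeans(M, na.rm = TRUE)
      idx <- which(is.na(M), arr.ind = TRUE)
      M[idx] <- mu[idx[, 2]]
    }
    Z <- sweep(M, 2L, colMeans(M[offspring, , drop = FALSE]))
    C <- config$genetic_correlation
    L <- chol_psd(C)
    qtl <- if (identical(config$n_qtl, "all")) seq_len(m) else
      sort(sample(m, config$n_qtl))
    B <- matrix(0, nrow = m, ncol = p)
    B[qtl, ] <- matrix(rnorm(length(qtl) * p), ncol = p) %*% L
    raw <- Z %*% B
    sf <- vapply(seq_len(p), function(t) {
      v <- var(raw[offspring, t])
      if (vars$s2_a[t] == 0 || v == 0) 0 else sqrt(vars$s2_a[t] / v)
    }, numeric(1))
    B <- sweep(B, 2L, sf, `*`)
    a <- Z %*% B
    bv <- array(0, dim = c(nrow(genotypes), p, config$n_sites),
                dimnames = list(rownames(genotypes), traits$name,
                                paste0("S", seq_len(config$n_sites))))
    for (s in seq_len(config$n_sites)) {
      dev <- matrix(0, nrow(genotypes), p)
      for (t in seq_len(p)) {
        if (vars$s2_sa[t] > 0) {
          g <- numeric(m)
          g[qtl] <- rnorm(length(qtl))
          d <- drop(Z %*% g)
          d <- d * sqrt(vars$s2_sa[t] / var(d[match(offspring, rownames(Z))]))
          dev[, t] <- d
        }
      }
      bv[, , s] <- a + dev
    }
    list(bv = bv, effects = B, variances = vars)
  })
}

# upper-triangular factor of a PSD matrix, tolerating tiny negative eigenvalues
chol_psd <- function(C) {
  ev <- eigen(C, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(d)))
}

#' Assemble phenotypes over a randomized complete block field layout
#'
#' Offspring of each family are split evenly across sites and dealt into
#' blocks; phenotype = site mean + block deviation (i.i.d. normal within
#' site) + site-specific breeding value + residual. Ordinal traits are
#' generated by cutting the gaussian liability at the configured thresholds
#' into categories 0..K.
#'
#' @inheritParams gene_drop_genotypes
#' @param bv Breeding-value array from [simulate_trait_effects()].
#' @return A tibble with `tree_id`, `site`, `block`, `family` and one column
#'   per trait.
#' @export
assemble_phenotypes <- function(pedigree, bv, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    off <- pedigree[!is.na(pedigree$sire), ]
    vars <- sim_variances(config)
    sites <- paste0("S", seq_len(config$n_sites))
    site_of <- unlist(lapply(split(off$id, off$family), function(ids) {
      ids <- sample(ids)
      setNames(rep_len(sites, length(ids)), ids)
    }))
    names(site_of) <- sub("^F[0-9]+\\.", "", names(site_of))
    site_of <- site_of[off$id]
    blocks <- paste0("B", seq_len(config$n_blocks_per_site))
    block_of <- character(nrow(off))
    names(block_of) <- off$id
    for (s in sites) {
      ids <- off$id[site_of == s]
      block_of[ids] <- sample(rep_len(blocks, length(ids)))
    }
    blk_eff <- setNames(
      rnorm(config$n_sites * config$n_blocks_per_site, 0,
            sqrt(config$block_variance_fraction)),
      as.vector(outer(blocks, sites, function(b, s) paste(s, b, sep = ":")))
    )
    out <- tibble::tibble(tree_id = off$id, site = unname(site_of),
                          block = unname(block_of), family = off$family)
    site_idx <- match(out$site, sites)
    for (t in seq_len(nrow(config$traits))) {
      tr <- config$traits[t, ]
      mu_site <- tr$site_means[[1]][site_idx]
      g <- bv[cbind(match(out$tree_id, rownames(bv)), t, site_idx)]
      e <- rnorm(nrow(out), 0, sqrt(vars$s2_e[t]))
      b <- blk_eff[paste(out$site, out$block, sep = ":")]
      liab <- unname(mu_site + b + g + e)
      out[[tr$name]] <- if (tr$type == "ordinal") {
        findInterval(liab, config$ordinal_thresholds)
      } else liab
    }
    out
  })
}

#' Simulate a complete breeding population
#'
#' One-call wrapper running [simulate_pedigree()], [gene_drop_genotypes()],
#' [simulate_trait_effects()] and [assemble_phenotypes()] with sub-seeds
#' derived from `seed`.
#'
#' @inheritParams simulate_pedigree
#' @return An object of class `spruce_sim`: a list with `pedigree`,
#'   `genotypes`, `bv` (true breeding values), `phenotypes`, `true_params`
#'   (realised variance partition) and the `config`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  ped <- simulate_pedigree(config, seeds[1])
  geno <- gene_drop_genotypes(ped, config, seeds[2])
  eff <- simulate_trait_effects(geno, config, seeds[3],
                                offspring = ped$id[!is.na(ped$sire)])
  phe <- assemble_phenotypes(ped, eff$bv, config, seeds[4])
  structure(list(pedigree = ped, genotypes = geno, bv = eff$bv,
                 effects = eff$effects, phenotypes = phe,
                 true_params = eff$variances, config = config),
            class = "spruce_sim")
}

#' @export
print.spruce_sim <- function(x, ...) {
  cat("<spruce_sim>", sum(is.na(x$pedigree$sire)), "founders +",
      sum(!is.na(x$pedigree$sire)), "offspring;",
      ncol(x$genotypes), "markers;",
      nrow(x$config$traits), "traits\n")
  invisible(x)
}

#' Inject pedigree-record errors into a simulated population
#'
#' Reassigns the recorded family (and therefore the recorded parents) of `k`
#' random offspring to a different, randomly chosen family, while their
#' genotypes remain those transmitted by the true parents, emulating
#' mislabelled trees in a progeny trial. The corrupted ids are recorded so
#' detection power of the A-versus-G pedigree check can be measured.
#'
#' @param population A `spruce_sim`.
#' @param k Number of offspring records to corrupt.
#' @param seed Integer seed.
#' @return The population with its `pedigree` (and phenotype `family` labels)
#'   rewritten and an `injected_errors` tibble (`tree_id`, `old_family`,
#'   `new_family`).
#' @export
inject_pedigree_errors <- function(population, k, seed = 1L) {
  stopifnot(inherits(population, "spruce_sim"), k >= 0)
  off_idx <- which(!is.na(population$pedigree$sire))
  if (k > length(off_idx)) stop("k exceeds the number of offspring", call. = FALSE)
  if (k == 0) {
    population$injected_errors <-
      tibble::tibble(tree_id = character(), old_family = character(),
                     new_family = character())
    return(population)
  }
  with_seed(seed, {
    ped <- population$pedigree
    fams <- unique(ped$family[!is.na(ped$family)])
    fam_parents <- ped[!is.na(ped$family), c("sire", "dam", "family")]
    fam_parents <- fam_parents[!duplicated(fam_parents$family), ]
    pick <- sample(off_idx, k)
    old_fam <- ped$family[pick]
    new_fam <- unname(vapply(old_fam, function(f) sample(setdiff(fams, f), 1L),
                             character(1)))
    ped$family[pick] <- new_fam
    rows <- match(new_fam, fam_parents$family)
    ped$sire[pick] <- fam_parents$sire[rows]
    ped$dam[pick] <- fam_parents$dam[rows]
    population$pedigree <- ped
    population$phenotypes$family[match(ped$id[pick], population$phenotypes$tree_id)] <-
      new_fam
    population$injected_errors <- tibble::tibble(
      tree_id = ped$id[pick], old_family = old_fam, new_family = new_fam)
    population
  })
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic sub-seeds below 2^31 (double arithmetic: exact below 2^53)
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483629)
}
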