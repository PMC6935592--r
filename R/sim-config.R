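#' Trait specifications for the population simulator
#'
#' Builds the per-trait specification table used by [sim_config()]. Each trait
#' has a target narrow-sense heritability `h2` (additive variance as a fraction
#' of the within-site phenotypic variance excluding block effects), a target
#' type-B genetic correlation `rB` (correlation of additive effects across
#' sites; 1 means no genotype-by-environment rank change), per-site means on
#' the phenotype (or liability) scale, and a response type, either
#' `"gaussian"` or `"ordinal"` (a latent-liability trait cut into ordered
#' categories).
#'
#' The default set emulates a spruce progeny trial: a height-like and a
#' height/diameter-ratio-like growth trait with moderate GxE, velocity- and
#' density-like wood-quality traits with low GxE, and an ordinal cumulative
#' weevil-attack count (`cwa`) scored in \{0, 1, 2, 3\}.
#'
#' @param name,h2,rB,type Parallel vectors of trait names, heritability
#'   targets, type-B correlation targets and response types.
#' @param site_means List of numeric vectors (one per trait) of per-site means.
#' @return A tibble with one row per trait.
#' @export
trait_specs <- function(name = c("height", "ratio", "velocity", "density", "cwa"),
                        h2 = c(0.22, 0.20, 0.29, 0.26, 0.27),
                        rB = c(0.52, 0.56, 0.76, 0.76, 0.86),
                        site_means = rep(list(c(0.25, -0.25)), length(name)),
                        type = c("gaussian", "gaussian", "gaussian", "gaussian",
                                 "ordinal")) {
  stopifnot(length(h2) == length(name), length(rB) == length(name),
            length(type) == length(name), length(site_means) == length(name))
  tibble::tibble(name = name, h2 = h2, rB = rB,
                 site_means = site_means, type = type)
}

#' Default additive genetic correlation matrix for the simulated traits
#'
#' Pairwise additive correlations patterned on a weevil-affected spruce trial:
#' growth traits positively correlated with each other and with acoustic
#' velocity, and the attack count strongly negatively correlated with the
#' height/diameter ratio (about -0.9), moderately with height and velocity.
#'
#' @param traits Character vector of trait names (must match [trait_specs()]).
#' @return A symmetric positive-definite correlation matrix.
#' @export
default_genetic_correlation <- function(traits = c("height", "ratio", "velocity",
                                                   "density", "cwa")) {
  C <- diag(5)
  dimnames(C) <- list(traits, traits)
  C["height", "ratio"] <- C["ratio", "height"] <- 0.72
  C["height", "velocity"] <- C["velocity", "height"] <- 0.55
  C["height", "density"] <- C["density", "height"] <- 0.08
  C["height", "cwa"] <- C["cwa", "height"] <- -0.65
  C["ratio", "velocity"] <- C["velocity", "ratio"] <- 0.55
  C["ratio", "density"] <- C["density", "ratio"] <- 0.19
  C["ratio", "cwa"] <- C["cwa", "ratio"] <- -0.88
  C["velocity", "density"] <- C["density", "velocity"] <- 0.38
  C["velocity", "cwa"] <- C["cwa", "velocity"] <- -0.55
  C["density", "cwa"] <- C["cwa", "density"] <- -0.13
  C
}

#' Configuration for a simulated partial-diallel breeding population
#'
#' Collects all knobs of the simulator: the mating design (a partial diallel
#' over `n_parents` realising `n_families` full-sib families of
#' `offspring_per_family` trees each), the field design (`n_sites` sites with
#' `n_blocks_per_site` complete blocks), the marker panel (unlinked biallelic
#' loci with founder minor-allele frequencies drawn uniformly from
#' `maf_range`), the trait architecture ([trait_specs()] plus an additive
#' genetic correlation matrix), and nuisance settings.
#'
#' Variance bookkeeping: for every trait the variance of the sum of additive,
#' site-by-additive and residual components is 1, split so that
#' `h2 = s2_a / (s2_a + s2_sa + s2_e)` and `rB = s2_a / (s2_a + s2_sa)` hit
#' their targets; block variance is `block_variance_fraction` of that unit.
#' This mirrors how heritability and the type-B correlation are defined in the
#' downstream mixed models (block variance excluded from both denominators),
#' and requires `h2 <= rB` for every trait.
#'
#' @param n_parents,n_families,offspring_per_family Mating design counts.
#' @param n_sites,n_blocks_per_site Field design counts.
#' @param n_markers Number of unlinked SNP loci.
#' @param maf_range Range of founder minor-allele frequencies, in (0, 0.5].
#' @param traits Trait specification tibble from [trait_specs()].
#' @param genetic_correlation Symmetric PSD correlation matrix of per-locus
#'   additive effects across traits, unit diagonal.
#' @param block_variance_fraction Block variance relative to the unit
#'   additive + GxE + residual variance.
#' @param ordinal_thresholds Strictly increasing liability cut points turning
#'   an ordinal trait's liability into categories 0..length(thresholds).
#' @param n_qtl `"all"` for a polygenic architecture (every locus has an
#'   effect) or an integer number of causal loci (oligogenic).
#' @param missing_rate Fraction of genotype calls masked to NA.
#' @param ld_blocks Optional `list(size =, flip_rate =)`: markers are
#'   generated in blocks of near-copies (copy error `flip_rate`) to create
#'   strong local LD, solely to exercise LD-based imputation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_parents = 35,
                       n_families = 40,
                       offspring_per_family = 18,
                       n_sites = 2,
                       n_blocks_per_site = 5,
                       n_markers = 3914,
                       maf_range = c(0.01, 0.5),
                       traits = trait_specs(),
                       genetic_correlation = default_genetic_correlation(traits$name),
                       block_variance_fraction = 0.10,
                       ordinal_thresholds = c(-0.2, 0.9, 1.8),
                       n_qtl = "all",
                       missing_rate = 0,
                       ld_blocks = NULL) {
  stopifnot(n_parents >= 4, n_families >= 1, offspring_per_family >= 1,
            n_sites >= 1, n_blocks_per_site >= 1, n_markers >= 1)
  if (n_families > n_parents * (n_parents - 1) / 2) {
    stop("infeasible design: n_families exceeds the number of distinct crosses ",
         "of ", n_parents, " parents without selfing", call. = FALSE)
  }
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  stopifnot(all(traits$h2 >= 0), all(traits$h2 <= 1),
            all(traits$rB >= 0), all(traits$rB <= 1))
  bad <- traits$h2 > traits$rB + 1e-12
  if (any(bad)) {
    stop("h2 must not exceed rB (trait ", paste(traits$name[bad], collapse = ", "),
         "): the implied residual variance would be negative", call. = FALSE)
  }
  p <- nrow(traits)
  stopifnot(is.matrix(genetic_correlation),
            nrow(genetic_correlation) == p, ncol(genetic_correlation) == p)
  if (max(abs(genetic_correlation - t(genetic_correlation))) > 1e-10 ||
      max(abs(diag(genetic_correlation) - 1)) > 1e-10) {
    stop("genetic_correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(genetic_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("genetic_correlation is not positive semi-definite", call. = FALSE)
  }
  stopifnot(all(diff(ordinal_thresholds) > 0))
  stopifnot(block_variance_fraction >= 0, missing_rate >= 0, missing_rate < 1)
  if (!identical(n_qtl, "all")) {
    stopifnot(is.numeric(n_qtl), n_qtl >= 1)
    if (n_qtl > n_markers) stop("n_qtl exceeds n_markers", call. = FALSE)
  }
  if (any(lengths(traits$site_means) != n_sites)) {
    stop("each trait needs one site mean per site", call. = FALSE)
  }
  structure(list(
    n_parents = n_parents, n_families = n_families,
    offspring_per_family = offspring_per_family,
    n_sites = n_sites, n_blocks_per_site = n_blocks_per_site,
    n_markers = n_markers, maf_range = maf_range,
    traits = traits, genetic_correlation = genetic_correlation,
    block_variance_fraction = block_variance_fraction,
    ordinal_thresholds = ordinal_thresholds,
    n_qtl = n_qtl, missing_rate = missing_rate, ld_blocks = ld_blocks
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> partial diallel:", x$n_parents, "parents,",
      x$n_families, "families x", x$offspring_per_family, "offspring;",
      x$n_sites, "sites x", x$n_blocks_per_site, "blocks;",
      x$n_markers, "markers\n")
  cat("traits:", paste0(x$traits$name, " (h2=", x$traits$h2, ", rB=",
                        x$traits$rB, ", ", x$traits$type, ")",
                        collapse = "; "), "\n")
  invisible(x)
}

# Per-trait variance partition implied by the config (unit a + sa + e scale).
sim_variances <- function(config) {
  h2 <- config$traits$h2
  rB <- config$traits$rB
  s2_a <- h2
  s2_sa <- ifelse(rB > 0, h2 * (1 - rB) / rB, 0)
  s2_sa[h2 == 0] <- 0  # (h2, rB) cannot identify s2_sa when s2_a = 0
  s2_e <- pmax(1 - s2_a - s2_sa, 0)
  tibble::tibble(trait = config$traits$name, s2_b = config$block_variance_fraction,
                 s2_a = s2_a, s2_sa = s2_sa, s2_e = s2_e)
}
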