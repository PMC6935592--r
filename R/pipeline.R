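#' Run the full genomic-selection workflow on simulated or supplied data
#'
#' Orchestrates the analysis stages in their natural order - simulate (or
#' load) a population, SNP QC and imputation, A and G relationship matrices,
#' pedigree verification, single-trait REML fits with genetic parameters,
#' family-stratified cross-validation, and selection-index genetic gains -
#' writing each stage's tables under `outdir` together with a `manifest.txt`
#' recording the inputs, seed and timings. Heavier optional stages (bivariate
#' fits, the missing-data experiment) can be switched on via `stages`.
#'
#' @param config A [sim_config()] describing the population to simulate, or
#'   a list with elements `pedigree`, `genotypes`, `phenotypes` (file paths)
#'   to load instead.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed governing all stochastic stages.
#' @param stages Character subset of `c("qc", "relate", "verify", "fit",
#'   "cv", "select", "bivariate", "missing")`.
#' @param cv_scheme A [cv_scheme()] for the CV stage.
#' @param select_weights Named weight vector for the gain report (names must
#'   be trait columns); defaults to an index emphasising the ordinal attack
#'   trait when present.
#' @return (Invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = 1L,
                         stages = c("qc", "relate", "verify", "fit", "cv",
                                    "select"),
                         cv_scheme = spruceGS::cv_scheme(n_folds = 10L,
                                                         n_repeats = 2L,
                                                         seed = seed),
                         select_weights = NULL) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(sprintf("seed: %d", seed),
                sprintf("stages: %s", paste(stages, collapse = ", ")))
  log_stage <- function(name) {
    manifest <<- c(manifest, sprintf("%s: done at +%.1fs", name,
                                     as.numeric(Sys.time() - t0, units = "secs")))
  }
  is_files <- !inherits(config, "sim_config")
  if (is_files) {
    stopifnot(all(c("pedigree", "genotypes", "phenotypes") %in% names(config)))
    ped <- read_pedigree(config$pedigree)
    geno <- read_genotypes(config$genotypes)
    phe <- read_phenotypes(config$phenotypes)
    traits <- setdiff(names(phe), c("tree_id", "site", "block", "family"))
    pop <- list(pedigree = ped, genotypes = geno, phenotypes = phe)
    manifest <- c(manifest, paste("inputs:", paste(unlist(config), collapse = ", ")))
  } else {
    pop <- simulate_population(config, seed)
    traits <- config$traits$name
    write_pedigree(pop$pedigree, file.path(outdir, "pedigree.csv"))
    write_phenotypes(pop$phenotypes, file.path(outdir, "phenotypes.csv"))
    manifest <- c(manifest, "inputs: simulated population")
  }
  log_stage("load")
  out <- list(population = pop)

  geno <- pop$genotypes
  if ("qc" %in% stages) {
    qc <- qc_filter(geno)
    geno <- impute_ld_knn(qc$genotypes)
    write_qc_report(qc$report, file.path(outdir, "qc_report.tsv"))
    out$qc <- qc
    log_stage("qc")
  } else if (anyNA(geno)) {
    geno <- impute_ld_knn(geno)
  }
  phe <- pop$phenotypes
  offspring_ids <- phe$tree_id

  if (any(c("relate", "verify", "fit", "cv", "select") %in% stages)) {
    A <- compute_A(pop$pedigree)[offspring_ids, offspring_ids]
    G <- compute_G(geno[offspring_ids, , drop = FALSE])
    write_relationship(A, file.path(outdir, "A_matrix.csv"))
    write_relationship(G, file.path(outdir, "G_matrix.csv"))
    out$A <- A; out$G <- G
    log_stage("relate")
  }
  if ("verify" %in% stages) {
    v <- verify_pedigree(out$A, out$G)
    utils::write.table(v$discordance, file.path(outdir, "pedigree_check.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, sprintf("pedigree check: r = %.4f, %d flagged",
                                    v$pearson_r, length(v$flagged)))
    out$verify <- v
    log_stage("verify")
  }
  if ("fit" %in% stages) {
    fits <- lapply(setNames(traits, traits), function(tr) {
      fit_single_trait(phe, out$G, tr)
    })
    params <- dplyr::bind_rows(lapply(fits, glance))
    vc <- dplyr::bind_rows(lapply(names(fits), function(tr) {
      dplyr::mutate(tidy(fits[[tr]]), trait = tr, .before = 1)
    }))
    utils::write.table(vc, file.path(outdir, "variance_components.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(params, file.path(outdir, "genetic_parameters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ebvs <- Reduce(function(a, b) dplyr::left_join(a, b, by = "tree_id"),
                   lapply(names(fits), function(tr) {
                     setNames(fits[[tr]]$blups, c("tree_id", tr))
                   }))
    ebvs <- ebvs[ebvs$tree_id %in% offspring_ids, ]
    utils::write.csv(ebvs, file.path(outdir, "gebv.csv"), row.names = FALSE,
                     quote = FALSE)
    out$fits <- fits; out$ebvs <- ebvs
    log_stage("fit")
  }
  if ("cv" %in% stages) {
    cvres <- lapply(setNames(traits, traits), function(tr) {
      cross_validate(phe, tr, fitter = "gblup", kernel = out$G,
                     scheme = cv_scheme,
                     h2 = if (!is.null(out$fits))
                       estimate_genetic_params(out$fits[[tr]])$h2)
    })
    cv_tab <- dplyr::bind_rows(lapply(names(cvres), function(tr) {
      dplyr::mutate(tidy(cvres[[tr]]), trait = tr, .before = 1)
    }))
    cv_sum <- dplyr::bind_rows(lapply(cvres, glance))
    utils::write.table(cv_tab, file.path(outdir, "cv_cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cv_sum, file.path(outdir, "cv_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$cv <- cvres
    log_stage("cv")
  }
  if ("select" %in% stages && !is.null(out$ebvs)) {
    pm <- vapply(traits, function(tr) mean(phe[[tr]], na.rm = TRUE), 0)
    # an all-zero or negative mean cannot serve as a percentage denominator
    usable <- traits[abs(pm[traits]) > 1e-8]
    neg <- intersect("cwa", usable)
    if (is.null(select_weights)) {
      w_traits <- head(usable, 4)
      select_weights <- setNames(rep(1 / length(w_traits), length(w_traits)),
                                 w_traits)
    }
    gr <- genetic_gain(out$ebvs[, c("tree_id", usable)], pm[usable],
                       weights = select_weights, negate = neg)
    utils::write.table(gr, file.path(outdir, "gain_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$gains <- gr
    log_stage("select")
  }
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(out)
}
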