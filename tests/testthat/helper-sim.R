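# Shared fixture builders: all data used by the tests is generated in code.

# small partial diallel with one gaussian trait
tiny_config <- function(h2 = 0.4, rB = 1, n_markers = 200,
                        n_parents = 10, n_families = 12,
                        offspring_per_family = 8, n_sites = 2,
                        type = "gaussian", ...) {
  sim_config(
    n_parents = n_parents, n_families = n_families,
    offspring_per_family = offspring_per_family,
    n_sites = n_sites, n_blocks_per_site = 3, n_markers = n_markers,
    traits = trait_specs(name = "t", h2 = h2, rB = rB,
                         site_means = list(rep(0, n_sites)), type = type),
    genetic_correlation = diag(1), ...)
}

# two gaussian traits with a chosen additive correlation
pair_config <- function(r_a, h2 = c(0.3, 0.3), rB = c(1, 1),
                        n_markers = 1000, ...) {
  C <- matrix(c(1, r_a, r_a, 1), 2, dimnames = list(c("t1", "t2"),
                                                    c("t1", "t2")))
  sim_config(
    n_markers = n_markers,
    traits = trait_specs(name = c("t1", "t2"), h2 = h2, rB = rB,
                         site_means = rep(list(c(0, 0)), 2),
                         type = c("gaussian", "gaussian")),
    genetic_correlation = C, ...)
}

offspring_ids <- function(pop) pop$phenotypes$tree_id

genomic_kernel <- function(pop) {
  compute_G(pop$genotypes[offspring_ids(pop), , drop = FALSE])
}
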