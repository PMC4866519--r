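# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so expected values frozen in the tests are reproducible.

make_sim <- function(n_samples = 120, n_variants = 50, n_phenotypes = 10,
                     effects = data.frame(phenotype = integer(),
                                          variant = integer(),
                                          slope = numeric()),
                     ld_rho = 0, noise_sd = 1, n_covariates = 0L,
                     covariate_sd = 0, seed = 101, ...) {
  cfg <- sim_config(n_samples = n_samples, n_variants = n_variants,
                    n_phenotypes = n_phenotypes, effects = effects,
                    ld_rho = ld_rho, noise_sd = noise_sd,
                    n_covariates = n_covariates, covariate_sd = covariate_sd,
                    seed = seed, ...)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, g = g, p = sim$phenotypes, cov = sim$covariates,
       truth = sim$truth)
}

# Write a minimal hand-rolled VCF; `rows` are pre-formatted data lines.
write_toy_vcf <- function(path, samples, rows, format = "GT") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

toy_row <- function(chrom, pos, id, format, cells) {
  paste(c(chrom, pos, id, "A", "G", ".", "PASS", ".", format, cells),
        collapse = "\t")
}
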