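#' Configuration for the synthetic QTL data generator
#'
#' Collects the knobs of the generator used throughout the test surface:
#' sample and variant counts, the minor-allele-frequency range, the AR(1)
#' latent correlation controlling linkage disequilibrium, the phenotype
#' count, a table of planted effects, the residual noise level and optional
#' covariates.
#'
#' @param n_samples Number of samples N.
#' @param n_variants Number of variant sites L.
#' @param maf_range Minor allele frequencies are drawn uniformly from this
#'   interval.
#' @param ld_rho AR(1) correlation of the latent Gaussian haplotype process
#'   across adjacent variants, in `[0, 1)`; 0 gives independent variants.
#' @param n_phenotypes Number of phenotypes; those absent from `effects` are
#'   pure noise (null).
#' @param effects Data frame with columns `phenotype` (index), `variant`
#'   (index) and `slope`: each row plants `slope * dosage` into one
#'   phenotype.
#' @param noise_sd Standard deviation of the Gaussian phenotype noise.
#' @param n_covariates Number of standard-normal covariates to simulate.
#' @param covariate_sd Standard deviation of the per-phenotype covariate
#'   loadings (0 disables covariate effects on phenotypes).
#' @param chrom Chromosome name used in all coordinates.
#' @param pos_start Position of the first variant (1-based).
#' @param spacing Base pairs between adjacent variants.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_variants = 200L,
                       maf_range = c(0.05, 0.5), ld_rho = 0,
                       n_phenotypes = 20L,
                       effects = data.frame(phenotype = integer(),
                                            variant = integer(),
                                            slope = numeric()),
                       noise_sd = 1, n_covariates = 0L, covariate_sd = 0,
                       chrom = "1", pos_start = 100000L, spacing = 5000L,
                       seed = 1L) {
  stopifnot(ld_rho >= 0, ld_rho < 1,
            all(effects$variant >= 1), all(effects$variant <= n_variants),
            all(effects$phenotype >= 1), all(effects$phenotype <= n_phenotypes))
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, ld_rho = ld_rho,
                 n_phenotypes = as.integer(n_phenotypes), effects = effects,
                 noise_sd = noise_sd, n_covariates = as.integer(n_covariates),
                 covariate_sd = covariate_sd, chrom = chrom,
                 pos_start = as.integer(pos_start),
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "sim_config")
}

ar1_matrix <- function(L, N, rho) {
  z <- matrix(stats::rnorm(L * N), nrow = L)
  if (rho > 0 && L > 1) {
    s <- sqrt(1 - rho^2)
    for (i in 2:L) z[i, ] <- rho * z[i - 1, ] + s * z[i, ]
  }
  z
}

#' Simulate a genotype dosage matrix with tunable LD
#'
#' Two latent Gaussian AR(1) haplotype processes run across the variant
#' index with correlation `ld_rho`; each is thresholded at the quantile
#' implied by the variant's target minor allele frequency, and the two
#' resulting allele indicators are summed into a 0/1/2 dosage
#' (Hardy-Weinberg by construction). Adjacent-variant dosage correlation
#' grows with `ld_rho`. Positions are evenly spaced.
#'
#' @param cfg A [sim_config()].
#' @return A `dosage_matrix` (monomorphic draws are dropped, as the readers
#'   would drop them).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$n_variants; N <- cfg$n_samples
  maf <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  thr <- stats::qnorm(1 - maf)
  h1 <- ar1_matrix(L, N, cfg$ld_rho)
  h2 <- ar1_matrix(L, N, cfg$ld_rho)
  dos <- (h1 > thr) + (h2 > thr)
  storage.mode(dos) <- "double"
  ids <- sprintf("var%04d", seq_len(L))
  pos <- cfg$pos_start + (seq_len(L) - 1L) * cfg$spacing
  keep <- apply(dos, 1, function(x) stats::var(x) > 0)
  out <- list(chrom = cfg$chrom, variant_ids = ids[keep],
              positions = pos[keep],
              dosages = dos[keep, , drop = FALSE],
              sample_ids = sprintf("S%03d", seq_len(N)),
              n_monomorphic = sum(!keep), n_below_maf = 0L,
              target_maf = maf[keep])
  dimnames(out$dosages) <- list(out$variant_ids, out$sample_ids)
  class(out) <- "dosage_matrix"
  out
}

#' Simulate phenotypes with planted cis effects
#'
#' Each phenotype is `sum(slope * dosage)` over its planted effects plus
#' covariate contributions plus Gaussian noise; phenotypes without effects
#' are pure noise. Anchors are placed at the planted variant's position
#' (center of the variant span for null phenotypes), so every planted
#' variant lies inside the default cis-window.
#'
#' @param g A `dosage_matrix` from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return List with `phenotypes` (a `phenotype_set`), `covariates` (a
#'   `covariate_matrix` or NULL), and `truth` (the effects table with
#'   variant ids resolved).
#' @export
simulate_phenotypes <- function(g, cfg) {
  set.seed(cfg$seed + 1L)
  N <- length(g$sample_ids)
  P <- cfg$n_phenotypes
  vals <- matrix(stats::rnorm(P * N, sd = cfg$noise_sd), nrow = P)

  cov <- NULL
  if (cfg$n_covariates > 0L) {
    cv <- matrix(stats::rnorm(cfg$n_covariates * N), nrow = cfg$n_covariates)
    rownames(cv) <- sprintf("cov%02d", seq_len(cfg$n_covariates))
    colnames(cv) <- g$sample_ids
    cov <- structure(list(covariate_ids = rownames(cv), values = cv,
                          sample_ids = g$sample_ids),
                     class = "covariate_matrix")
    if (cfg$covariate_sd > 0) {
      load <- matrix(stats::rnorm(P * cfg$n_covariates, sd = cfg$covariate_sd),
                     nrow = P)
      vals <- vals + load %*% cv
    }
  }

  mid <- g$positions[ceiling(length(g$positions) / 2)]
  anchor <- rep(mid, P)
  eff <- cfg$effects
  if (nrow(eff) > 0L) {
    for (i in seq_len(nrow(eff))) {
      v <- eff$variant[i]
      if (v > length(g$variant_ids))
        stop("planted effect references variant ", v,
             " but only ", length(g$variant_ids), " polymorphic variants exist")
      vals[eff$phenotype[i], ] <- vals[eff$phenotype[i], ] +
        eff$slope[i] * g$dosages[v, ]
      anchor[eff$phenotype[i]] <- g$positions[v]
    }
    eff$variant_id <- g$variant_ids[eff$variant]
  }

  ids <- sprintf("pheno%03d", seq_len(P))
  dimnames(vals) <- list(ids, g$sample_ids)
  p <- structure(list(phenotype_ids = ids, chrom = rep(g$chrom, P),
                      start = as.integer(anchor - 1L),
                      end = as.integer(anchor),
                      anchor = as.integer(anchor), values = vals,
                      sample_ids = g$sample_ids),
                 class = "phenotype_set")
  list(phenotypes = p, covariates = cov, truth = eff)
}

#' Write a simulated dataset to VCF / BED / covariate files
#'
#' Emits the standard file formats the readers consume: a VCF 4.2 with both
#' `GT` and `DS` fields, a BED with the `#chr start end id sample...` header,
#' and (when covariates are present) a whitespace-separated covariate table.
#' With `bgzip = TRUE` the VCF and BED are bgzip-compressed and
#' Tabix-indexed via Rsamtools, enabling region queries.
#'
#' @param g A `dosage_matrix`.
#' @param p A `phenotype_set`.
#' @param cov A `covariate_matrix` or NULL.
#' @param dir Output directory (created if absent).
#' @param bgzip Compress and index the VCF and BED.
#' @return Named list of file paths (`vcf`, `bed`, `cov`).
#' @export
write_fixture <- function(g, p, cov = NULL, dir, bgzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  bed <- file.path(dir, "phenotypes.bed")

  gt_code <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  rows <- vapply(seq_along(g$variant_ids), function(i) {
    d <- g$dosages[i, ]
    di <- as.integer(round(pmin(pmax(d, 0), 2)))
    cells <- paste0(gt_code[di + 1L], ":", fmt_num(d))
    paste(c(g$chrom, g$positions[i], g$variant_ids[i], "A", "G", ".", "PASS",
            ".", "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), vcf)

  bhdr <- paste(c("#chr", "start", "end", "id", p$sample_ids), collapse = "\t")
  # tabix requires coordinate-sorted rows
  brows <- vapply(order(p$chrom, p$start, p$phenotype_ids), function(i) {
    paste(c(p$chrom[i], p$start[i], p$end[i], p$phenotype_ids[i],
            sprintf("%.17g", p$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(bhdr, brows), bed)

  cov_path <- NULL
  if (!is.null(cov)) {
    cov_path <- file.path(dir, "covariates.txt")
    chdr <- paste(c("id", cov$sample_ids), collapse = "\t")
    crows <- vapply(seq_along(cov$covariate_ids), function(i) {
      paste(c(cov$covariate_ids[i], sprintf("%.17g", cov$values[i, ])),
            collapse = "\t")
    }, character(1))
    writeLines(c(chdr, crows), cov_path)
  }

  if (bgzip) {
    vcf_gz <- Rsamtools::bgzip(vcf, dest = paste0(vcf, ".gz"), overwrite = TRUE)
    Rsamtools::indexTabix(vcf_gz, format = "vcf")
    bed_gz <- Rsamtools::bgzip(bed, dest = paste0(bed, ".gz"), overwrite = TRUE)
    Rsamtools::indexTabix(bed_gz, format = "bed", comment = "#")
    file.remove(vcf, bed)
    vcf <- vcf_gz; bed <- bed_gz
  }
  list(vcf = vcf, bed = bed, cov = cov_path)
}
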