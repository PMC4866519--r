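#' Partition phenotypes into non-overlapping chunks
#'
#' Orders phenotypes by genomic coordinate and splits them into `total`
#' contiguous groups of near-equal size (the first `m %% total` groups take
#' the extra phenotype), so a genome-wide run can be distributed across
#' processes and the per-chunk outputs concatenated. Phenotypes sharing an
#' anchor coordinate are kept in the same chunk. Deterministic.
#'
#' @param p A `phenotype_set` (only ids, chromosomes and anchors are used).
#' @param total Number of chunks (>= 1).
#' @return List of `total` character vectors of phenotype ids; empty groups
#'   are allowed when `total` exceeds the phenotype count.
#' @export
plan_chunks <- function(p, total) {
  stopifnot(total >= 1)
  m <- length(p$phenotype_ids)
  ord <- order(p$chrom, p$anchor, p$phenotype_ids)
  ids <- p$phenotype_ids[ord]
  key <- paste(p$chrom[ord], p$anchor[ord])

  sizes <- rep(m %/% total, total)
  extra <- m %% total
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(sizes)

  groups <- vector("list", total)
  taken <- 0L
  for (k in seq_len(total)) {
    if (taken >= m) { groups[[k]] <- character(0); next }
    cut <- bounds[k]
    # grow the cut so phenotypes sharing an anchor stay together
    while (cut < m && cut > taken && key[cut + 1L] == key[cut]) cut <- cut + 1L
    if (k == total) cut <- m
    groups[[k]] <- ids[(taken + 1L):cut]
    taken <- cut
  }
  groups
}

#' Map cis-QTLs from genotype and phenotype files
#'
#' The main fitting function. Reads genotype dosages (VCF), phenotype
#' quantifications (BED) and optional covariates, aligns samples, and for
#' each phenotype scans all variants within `window` of its anchor for the
#' strongest Pearson correlation, correcting the best nominal P-value for
#' the correlated variants tested with the chosen permutation scheme (see
#' [full_permutation_pass()]). Phenotype-level significance across the whole
#' set is then assessed with [qtl_fdr()].
#'
#' Exactly one scope may be active: the whole file (default), a genomic
#' `region`, or `chunk = c(i, n)` meaning the i-th of `n` coordinate-ordered
#' phenotype chunks. Genotypes are fetched only for the span the selected
#' phenotypes' cis-windows cover. Per-phenotype RNG substreams make chunked
#' and whole runs row-identical.
#'
#' @param vcf Path to the genotype VCF (`.vcf` or bgzipped+indexed
#'   `.vcf.gz`).
#' @param bed Path to the phenotype BED.
#' @param cov Optional path to a covariate table, or a `covariate_matrix`.
#' @param region Optional `"chr:start-end"` restriction on phenotype
#'   anchors.
#' @param chunk Optional `c(index, total)` pair.
#' @param window Cis-window half-width in bp (default 1e6, i.e. +/- 1 Mb).
#' @param scheme Permutation scheme: `"beta"` (default), `"direct"`,
#'   `"adaptive"`.
#' @param permutations `R` for the direct/beta schemes (default 1000).
#' @param B,M Adaptive-scheme exceedance target and permutation cap.
#' @param seed Run seed (default 1).
#' @param normalize Rank-based inverse normal transform of each phenotype.
#' @param maf_min Minor-allele-frequency filter for variants (default 0).
#' @param missing_policy Missing-genotype handling, see
#'   [read_genotype_region()].
#' @param df_policy Degrees-of-freedom accounting, see [nominal_pass()].
#' @param verbose Print progress messages.
#' @return An object of class `qtl_map`: `results` (ten-column data frame,
#'   one row per phenotype), `scheme`, `window`, `n_samples`,
#'   `n_variants_loaded`, `seed`, `call`, plus sample-intersection and
#'   filter bookkeeping.
#' @export
qtl_map <- function(vcf, bed, cov = NULL, region = NULL, chunk = NULL,
                    window = 1e6, scheme = c("beta", "direct", "adaptive"),
                    permutations = 1000L, B = 100L, M = 100000L, seed = 1L,
                    normalize = FALSE, maf_min = 0,
                    missing_policy = c("mean", "drop_sample"),
                    df_policy = c("adjusted", "legacy"), verbose = FALSE) {
  scheme <- match.arg(scheme)
  missing_policy <- match.arg(missing_policy)
  df_policy <- match.arg(df_policy)
  if (!is.null(region) && !is.null(chunk))
    stop("give either a region or a chunk, not both")
  if (!is.null(chunk)) {
    if (length(chunk) != 2L || chunk[1] < 1 || chunk[1] > chunk[2])
      stop("chunk must be c(index, total) with 1 <= index <= total")
  }

  p <- read_phenotype_bed(bed, region = region)
  if (!is.null(chunk)) {
    keep_ids <- plan_chunks(p, chunk[2])[[chunk[1]]]
    sel <- p$phenotype_ids %in% keep_ids
    p$phenotype_ids <- p$phenotype_ids[sel]
    p$chrom <- p$chrom[sel]; p$start <- p$start[sel]; p$end <- p$end[sel]
    p$anchor <- p$anchor[sel]
    p$values <- p$values[sel, , drop = FALSE]
  }
  empty <- length(p$phenotype_ids) == 0L

  if (empty) {
    results <- scheme_fields(na_scan("drop"))[0, ]
    g <- NULL; inter <- NULL
  } else {
    g_region <- sprintf("%s:%d-%d", p$chrom[1],
                        max(1L, min(p$anchor) - as.integer(window)),
                        max(p$anchor) + as.integer(window))
    g <- read_genotype_region(vcf, region = g_region, maf_min = maf_min,
                              missing_policy = missing_policy)
    if (is.character(cov)) cov <- read_covariates(cov)
    inter <- intersect_samples(g, p, cov)
    if (verbose)
      message(sprintf(
        "%d phenotypes, %d variants, %d samples (%d dropped in intersection)",
        length(p$phenotype_ids), length(g$variant_ids),
        length(inter$genotypes$sample_ids), inter$n_dropped))
    t0 <- proc.time()[3]
    results <- full_permutation_pass(inter$phenotypes, inter$genotypes,
                                     window = window, scheme = scheme,
                                     R = permutations, B = B, M = M,
                                     seed = seed, cov = inter$covariates,
                                     normalize = normalize,
                                     df_policy = df_policy)
    if (verbose)
      message(sprintf("permutation pass done in %.1f s", proc.time()[3] - t0))
  }

  structure(list(results = results, scheme = scheme, window = window,
                 permutations = if (scheme == "adaptive") c(B = B, M = M)
                                else c(R = permutations),
                 seed = seed, normalize = normalize,
                 n_samples = if (empty) 0L else length(inter$genotypes$sample_ids),
                 n_variants_loaded = if (empty) 0L else length(g$variant_ids),
                 n_monomorphic = if (empty) 0L else g$n_monomorphic,
                 n_samples_dropped = if (empty) 0L else inter$n_dropped,
                 call = match.call()),
            class = "qtl_map")
}

#' @export
print.qtl_map <- function(x, ...) {
  cat("cis-QTL scan (", x$scheme, " permutation scheme)\n", sep = "")
  cat(sprintf("  %d phenotype(s), %d variant(s) loaded, %d sample(s)\n",
              nrow(x$results), x$n_variants_loaded, x$n_samples))
  cat(sprintf("  cis-window: +/- %s bp; seed %d; permutations: %s\n",
              format(x$window, big.mark = ",", scientific = FALSE), x$seed,
              paste(names(x$permutations), x$permutations, sep = "=",
                    collapse = " ")))
  if (nrow(x$results) > 0L) {
    p <- if (x$scheme == "beta") x$results$beta_perm_p else x$results$direct_perm_p
    cat(sprintf("  smallest adjusted P: %.3g\n", suppressWarnings(min(p, na.rm = TRUE))))
  }
  invisible(x)
}

#' @method summary qtl_map
#' @export
summary.qtl_map <- function(object, fdr = 0.05, ...) {
  res <- object$results
  out <- list(fit = object, fdr = NULL)
  if (nrow(res) > 0L && any(!is.na(res$direct_perm_p) | !is.na(res$beta_perm_p)))
    out$fdr <- suppressWarnings(qtl_fdr(object, fdr = fdr))
  class(out) <- "summary.qtl_map"
  out
}

#' @export
print.summary.qtl_map <- function(x, ...) {
  print(x$fit)
  res <- x$fit$results
  if (nrow(res) == 0L) return(invisible(x))
  if (any(!is.na(res$k_hat)))
    cat(sprintf("  beta shapes: mean k-hat %.3f; median n-hat %.1f (of %s variants tested, median)\n",
                mean(res$k_hat, na.rm = TRUE),
                stats::median(res$n_hat, na.rm = TRUE),
                format(stats::median(res$n_variants_tested))))
  if (!is.null(x$fdr)) print(x$fdr)
  top <- res[order(res$beta_perm_p, res$direct_perm_p, res$nominal_p), ]
  cat("  top associations:\n")
  print(utils::head(top[, c("phenotype_id", "best_variant_id",
                            "distance_to_anchor", "nominal_p", "slope",
                            "direct_perm_p", "beta_perm_p")], 5),
        row.names = FALSE)
  invisible(x)
}

#' @method coef qtl_map
#' @export
coef.qtl_map <- function(object, ...) {
  stats::setNames(object$results$slope, object$results$phenotype_id)
}

#' @method as.data.frame qtl_map
#' @export
as.data.frame.qtl_map <- function(x, ...) x$results

#' Diagnostic plots for a cis-QTL scan
#'
#' `which = "pvalues"` draws the histogram of adjusted P-values (flat for
#' null data, with a spike near 0 when signal is present); `which = "shapes"`
#' plots the fitted effective number of tests `n-hat` against the number of
#' variants actually tested, where LD pulls points below the diagonal.
#'
#' @param x A `qtl_map` object.
#' @param which `"pvalues"` or `"shapes"`.
#' @param ... Passed to the underlying base graphics call.
#' @method plot qtl_map
#' @export
plot.qtl_map <- function(x, which = c("pvalues", "shapes"), ...) {
  which <- match.arg(which)
  res <- x$results
  if (which == "pvalues") {
    p <- if (any(!is.na(res$beta_perm_p))) res$beta_perm_p else res$direct_perm_p
    graphics::hist(p, breaks = 20, main = "Adjusted P-values",
                   xlab = "adjusted P", col = "grey85", ...)
  } else {
    graphics::plot(res$n_variants_tested, res$n_hat,
                   xlab = "variants tested in cis (L)",
                   ylab = "effective number of tests (n-hat)", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
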