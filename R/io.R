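# Parse a "chr:start-end" region string into list(chrom, start, end).
parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region '", region, "'; expected chr:start-end")
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$start > out$end) stop("region start exceeds end: ", region)
  out
}

is_gzipped <- function(path) grepl("\\.gz$", path)

# Fetch raw data lines (no header) from a VCF, honouring a region restriction.
vcf_data_lines <- function(vcf_path, region = NULL) {
  region <- parse_region(region)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!is.null(region) && is_gzipped(vcf_path)) {
    tbi <- paste0(vcf_path, ".tbi")
    if (!file.exists(tbi))
      stop("region query on a compressed VCF requires a Tabix index (missing ",
           tbi, ")")
    tf <- Rsamtools::TabixFile(vcf_path, index = tbi)
    param <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start, region$end))
    return(unlist(Rsamtools::scanTabix(tf, param = param), use.names = FALSE))
  }
  con <- if (is_gzipped(vcf_path)) gzfile(vcf_path, "rt") else file(vcf_path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines[!startsWith(lines, "#")]
}

vcf_header_samples <- function(vcf_path) {
  con <- if (is_gzipped(vcf_path)) gzfile(vcf_path, "rt") else file(vcf_path, "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("no #CHROM header line in ", vcf_path)
    if (startsWith(ln, "#CHROM")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 10L) stop("VCF header has no sample columns: ", vcf_path)
      return(f[-(1:9)])
    }
    if (!startsWith(ln, "#")) stop("no #CHROM header line in ", vcf_path)
  }
}

# Dosage from one FORMAT-keyed sample field: DS preferred, else GT allele count.
field_dosage <- function(values, keys, ds_idx, gt_idx) {
  if (!is.na(ds_idx)) {
    parts <- vapply(values, function(v) strsplit(v, ":", fixed = TRUE)[[1]][ds_idx],
                    character(1), USE.NAMES = FALSE)
    d <- suppressWarnings(as.numeric(parts))
    d[parts %in% c(".", "")] <- NA_real_
    return(d)
  }
  gt <- vapply(values, function(v) strsplit(v, ":", fixed = TRUE)[[1]][gt_idx],
               character(1), USE.NAMES = FALSE)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    if (any(x == "." | x == "")) return(NA_real_)
    sum(x != "0")
  }, numeric(1))
}

#' Read genotype dosages from a VCF file
#'
#' Builds a dosage matrix (variants x samples) from a VCF, optionally
#' restricted to a genomic region. Dosages come from the `DS` FORMAT field
#' when present, otherwise from `GT` as the count of alternate alleles.
#' Variants that are monomorphic (zero variance) after missing-value handling
#' are always dropped; a minor-allele-frequency filter is applied when
#' `maf_min > 0`.
#'
#' Region queries on bgzip-compressed files require a Tabix `.tbi` index and
#' are served through [Rsamtools::scanTabix()]; plain-text and whole-file
#' reads need no index.
#'
#' @param vcf_path Path to a VCF file (`.vcf` or bgzipped `.vcf.gz`).
#' @param region Optional `"chr:start-end"` string (1-based, inclusive).
#' @param maf_min Minimum minor allele frequency; variants below it are
#'   dropped. Default 0 (only zero-variance variants removed).
#' @param missing_policy `"mean"` imputes missing genotypes to the per-variant
#'   mean dosage; `"drop_sample"` removes any sample with a missing genotype
#'   at a retained variant.
#' @return An object of class `dosage_matrix`: a list with `chrom`,
#'   `variant_ids`, `positions` (1-based), `dosages` (L x N numeric matrix),
#'   `sample_ids`, and the counts of variants dropped as monomorphic or
#'   below the MAF threshold.
#' @export
read_genotype_region <- function(vcf_path, region = NULL, maf_min = 0,
                                 missing_policy = c("mean", "drop_sample")) {
  missing_policy <- match.arg(missing_policy)
  region <- parse_region(region)
  samples <- vcf_header_samples(vcf_path)
  lines <- vcf_data_lines(vcf_path, region)

  n <- length(samples)
  L <- length(lines)
  dos <- matrix(NA_real_, nrow = L, ncol = n)
  ids <- character(L)
  pos <- integer(L)
  chroms <- character(L)
  for (i in seq_len(L)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + n)
      stop("malformed VCF data line ", i, ": expected ", 9L + n,
           " fields, found ", length(f))
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p)) stop("malformed VCF data line ", i, ": non-integer POS")
    chroms[i] <- f[1]
    pos[i] <- p
    ids[i] <- if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3]
    keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_idx <- match("DS", keys)
    gt_idx <- match("GT", keys)
    if (is.na(ds_idx) && is.na(gt_idx))
      stop("malformed VCF data line ", i, ": FORMAT has neither DS nor GT")
    dos[i, ] <- field_dosage(f[-(1:9)], keys, ds_idx, gt_idx)
  }

  # plain-text whole-file reads may still need the in-memory region filter
  if (!is.null(region)) {
    keep <- chroms == region$chrom & pos >= region$start & pos <= region$end
    dos <- dos[keep, , drop = FALSE]; ids <- ids[keep]; pos <- pos[keep]
    chroms <- chroms[keep]
  }
  chrom <- if (length(chroms)) chroms[1] else if (!is.null(region)) region$chrom else NA_character_
  if (length(unique(chroms)) > 1L)
    stop("multiple chromosomes in one dosage matrix; use a region restriction")

  if (missing_policy == "drop_sample") {
    bad <- apply(dos, 2, anyNA)
    dos <- dos[, !bad, drop = FALSE]
    samples <- samples[!bad]
  } else if (anyNA(dos)) {
    for (i in which(apply(dos, 1, anyNA))) {
      m <- mean(dos[i, ], na.rm = TRUE)
      dos[i, is.na(dos[i, ])] <- m
    }
  }

  af <- rowMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  v <- apply(dos, 1, stats::var)
  mono <- v == 0 | is.na(v)
  low <- !mono & maf < maf_min
  keep <- !mono & !low
  ord <- order(pos[keep])

  out <- list(chrom = chrom,
              variant_ids = ids[keep][ord],
              positions = pos[keep][ord],
              dosages = dos[keep, , drop = FALSE][ord, , drop = FALSE],
              sample_ids = samples,
              n_monomorphic = sum(mono),
              n_below_maf = sum(low))
  dimnames(out$dosages) <- list(out$variant_ids, samples)
  class(out) <- "dosage_matrix"
  out
}

#' Read molecular phenotype quantifications from a UCSC BED file
#'
#' The expected layout is the QTL-mapping convention: a header line beginning
#' `#chr` (or `#Chr`) naming `chr`, `start`, `end`, `id` and then one column
#' per sample; each data row carries one phenotype. Coordinates are kept
#' 0-based half-open internally; the cis-window anchor of a phenotype is
#' `start + 1` (its 1-based position, TSS-style).
#'
#' @param bed_path Path to the BED file (plain or gzipped).
#' @param region Optional `"chr:start-end"` string; phenotypes whose anchor
#'   falls inside it (1-based, inclusive) are returned.
#' @return An object of class `phenotype_set`: `phenotype_ids`, `chrom`,
#'   `start`, `end` (0-based half-open), `anchor` (1-based), `values`
#'   (phenotypes x samples matrix), `sample_ids`.
#' @export
read_phenotype_bed <- function(bed_path, region = NULL) {
  region <- parse_region(region)
  con <- if (is_gzipped(bed_path)) gzfile(bed_path, "rt") else file(bed_path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) stop("empty BED file: ", bed_path)
  hdr_i <- which(startsWith(lines, "#"))
  if (length(hdr_i) == 0L) stop("BED header line beginning '#chr' required: ", bed_path)
  header <- strsplit(lines[hdr_i[length(hdr_i)]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5L) stop("BED needs >= 5 columns (chr start end id samples...)")
  samples <- header[-(1:4)]
  data <- lines[-seq_len(hdr_i[length(hdr_i)])]
  data <- data[nzchar(data)]

  P <- length(data)
  ids <- character(P); chrom <- character(P)
  start <- integer(P); end <- integer(P)
  vals <- matrix(NA_real_, nrow = P, ncol = length(samples))
  for (i in seq_len(P)) {
    f <- strsplit(data[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("BED row ", i, " has ", length(f), " fields; header has ",
           length(header))
    chrom[i] <- f[1]; start[i] <- as.integer(f[2]); end[i] <- as.integer(f[3])
    ids[i] <- f[4]
    vals[i, ] <- as.numeric(f[-(1:4)])
  }
  if (anyDuplicated(ids))
    stop("duplicated phenotype id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  anchor <- start + 1L
  if (!is.null(region)) {
    keep <- chrom == region$chrom & anchor >= region$start & anchor <= region$end
    ids <- ids[keep]; chrom <- chrom[keep]; start <- start[keep]
    end <- end[keep]; anchor <- anchor[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- ids; colnames(vals) <- samples
  structure(list(phenotype_ids = ids, chrom = chrom, start = start, end = end,
                 anchor = anchor, values = vals, sample_ids = samples),
            class = "phenotype_set")
}

#' Read a covariate table
#'
#' Whitespace-separated matrix with covariate ids in column 1 and sample ids
#' on the header line. Qualitative covariates must already be numerically
#' encoded.
#'
#' @param cov_path Path to the covariate file (plain or gzipped).
#' @return An object of class `covariate_matrix`: `covariate_ids`, `values`
#'   (C x N matrix), `sample_ids`.
#' @export
read_covariates <- function(cov_path) {
  tab <- utils::read.table(cov_path, header = TRUE, check.names = FALSE,
                           comment.char = "")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("covariates must be numeric; encode qualitative covariates first")
  rownames(vals) <- ids
  structure(list(covariate_ids = ids, values = vals,
                 sample_ids = colnames(vals)),
            class = "covariate_matrix")
}

#' Align genotype, phenotype and covariate samples
#'
#' Intersects the sample ids of the three inputs and reorders every matrix to
#' a single shared sample order (the genotype order of the common samples).
#' Covariates that become constant after intersection are dropped with a
#' warning.
#'
#' @param g A `dosage_matrix`.
#' @param p A `phenotype_set`.
#' @param cov A `covariate_matrix` or `NULL`.
#' @return List with elements `genotypes`, `phenotypes`, `covariates` (NULL if
#'   not supplied) and `n_dropped`, the count of sample ids discarded from at
#'   least one input.
#' @export
intersect_samples <- function(g, p, cov = NULL) {
  common <- intersect(g$sample_ids, p$sample_ids)
  if (!is.null(cov)) common <- intersect(common, cov$sample_ids)
  common <- g$sample_ids[g$sample_ids %in% common]  # deterministic order
  if (length(common) < 3L)
    stop("fewer than 3 samples shared across inputs (", length(common), ")")
  n_dropped <- length(unique(c(g$sample_ids, p$sample_ids,
                               if (!is.null(cov)) cov$sample_ids))) -
    length(common)

  g$dosages <- g$dosages[, match(common, g$sample_ids), drop = FALSE]
  g$sample_ids <- common
  p$values <- p$values[, match(common, p$sample_ids), drop = FALSE]
  p$sample_ids <- common
  if (!is.null(cov)) {
    cov$values <- cov$values[, match(common, cov$sample_ids), drop = FALSE]
    cov$sample_ids <- common
    const <- apply(cov$values, 1, function(x) stats::var(x) == 0 || anyNA(x))
    if (any(const)) {
      warning("dropping constant covariate(s) after sample intersection: ",
              paste(cov$covariate_ids[const], collapse = ", "))
      cov$values <- cov$values[!const, , drop = FALSE]
      cov$covariate_ids <- cov$covariate_ids[!const]
    }
  }
  list(genotypes = g, phenotypes = p, covariates = cov, n_dropped = n_dropped)
}

result_columns <- c("phenotype_id", "n_variants_tested", "k_hat", "n_hat",
                    "best_variant_id", "distance_to_anchor", "nominal_p",
                    "slope", "direct_perm_p", "beta_perm_p")

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE),
                sprintf("%.6g", x)))
}

#' Write per-phenotype mapping results
#'
#' One space-separated row per phenotype, headerless (so per-chunk outputs can
#' be concatenated into a whole-run file): phenotype id, number of variants
#' tested, fitted beta shapes k and n, best variant id, signed distance of the
#' variant to the phenotype anchor, nominal P-value, slope, direct permutation
#' adjusted P and beta-approximation adjusted P. Fields a scheme does not
#' produce are written as `NA`. Output is gzip-compressed when `out_path`
#' ends in `.gz`.
#'
#' @param records A data frame of results (as found in `$results` of a
#'   [qtl_map()] fit) or a `qtl_map` object.
#' @param out_path Destination path.
#' @return Invisibly, `out_path`.
#' @export
write_results <- function(records, out_path) {
  if (inherits(records, "qtl_map")) records <- records$results
  con <- if (is_gzipped(out_path)) gzfile(out_path, "wt") else file(out_path, "wt")
  on.exit(close(con))
  if (nrow(records) == 0L) return(invisible(out_path))
  num <- function(col) fmt_num(records[[col]])
  rows <- paste(records$phenotype_id, records$n_variants_tested,
                num("k_hat"), num("n_hat"),
                ifelse(is.na(records$best_variant_id), "NA", records$best_variant_id),
                ifelse(is.na(records$distance_to_anchor), "NA",
                       as.character(records$distance_to_anchor)),
                num("nominal_p"), num("slope"),
                num("direct_perm_p"), num("beta_perm_p"))
  writeLines(rows, con)
  invisible(out_path)
}

#' Read a results file written by [write_results()]
#'
#' @param path Path to the (possibly gzipped) results file.
#' @return Data frame with the ten result columns.
#' @export
read_results <- function(path) {
  con <- if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)),
                                             length(result_columns)),
                                         result_columns))
    return(out)
  }
  tab <- utils::read.table(text = lines, header = FALSE,
                           col.names = result_columns,
                           na.strings = "NA", stringsAsFactors = FALSE)
  tab
}
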