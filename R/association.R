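#' Rank-based inverse normal transform
#'
#' Quantile-normalizes a vector of phenotype quantifications: values are
#' replaced by normal quantiles of their ranks, `qnorm(rank / (n + 1))`, and
#' rescaled to mean 0, standard deviation 1. This makes the downstream
#' correlation scan robust to outliers while preserving the rank order of
#' distinct values.
#'
#' @param x Numeric vector, length >= 3, not constant.
#' @param tie_policy `"average"` gives tied values their average rank;
#'   `"random"` breaks ties randomly (seeded by the caller's RNG state).
#' @return Numeric vector with mean 0 and sd 1.
#' @export
quantile_normalize <- function(x, tie_policy = c("average", "random")) {
  tie_policy <- match.arg(tie_policy)
  if (length(x) < 3L) stop("need at least 3 values to quantile normalize")
  if (anyNA(x)) stop("missing values not allowed in quantile normalization")
  if (stats::var(x) == 0) stop("constant vector: ranks undefined")
  r <- rank(x, ties.method = if (tie_policy == "average") "average" else "random")
  z <- stats::qnorm(r / (length(x) + 1))
  (z - mean(z)) / stats::sd(z)
}

covariate_basis <- function(cov, n) {
  X <- matrix(1, nrow = n, ncol = 1)
  if (!is.null(cov) && length(cov$covariate_ids) > 0L) {
    X <- cbind(X, t(cov$values))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping ", length(dropped),
            " collinear covariate column(s) before residualization")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  qrX
}

#' Residualize a matrix on covariates
#'
#' Projects each row of `mat` (rows are variables, columns samples) onto the
#' orthogonal complement of the span of the covariates plus an intercept —
#' the same operation is applied to genotypes and phenotypes so that the
#' subsequent correlation is the partial correlation given covariates.
#' Rank-deficient covariate sets lose their collinear columns with a warning.
#'
#' @param mat Numeric matrix, variables x samples.
#' @param cov A `covariate_matrix`, or `NULL` for intercept-only (row
#'   centering).
#' @return Matrix of residuals, same dimensions as `mat`.
#' @export
residualize <- function(mat, cov = NULL) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  n <- ncol(mat)
  n_cov <- if (is.null(cov)) 0L else length(cov$covariate_ids)
  if (n <= n_cov + 2L)
    stop("need more samples (", n, ") than covariates + 2 (", n_cov + 2L, ")")
  qrX <- covariate_basis(cov, n)
  t(qr.resid(qrX, t(mat)))
}

# Scale rows to zero mean and unit Euclidean norm so that the cross product
# of two standardized rows is their Pearson correlation.
std_rows <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  c_ <- mat - rowMeans(mat)
  ss <- sqrt(rowSums(c_^2))
  if (any(ss == 0)) stop("zero-variance row cannot be standardized")
  c_ / ss
}

std_vec <- function(x) {
  x <- x - mean(x)
  ss <- sqrt(sum(x^2))
  if (ss == 0) stop("zero-variance phenotype")
  x / ss
}

#' Correlate one phenotype against every variant in a dosage matrix
#'
#' Computes the Pearson correlation of the phenotype with each variant row
#' and identifies the most strongly correlated variant (largest `|r|`; exact
#' ties go to the lowest variant index, i.e. the lowest genomic position).
#' The scan is a single matrix-vector product against row-standardized
#' dosages, so repeated scans of permuted phenotypes reuse the standardized
#' matrix.
#'
#' @param phenotype Numeric vector, one value per sample.
#' @param g A `dosage_matrix`, or a row-standardized numeric matrix as
#'   returned by the internal standardization (rows unit-norm, zero-mean).
#' @return List with `r_values` (correlation per variant) and `best_index`.
#' @export
correlation_scan <- function(phenotype, g) {
  gs <- if (inherits(g, "dosage_matrix")) std_rows(g$dosages) else g
  if (ncol(gs) != length(phenotype))
    stop("phenotype length does not match sample count")
  r <- as.vector(gs %*% std_vec(phenotype))
  r <- pmin(pmax(r, -1), 1)
  list(r_values = r, best_index = which.max(abs(r)))
}

#' Nominal P-value for a Pearson correlation
#'
#' Two-sided P from the t statistic `t = r * sqrt(df / (1 - r^2))`. `1 - r^2`
#' is floored at 1e-16 and the result at the smallest positive double, so a
#' perfect correlation yields a representable nonzero P.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param df Residual degrees of freedom (>= 1).
#' @return P-value(s) in (0, 1].
#' @export
correlation_to_pvalue <- function(r, df) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1")
  if (df < 1) stop("df must be >= 1")
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, 1e-16))
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

# Restrict a dosage matrix to the cis-window around a 1-based anchor.
window_variants <- function(g, anchor, window) {
  which(g$positions >= anchor - window & g$positions <= anchor + window)
}

na_scan <- function(id, n_tested = 0L) {
  list(phenotype_id = id, n_tested = n_tested, best_index = NA_integer_,
       best_r = NA_real_, nominal_p = NA_real_, slope = NA_real_,
       df = NA_real_, best_variant_id = NA_character_, distance = NA_integer_)
}

# Shared per-phenotype preparation: window restriction, optional inverse
# normal transform, residualization of both sides, df bookkeeping.
prepare_phenotype <- function(y, g, anchor, window, cov = NULL,
                              normalize = FALSE, df_policy = c("adjusted", "legacy")) {
  df_policy <- match.arg(df_policy)
  idx <- window_variants(g, anchor, window)
  if (length(idx) == 0L) return(NULL)
  n <- length(y)
  n_cov <- if (is.null(cov)) 0L else length(cov$covariate_ids)
  if (normalize) y <- quantile_normalize(y)
  gd <- g$dosages[idx, , drop = FALSE]
  if (n_cov > 0L) {
    y <- as.vector(residualize(matrix(y, nrow = 1), cov))
    gd <- residualize(gd, cov)
  }
  keep <- apply(gd, 1, function(x) stats::var(x) > 0)
  idx <- idx[keep]
  if (length(idx) == 0L) return(NULL)
  gd <- gd[keep, , drop = FALSE]
  df <- if (df_policy == "adjusted") n - 2L - n_cov else n - 2L
  list(y = y, y_std = std_vec(y), g_std = std_rows(gd), idx = idx,
       g_resid = gd, df = df)
}

scan_one <- function(prep, g, id, anchor) {
  sc <- correlation_scan(prep$y_std, prep$g_std)
  b <- sc$best_index
  r <- sc$r_values[b]
  p <- correlation_to_pvalue(r, prep$df)
  slope <- r * stats::sd(prep$y) / stats::sd(prep$g_resid[b, ])
  list(phenotype_id = id, n_tested = length(prep$idx),
       best_index = prep$idx[b], best_r = r, nominal_p = p, slope = slope,
       df = prep$df,
       best_variant_id = g$variant_ids[prep$idx[b]],
       distance = g$positions[prep$idx[b]] - anchor)
}

#' Nominal cis-scan over a set of phenotypes
#'
#' For each phenotype, restricts variants to `anchor +/- window`, optionally
#' applies the rank-based inverse normal transform and residualizes both
#' phenotype and genotypes on covariates, and returns the best-correlated
#' variant with its nominal P-value and slope (on the phenotype scale used
#' for testing). Phenotypes with no variant in their window are reported with
#' `n_tested = 0` and `NA` statistics.
#'
#' @param p A `phenotype_set`.
#' @param g A `dosage_matrix`, sample-aligned with `p`.
#' @param window Cis-window half-width in base pairs (default 1e6).
#' @param cov Optional `covariate_matrix`, sample-aligned.
#' @param normalize Apply [quantile_normalize()] to each phenotype first.
#' @param df_policy `"adjusted"` uses `N - 2 - C` residual degrees of freedom
#'   when `C` covariates are regressed out; `"legacy"` keeps `N - 2`.
#' @return List of per-phenotype scan records.
#' @export
nominal_pass <- function(p, g, window = 1e6, cov = NULL, normalize = FALSE,
                         df_policy = c("adjusted", "legacy")) {
  df_policy <- match.arg(df_policy)
  lapply(seq_along(p$phenotype_ids), function(i) {
    prep <- prepare_phenotype(p$values[i, ], g, p$anchor[i], window, cov,
                              normalize, df_policy)
    if (is.null(prep)) return(na_scan(p$phenotype_ids[i]))
    scan_one(prep, g, p$phenotype_ids[i], p$anchor[i])
  })
}
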