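#' Estimate the proportion of true null hypotheses
#'
#' Storey-Tibshirani estimator: for each `lambda` in the grid,
#' `pi0(lambda) = #[p > lambda] / (m (1 - lambda))`; the sequence is smoothed
#' with a cubic smoothing spline against `lambda` and evaluated at the
#' largest `lambda`, then clamped to `(0, 1]`. A `"fixed"` method using a
#' single `lambda = 0.5` is provided for small collections where the spline
#' is unstable.
#'
#' @param pvalues Vector of P-values (a warning is issued below 100 — the
#'   estimate is noisy for small collections).
#' @param lambda_grid Grid of lambda values (default `seq(0.05, 0.95, 0.05)`).
#' @param method `"smoother"` (spline, the default) or `"fixed"`
#'   (`lambda = 0.5` only).
#' @return Estimated pi0 in `(0, 1]`.
#' @export
estimate_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed")) {
  method <- match.arg(method)
  if (anyNA(pvalues)) pvalues <- pvalues[!is.na(pvalues)]
  m <- length(pvalues)
  if (m == 0L) stop("no P-values")
  if (m < 100L)
    warning("pi0 estimated from only ", m, " P-values; expect instability")
  if (method == "fixed") {
    pi0 <- mean(pvalues > 0.5) / 0.5
    return(min(max(pi0, 1 / m), 1))
  }
  lambda_grid <- sort(unique(lambda_grid))
  if (length(lambda_grid) < 4L || any(lambda_grid <= 0) || any(lambda_grid >= 1))
    stop("degenerate lambda grid: need >= 4 distinct values in (0, 1)")
  pi0_l <- vapply(lambda_grid,
                  function(l) mean(pvalues > l) / (1 - l), numeric(1))
  sp <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
  pi0 <- stats::predict(sp, x = max(lambda_grid))$y
  min(max(pi0, 1 / m), 1)
}

#' Storey-Tibshirani q-values
#'
#' `q_(i) = min_{j >= i} pi0 m p_(j) / j` on the sorted P-values, mapped back
#' to the input order. With `pi0 = 1` this is exactly the Benjamini-Hochberg
#' adjustment; learning `pi0 < 1` from the data makes every q-value
#' proportionally smaller, hence more calls at the same FDR.
#'
#' @param pvalues Vector of P-values.
#' @param pi0 Proportion of true nulls, in `(0, 1]`.
#' @return Vector of q-values aligned with `pvalues`.
#' @export
qvalue_transform <- function(pvalues, pi0 = 1) {
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(pi0 * m * p[o] / seq_len(m), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- q
  out
}

#' Call significant phenotypes at a target FDR
#'
#' @param qvalues Vector of q-values.
#' @param fdr Target false discovery rate (e.g. 0.05 or 0.10).
#' @param pvalues Optional adjusted P-values aligned with `qvalues`, used to
#'   report `threshold_p`, the largest adjusted P among the called set.
#' @return List with `significant` (logical mask) and `threshold_p` (`NA`
#'   when nothing is called).
#' @export
call_significant <- function(qvalues, fdr, pvalues = NULL) {
  mask <- !is.na(qvalues) & qvalues <= fdr
  ref <- if (is.null(pvalues)) qvalues else pvalues
  threshold_p <- if (any(mask)) max(ref[mask], na.rm = TRUE) else NA_real_
  list(significant = mask, threshold_p = threshold_p)
}

#' Genome-wide FDR across phenotype-level adjusted P-values
#'
#' Applies the Storey-Tibshirani procedure to the adjusted P-values of a
#' [qtl_map()] fit (or a plain numeric vector): estimates `pi0`, converts to
#' q-values, and calls phenotypes at the target FDR.
#'
#' @param x A `qtl_map` object or numeric vector of adjusted P-values.
#' @param fdr Target FDR (default 0.05).
#' @param pi0 Override the estimated pi0 (e.g. `pi0 = 1` for BH).
#' @param use For a `qtl_map` fit, which adjusted P column to use:
#'   `"auto"` prefers the beta-approximation column when present, else the
#'   permutation column; or name one of `"beta_perm_p"`, `"direct_perm_p"`,
#'   `"nominal_p"`.
#' @param ... Passed to [estimate_pi0()].
#' @return An object of class `qtl_fdr`: `pvalues`, `pi0`, `qvalues`,
#'   `significant`, `threshold_p`, `fdr`, and `phenotype_id` when available.
#' @export
qtl_fdr <- function(x, fdr = 0.05, pi0 = NULL, use = "auto", ...) {
  ids <- NULL
  if (inherits(x, "qtl_map")) {
    res <- x$results
    col <- if (use == "auto") {
      if (any(!is.na(res$beta_perm_p))) "beta_perm_p" else "direct_perm_p"
    } else use
    p <- res[[col]]
    ids <- res$phenotype_id
  } else {
    p <- as.numeric(x)
    col <- "pvalues"
  }
  if (is.null(pi0)) pi0 <- estimate_pi0(p, ...)
  q <- qvalue_transform(p, pi0)
  call <- call_significant(q, fdr, pvalues = p)
  structure(list(phenotype_id = ids, pvalues = p, source = col, pi0 = pi0,
                 qvalues = q, significant = call$significant,
                 threshold_p = call$threshold_p, fdr = fdr),
            class = "qtl_fdr")
}

#' @export
print.qtl_fdr <- function(x, ...) {
  cat("Storey-Tibshirani FDR on", length(x$pvalues), "adjusted P-values (",
      x$source, ")\n", sep = " ")
  cat(sprintf("  pi0 = %.4f\n", x$pi0))
  cat(sprintf("  significant at FDR %.2g: %d phenotype(s)\n", x$fdr,
              sum(x$significant, na.rm = TRUE)))
  if (!is.na(x$threshold_p))
    cat(sprintf("  adjusted-P threshold: %.4g\n", x$threshold_p))
  invisible(x)
}
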