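# Maximum |r| per column of an L x B correlation matrix, via a pmax
# reduction over rows (fast for the modest L of a cis-window).
col_max_abs <- function(rmat) {
  a <- abs(rmat)
  out <- a[1, ]
  if (nrow(a) > 1L) for (i in 2:nrow(a)) out <- pmax(out, a[i, ])
  unname(out)
}

# Deterministic per-phenotype RNG substream: a stable string hash folded with
# the run seed, so results do not depend on chunking or phenotype order.
phenotype_seed <- function(seed, id) {
  h <- 0
  for (c_ in utf8ToInt(id)) h <- (h * 31 + c_) %% 2147483647
  as.integer((h * 69069 + seed * 1013904223 + 17) %% 2147483647)
}

#' Permute a phenotype and rescan the cis-window
#'
#' Draws `R` uniform random permutations of the phenotype, leaving the
#' genotypes unchanged so the correlation structure among variants (LD) is
#' preserved, and records for each permutation the best (smallest) nominal
#' P-value across the window. Permutations are evaluated in batches as
#' matrix products against the standardized dosage matrix.
#'
#' @param phenotype Numeric phenotype vector, already normalized and
#'   residualized exactly as in the nominal pass.
#' @param g_std Row-standardized dosage matrix (variants x samples).
#' @param R Number of permutations (>= 1).
#' @param df Residual degrees of freedom for the P-value transform.
#' @param nominal_p Observed nominal P-value; permutation minima `<=` it
#'   (ties included, conservatively) are counted as exceedances.
#' @param seed Optional integer; when given, `set.seed(seed)` is applied
#'   first so the draw is reproducible.
#' @param batch Permutations evaluated per matrix product.
#' @return An object of class `permutation_null`: `null_pvalues` (length R),
#'   `r_exceed`, `R`.
#' @export
permute_and_scan <- function(phenotype, g_std, R, df, nominal_p = NA_real_,
                             seed = NULL, batch = 1000L) {
  stopifnot(R >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- std_vec(phenotype)
  n <- length(y)
  null_p <- numeric(R)
  done <- 0L
  while (done < R) {
    b <- min(batch, R - done)
    perm <- matrix(0, nrow = n, ncol = b)
    for (j in seq_len(b)) perm[, j] <- y[sample.int(n)]
    best_r <- col_max_abs(g_std %*% perm)
    null_p[done + seq_len(b)] <- correlation_to_pvalue(best_r, df)
    done <- done + b
  }
  structure(list(null_pvalues = null_p,
                 r_exceed = if (is.na(nominal_p)) NA_integer_
                            else sum(null_p <= nominal_p),
                 R = R),
            class = "permutation_null")
}

#' Direct permutation adjusted P-value
#'
#' The empirical adjusted P-value `(r + 1) / (R + 1)` for `r` null best
#' associations at least as strong as the observed one out of `R`
#' permutations. Its lower bound is `1 / (R + 1)`.
#'
#' @param r_exceed Exceedance count, `0 <= r_exceed <= R`.
#' @param R Number of permutations performed (>= 1).
#' @return Adjusted P-value in `[1/(R+1), 1]`.
#' @export
direct_adjusted_p <- function(r_exceed, R) {
  if (R < 1) stop("R must be >= 1")
  if (any(r_exceed < 0) || any(r_exceed > R)) stop("need 0 <= r_exceed <= R")
  (r_exceed + 1) / (R + 1)
}

#' Adaptive permutation adjusted P-value
#'
#' Permutes the phenotype in batches until `B` null associations stronger
#' than (or tying) the observed one have accumulated, or until `M`
#' permutations have been spent, and returns
#' `(min(r, B) + 1) / (min(R, M) + 1)`. Insignificant hits stop after few
#' permutations; strong ones run to the `M` cap, so the smallest achievable
#' value is `1 / (M + 1)`.
#'
#' @inheritParams permute_and_scan
#' @param B Stop once this many exceedances are seen (default 100).
#' @param M Hard cap on total permutations (default 100000).
#' @return List with `p_adj` and the accumulated `permutation_null`.
#' @export
adaptive_adjusted_p <- function(phenotype, g_std, nominal_p, df, B = 100L,
                                M = 100000L, batch = 100L, seed = NULL) {
  stopifnot(B >= 1, M >= B)
  if (!is.null(seed)) set.seed(seed)
  y <- std_vec(phenotype)
  n <- length(y)
  null_p <- numeric(0)
  r <- 0L; R <- 0L
  while (r < B && R < M) {
    b <- min(batch, M - R)
    perm <- matrix(0, nrow = n, ncol = b)
    for (j in seq_len(b)) perm[, j] <- y[sample.int(n)]
    p_b <- correlation_to_pvalue(col_max_abs(g_std %*% perm), df)
    # stop at the permutation where the B-th exceedance lands, as if the
    # condition were checked after every single permutation
    hit <- which(r + cumsum(p_b <= nominal_p) >= B)
    if (length(hit) > 0L) {
      p_b <- p_b[seq_len(hit[1])]
      b <- hit[1]
    }
    null_p <- c(null_p, p_b)
    r <- r + sum(p_b <= nominal_p)
    R <- R + b
  }
  p_adj <- (min(r, B) + 1) / (min(R, M) + 1)
  list(p_adj = p_adj,
       null = structure(list(null_pvalues = null_p, r_exceed = r, R = R),
                        class = "permutation_null"))
}

beta_loglik <- function(log_kn, lp, l1p) {
  k <- exp(log_kn[1]); n <- exp(log_kn[2])
  R <- length(lp)
  (k - 1) * sum(lp) + (n - 1) * sum(l1p) -
    R * (lgamma(k) + lgamma(n) - lgamma(k + n))
}

beta_loglik_grad <- function(log_kn, lp, l1p) {
  k <- exp(log_kn[1]); n <- exp(log_kn[2])
  R <- length(lp)
  dk <- sum(lp) - R * (digamma(k) - digamma(k + n))
  dn <- sum(l1p) - R * (digamma(n) - digamma(k + n))
  c(dk * k, dn * n)  # chain rule for log-parameters
}

beta_moment_start <- function(p) {
  m <- mean(p); v <- stats::var(p)
  v <- max(v, 1e-12)
  common <- m * (1 - m) / v - 1
  k <- max(m * common, 1e-3)
  n <- max((1 - m) * common, 1e-3)
  c(k, n)
}

#' Fit a beta distribution to null minimum P-values by maximum likelihood
#'
#' Models the per-permutation minimum P-value as `Beta(k, n)` — the order
#' statistic of independent uniforms — and estimates the shapes by maximizing
#' the log-likelihood
#' `(k-1) sum(log p) + (n-1) sum(log(1-p)) - R log(B(k, n))`
#' with BFGS on `(log k, log n)` (positivity by construction, analytic
#' gradient), starting from method-of-moments estimates with up to three
#' deterministic jittered restarts. `k` is interpretable as the rank of the
#' association and `n` as the effective number of independent tests, which
#' LD pulls below the actual variant count.
#'
#' @param null_pvalues At least 10 probabilities; values are clamped to
#'   `[1e-300, 1 - 1e-16]` before taking logs.
#' @return An object of class `beta_fit`: `k_hat`, `n_hat`, `loglik`,
#'   `converged`.
#' @export
fit_beta_mle <- function(null_pvalues) {
  if (inherits(null_pvalues, "permutation_null"))
    null_pvalues <- null_pvalues$null_pvalues
  if (length(null_pvalues) < 10L) stop("need at least 10 null P-values")
  p <- pmin(pmax(null_pvalues, 1e-300), 1 - 1e-16)
  lp <- log(p); l1p <- log1p(-p)

  start0 <- log(beta_moment_start(p))
  ll0 <- beta_loglik(start0, lp, l1p)
  jitters <- list(c(0, 0), c(0.5, -0.5), c(-0.5, 0.5), c(1, 1))
  last <- NULL
  for (jit in jitters) {
    fit <- tryCatch(
      stats::optim(start0 + jit, fn = beta_loglik, gr = beta_loglik_grad,
                   lp = lp, l1p = l1p, method = "BFGS",
                   control = list(fnscale = -1, reltol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      last <- fit
      if (fit$convergence == 0 && fit$value >= ll0 - 1e-8) break
    }
  }
  if (is.null(last))
    stop("beta maximum-likelihood fit failed after restarts")
  k <- exp(last$par[1]); n <- exp(last$par[2])
  if (last$convergence != 0)
    stop(errorCondition(
      sprintf("beta ML optimizer did not converge (last iterate k=%.4g, n=%.4g)",
              k, n),
      k = k, n = n, class = c("beta_mle_error", "error", "condition")))
  structure(list(k_hat = k, n_hat = n, loglik = last$value,
                 loglik_start = ll0, converged = TRUE),
            class = "beta_fit")
}

#' Beta-approximation adjusted P-value
#'
#' Evaluates the fitted beta CDF at the nominal P-value,
#' `P(U <= p_n)` with `U ~ Beta(k_hat, n_hat)` — the regularized incomplete
#' beta function — giving an adjusted P-value with no permutation-count lower
#' bound. With `k = 1` and `n = L` this reduces to the independent-tests
#' closed form `1 - (1 - p_n)^L`.
#'
#' @param nominal_p Nominal P-value(s).
#' @param fit A `beta_fit` (must have converged), or a list with `k_hat`,
#'   `n_hat`.
#' @param log.p Return `log(p_b)` (useful far in the tail).
#' @return Adjusted P-value(s), strictly increasing in `nominal_p`.
#' @export
beta_adjusted_p <- function(nominal_p, fit, log.p = FALSE) {
  if (inherits(fit, "beta_fit") && !isTRUE(fit$converged))
    stop("beta fit did not converge")
  stats::pbeta(nominal_p, fit$k_hat, fit$n_hat, log.p = log.p)
}

scheme_fields <- function(scan, direct_p = NA_real_, beta_p = NA_real_,
                          k = NA_real_, n = NA_real_) {
  data.frame(phenotype_id = scan$phenotype_id,
             n_variants_tested = scan$n_tested,
             k_hat = k, n_hat = n,
             best_variant_id = scan$best_variant_id,
             distance_to_anchor = scan$distance,
             nominal_p = scan$nominal_p, slope = scan$slope,
             direct_perm_p = direct_p, beta_perm_p = beta_p,
             stringsAsFactors = FALSE)
}

#' Full permutation pass over a phenotype set
#'
#' Runs the nominal cis-scan for every phenotype and corrects each best
#' nominal P-value for the number of correlated variants tested, using the
#' requested scheme:
#' \describe{
#'   \item{direct}{`R` permutations, adjusted P `(r + 1)/(R + 1)`.}
#'   \item{adaptive}{permute until `B` exceedances or `M` permutations,
#'     adjusted P `(min(r,B) + 1)/(min(R,M) + 1)`.}
#'   \item{beta}{`R` permutations; `Beta(k, n)` fitted by ML to the null
#'     minima; adjusted P is the fitted CDF at the nominal P. The direct
#'     estimate from the same permutations is reported alongside.}
#' }
#' Each phenotype consumes its own RNG substream derived from `(seed,
#' phenotype_id)`, so chunked and whole runs produce identical rows.
#'
#' @inheritParams nominal_pass
#' @param scheme One of `"beta"`, `"direct"`, `"adaptive"`.
#' @param R Permutations for the direct and beta schemes (default 1000).
#' @param B,M Adaptive-scheme stop count and permutation cap.
#' @param seed Integer run seed.
#' @param batch Permutations per matrix product.
#' @return Data frame with one row per phenotype and the ten result columns
#'   (see [write_results()]).
#' @export
full_permutation_pass <- function(p, g, window = 1e6,
                                  scheme = c("beta", "direct", "adaptive"),
                                  R = 1000L, B = 100L, M = 100000L,
                                  seed = 1L, cov = NULL, normalize = FALSE,
                                  df_policy = c("adjusted", "legacy"),
                                  batch = 1000L) {
  scheme <- match.arg(scheme)
  df_policy <- match.arg(df_policy)
  rows <- lapply(seq_along(p$phenotype_ids), function(i) {
    id <- p$phenotype_ids[i]
    prep <- prepare_phenotype(p$values[i, ], g, p$anchor[i], window, cov,
                              normalize, df_policy)
    if (is.null(prep)) return(scheme_fields(na_scan(id)))
    scan <- scan_one(prep, g, id, p$anchor[i])
    sub_seed <- phenotype_seed(seed, id)
    if (scheme == "adaptive") {
      ad <- adaptive_adjusted_p(prep$y, prep$g_std, scan$nominal_p, prep$df,
                                B = B, M = M, batch = min(batch, 100L),
                                seed = sub_seed)
      return(scheme_fields(scan, direct_p = ad$p_adj))
    }
    null <- permute_and_scan(prep$y, prep$g_std, R = R, df = prep$df,
                             nominal_p = scan$nominal_p, seed = sub_seed,
                             batch = batch)
    direct_p <- direct_adjusted_p(null$r_exceed, null$R)
    if (scheme == "direct") return(scheme_fields(scan, direct_p = direct_p))
    fit <- fit_beta_mle(null$null_pvalues)
    scheme_fields(scan, direct_p = direct_p,
                  beta_p = beta_adjusted_p(scan$nominal_p, fit),
                  k = fit$k_hat, n = fit$n_hat)
  })
  do.call(rbind, rows)
}
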