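test_that("inverse normal transform matches the normal-quantile oracle", {
  z <- quantile_normalize(c(3, 1, 2))
  raw <- qnorm(c(0.75, 0.25, 0.50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, raw / sd(raw), tolerance = 1e-12)
  expect_equal(z / max(z), c(0.6745, -0.6745, 0) / 0.6745, tolerance = 1e-4)
})

test_that("inverse normal transform is permutation-equivariant and rank-preserving", {
  set.seed(42)
  x <- rnorm(25)
  perm <- sample(25)
  expect_equal(quantile_normalize(x)[perm], quantile_normalize(x[perm]))
  expect_equal(order(quantile_normalize(x)), order(x))
  expect_error(quantile_normalize(c(5, 5, 5)), "constant")
  expect_error(quantile_normalize(c(1, 2)), "at least 3")
})

test_that("residualization is an orthogonal projection matching least squares", {
  set.seed(7)
  mat <- matrix(rnorm(5 * 20), nrow = 5)
  cv <- structure(list(covariate_ids = c("c1", "c2"),
                       values = matrix(rnorm(2 * 20), nrow = 2),
                       sample_ids = paste0("s", 1:20)),
                  class = "covariate_matrix")
  res <- residualize(mat, cv)

  X <- cbind(1, t(cv$values))
  for (i in 1:5) {
    oracle <- stats::lm.fit(X, mat[i, ])$residuals  # normal-equations oracle
    expect_equal(unname(res[i, ]), unname(oracle), tolerance = 1e-10)
    expect_lt(max(abs(crossprod(X, res[i, ]))), 1e-8)
  }

  # idempotence and the intercept-only (centering) case
  expect_equal(residualize(res, cv), res, tolerance = 1e-12)
  expect_equal(residualize(mat, NULL), mat - rowMeans(mat), tolerance = 1e-12)
})

test_that("collinear covariates are dropped with a warning, not an error", {
  set.seed(8)
  v <- rnorm(20)
  cv <- structure(list(covariate_ids = c("c1", "c2"),
                       values = rbind(v, 2 * v), sample_ids = paste0("s", 1:20)),
                  class = "covariate_matrix")
  expect_warning(res <- residualize(matrix(rnorm(20), 1), cv), "collinear")
  expect_equal(ncol(res), 20)
})

test_that("correlation scan equals the direct per-pair formula", {
  sim <- make_sim(n_samples = 30, n_variants = 10, n_phenotypes = 1, seed = 21)
  y <- sim$p$values[1, ]
  sc <- correlation_scan(y, sim$g)
  naive <- apply(sim$g$dosages, 1, function(g_) {
    sum((g_ - mean(g_)) * (y - mean(y))) /
      sqrt(sum((g_ - mean(g_))^2) * sum((y - mean(y))^2))
  })
  expect_equal(sc$r_values, unname(naive), tolerance = 1e-12)
  expect_equal(sc$best_index, unname(which.max(abs(naive))))

  # a phenotype equal to a variant row is found with r = 1
  sc2 <- correlation_scan(sim$g$dosages[4, ], sim$g)
  expect_equal(sc2$best_index, 4L)
  expect_equal(sc2$r_values[4], 1, tolerance = 1e-12)

  expect_error(correlation_scan(rep(1, 30), sim$g), "zero-variance")
})

test_that("correlation P-values follow the t transform and its symmetries", {
  expect_equal(correlation_to_pvalue(0, 10), 1)
  expect_equal(correlation_to_pvalue(0.5, 10),
               2 * pt(0.5 * sqrt(10 / 0.75), 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(correlation_to_pvalue(0.5, 10), 0.097855, tolerance = 1e-4)
  expect_equal(correlation_to_pvalue(0.5, 10), correlation_to_pvalue(-0.5, 10))
  # monotone decreasing in |r|, and |r| = 1 stays positive
  rs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(correlation_to_pvalue(rs, 20)) <= 0))
  expect_gt(correlation_to_pvalue(1, 20), 0)
})

test_that("nominal P equals the OLS slope test and slope the sd-ratio identity", {
  set.seed(99)
  for (rep in 1:5) {
    sim <- make_sim(n_samples = 50, n_variants = 12, n_phenotypes = 1,
                    seed = 200 + rep)
    y <- sim$p$values[1, ]
    res <- nominal_pass(sim$p, sim$g, window = 1e6)[[1]]
    gbest <- sim$g$dosages[res$best_index, ]
    fit <- summary(lm(y ~ gbest))
    expect_equal(res$nominal_p, fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(res$slope, fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(res$slope, res$best_r * sd(y) / sd(gbest), tolerance = 1e-12)
  }
})

test_that("nominal P with covariates equals the multiple-regression slope test", {
  sim <- make_sim(n_samples = 60, n_variants = 10, n_phenotypes = 1,
                  n_covariates = 2, covariate_sd = 0.7, seed = 31)
  res <- nominal_pass(sim$p, sim$g, cov = sim$cov)[[1]]
  y <- sim$p$values[1, ]
  gbest <- sim$g$dosages[res$best_index, ]
  fit <- summary(lm(y ~ gbest + t(sim$cov$values)))
  expect_equal(res$nominal_p, fit$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(res$slope, fit$coefficients[2, 1], tolerance = 1e-8)
})

test_that("scan statistics are invariant under affine phenotype transforms", {
  sim <- make_sim(n_samples = 40, n_variants = 15, n_phenotypes = 1, seed = 55)
  y <- sim$p$values[1, ]
  a <- correlation_scan(y, sim$g)
  b <- correlation_scan(3 * y + 7, sim$g)
  d <- correlation_scan(-2 * y, sim$g)
  expect_equal(a$r_values, b$r_values, tolerance = 1e-12)
  expect_equal(a$r_values, -d$r_values, tolerance = 1e-12)
  expect_equal(a$best_index, d$best_index)
})

test_that("planted effects are located and their slopes recovered", {
  hits <- 0; within3 <- 0; n_rep <- 30
  for (rep in seq_len(n_rep)) {
    sim <- make_sim(n_samples = 80, n_variants = 30, n_phenotypes = 1,
                    effects = data.frame(phenotype = 1, variant = 12,
                                         slope = 1.5),
                    noise_sd = 0.5, seed = 400 + rep)
    res <- nominal_pass(sim$p, sim$g)[[1]]
    if (sim$g$variant_ids[res$best_index] == "var0012") hits <- hits + 1
    y <- sim$p$values[1, ]
    g12 <- sim$g$dosages[which(sim$g$variant_ids == "var0012"), ]
    se <- summary(lm(y ~ g12))$coefficients[2, 2]
    if (abs(res$slope - 1.5) <= 3 * se) within3 <- within3 + 1
  }
  expect_gte(hits, n_rep - 2)     # LD-free: the planted variant should win
  expect_gte(within3, n_rep - 2)  # 3-SE recovery, allowing rare excursions
})

test_that("phenotypes with an empty cis-window yield NA records", {
  sim <- make_sim(n_samples = 30, n_variants = 5, n_phenotypes = 1, seed = 61)
  sim$p$anchor <- sim$p$anchor + 10000000L
  res <- nominal_pass(sim$p, sim$g, window = 100)[[1]]
  expect_equal(res$n_tested, 0L)
  expect_true(is.na(res$nominal_p))
  expect_true(is.na(res$slope))
})

test_that("degrees of freedom account for residualized covariates", {
  sim <- make_sim(n_samples = 40, n_variants = 6, n_phenotypes = 1,
                  n_covariates = 3, seed = 71)
  adj <- nominal_pass(sim$p, sim$g, cov = sim$cov, df_policy = "adjusted")[[1]]
  leg <- nominal_pass(sim$p, sim$g, cov = sim$cov, df_policy = "legacy")[[1]]
  expect_equal(adj$df, 40 - 2 - 3)
  expect_equal(leg$df, 40 - 2)
  expect_gt(adj$nominal_p, leg$nominal_p)  # fewer df, less significance
})
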