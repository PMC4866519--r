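test_that("direct adjusted P follows (r+1)/(R+1) with its lower bound", {
  expect_identical(direct_adjusted_p(0, 999), 1e-3)
  expect_identical(direct_adjusted_p(999, 999), 1)
  expect_identical(direct_adjusted_p(49, 999), 0.05)
  expect_error(direct_adjusted_p(0, 0), "R")
  expect_error(direct_adjusted_p(10, 5))
})

test_that("permutation draws are reproducible and count ties as exceedances", {
  sim <- make_sim(n_samples = 40, n_variants = 8, n_phenotypes = 1, seed = 13)
  y <- residualize(sim$p$values[1, , drop = FALSE])[1, ]
  gs <- qtlperm:::std_rows(sim$g$dosages)
  a <- permute_and_scan(y, gs, R = 50, df = 38, nominal_p = 0.5, seed = 99)
  b <- permute_and_scan(y, gs, R = 50, df = 38, nominal_p = 0.5, seed = 99)
  expect_identical(a$null_pvalues, b$null_pvalues)
  expect_identical(a$r_exceed, b$r_exceed)
  expect_true(all(a$null_pvalues > 0 & a$null_pvalues <= 1))

  # a nominal P equal to a null P counts that permutation as an exceedance
  nom <- a$null_pvalues[7]
  c_ <- permute_and_scan(y, gs, R = 50, df = 38, nominal_p = nom, seed = 99)
  expect_gte(c_$r_exceed, 1L)
  expect_equal(c_$r_exceed, sum(a$null_pvalues <= nom))
})

test_that("single-variant null P-values are uniform (KS)", {
  set.seed(3)
  g1 <- matrix(rnorm(200), nrow = 1)
  gs <- qtlperm:::std_rows(g1)
  y <- rnorm(200)
  null <- permute_and_scan(y, gs, R = 400, df = 198, seed = 17)
  ks <- suppressWarnings(ks.test(null$null_pvalues, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong planted effect is never exceeded in 100 permutations", {
  sim <- make_sim(n_samples = 100, n_variants = 20, n_phenotypes = 1,
                  effects = data.frame(phenotype = 1, variant = 10, slope = 1.5),
                  noise_sd = 0.1, seed = 23)
  res <- full_permutation_pass(sim$p, sim$g, scheme = "direct", R = 100,
                               seed = 5)
  expect_equal(res$direct_perm_p, 1 / 101)
})

test_that("adaptive scheme enumerates correctly at B = M = 1 and stops early", {
  sim <- make_sim(n_samples = 30, n_variants = 5, n_phenotypes = 1, seed = 29)
  y <- residualize(sim$p$values[1, , drop = FALSE])[1, ]
  gs <- qtlperm:::std_rows(sim$g$dosages)
  for (s in 1:10) {
    out <- adaptive_adjusted_p(y, gs, nominal_p = 0.5, df = 28, B = 1, M = 1,
                               batch = 1, seed = s)
    expect_true(out$p_adj %in% c(1 / 2, 1))
    expect_equal(out$null$R, 1L)
  }
  # an insignificant hit reaches B quickly and stops well before M
  out <- adaptive_adjusted_p(y, gs, nominal_p = 0.9, df = 28, B = 10,
                             M = 10000, batch = 50, seed = 1)
  expect_lt(out$null$R, 1000)
  expect_gt(out$p_adj, 0.5)
})

test_that("adaptive and direct schemes agree within binomial sampling error", {
  sim <- make_sim(n_samples = 60, n_variants = 10, n_phenotypes = 1, seed = 37)
  prep <- qtlperm:::prepare_phenotype(sim$p$values[1, ], sim$g,
                                      sim$p$anchor[1], 1e6)
  scan <- qtlperm:::scan_one(prep, sim$g, "ph", sim$p$anchor[1])
  ad <- adaptive_adjusted_p(prep$y, prep$g_std, scan$nominal_p, prep$df,
                            B = 10, M = 1000, seed = 41)
  null <- permute_and_scan(prep$y, prep$g_std, R = 1000, df = prep$df,
                           nominal_p = scan$nominal_p, seed = 43)
  direct <- direct_adjusted_p(null$r_exceed, null$R)
  # the direct estimate must sit inside the adaptive run's own 99% binomial CI
  ci <- binom.test(min(ad$null$r_exceed, 10), ad$null$R,
                   conf.level = 0.99)$conf.int
  expect_gte(direct, ci[1])
  expect_lte(direct, ci[2] + 2 / ad$null$R)
})

test_that("beta ML fit recovers known shape parameters", {
  set.seed(51)
  p <- rbeta(1000, 1, 500)
  fit <- fit_beta_mle(p)
  # bounds ~ 4 x Fisher-information SE for Beta(1, 500) at R = 1000
  expect_true(fit$converged)
  expect_gt(fit$k_hat, 0.85); expect_lt(fit$k_hat, 1.15)
  expect_gt(fit$n_hat, 420);  expect_lt(fit$n_hat, 580)
  expect_gte(fit$loglik, fit$loglik_start)  # optimizer never degrades
})

test_that("minima of independent uniform batteries fit k near 1, n near L", {
  set.seed(53)
  L <- 100
  ks <- ns <- numeric(40)
  for (i in 1:40) {
    minima <- matrix(runif(300 * L), nrow = 300)
    minima <- apply(minima, 1, min)
    fit <- fit_beta_mle(minima)
    ks[i] <- fit$k_hat; ns[i] <- fit$n_hat
  }
  expect_equal(mean(ks), 1, tolerance = 0.05)
  expect_equal(median(ns), L, tolerance = 0.15)
})

test_that("beta fit input validation and degenerate samples error cleanly", {
  expect_error(fit_beta_mle(runif(5)), "at least 10")
  expect_silent(fit_beta_mle(rep(c(1e-320, 1 - 1e-17), 10)))
})

test_that("beta adjusted P is the fitted CDF with its closed-form k = 1 limit", {
  fit <- list(k_hat = 1, n_hat = 50)
  expect_equal(beta_adjusted_p(0.01, fit), 1 - 0.99^50, tolerance = 1e-12)
  expect_equal(beta_adjusted_p(0.01, fit), 0.39499, tolerance = 1e-4)
  expect_equal(beta_adjusted_p(0, fit), 0)
  expect_equal(beta_adjusted_p(1, fit), 1)

  # strictly increasing in the nominal P wherever the CDF is below saturation
  ps <- 10^seq(-12, -1.5, length.out = 40)
  expect_true(all(diff(beta_adjusted_p(ps, list(k_hat = 1.1, n_hat = 80))) > 0))

  # far-tail nominal P must not underflow to zero
  expect_gt(beta_adjusted_p(1e-200, list(k_hat = 1, n_hat = 1000)), 0)
  expect_equal(beta_adjusted_p(1e-200, list(k_hat = 1, n_hat = 1000), log.p = TRUE),
               log(1000) - 200 * log(10), tolerance = 1e-3)
})

test_that("full pass is deterministic and independent of phenotype order", {
  sim <- make_sim(n_samples = 50, n_variants = 12, n_phenotypes = 4, seed = 57)
  a <- full_permutation_pass(sim$p, sim$g, scheme = "beta", R = 100, seed = 2)
  b <- full_permutation_pass(sim$p, sim$g, scheme = "beta", R = 100, seed = 2)
  expect_identical(a, b)

  rev_p <- sim$p
  idx <- rev(seq_along(rev_p$phenotype_ids))
  rev_p$phenotype_ids <- rev_p$phenotype_ids[idx]
  rev_p$chrom <- rev_p$chrom[idx]; rev_p$start <- rev_p$start[idx]
  rev_p$end <- rev_p$end[idx]; rev_p$anchor <- rev_p$anchor[idx]
  rev_p$values <- rev_p$values[idx, , drop = FALSE]
  c_ <- full_permutation_pass(rev_p, sim$g, scheme = "beta", R = 100, seed = 2)
  expect_equal(c_[order(c_$phenotype_id), ], a[order(a$phenotype_id), ],
               ignore_attr = TRUE)
})

test_that("the planted phenotype earns the smallest adjusted P of its set", {
  sim <- make_sim(n_samples = 100, n_variants = 30, n_phenotypes = 10,
                  effects = data.frame(phenotype = 4, variant = 15, slope = 1),
                  noise_sd = 0.5, seed = 59)
  res <- full_permutation_pass(sim$p, sim$g, scheme = "beta", R = 200, seed = 3)
  expect_equal(res$phenotype_id[which.min(res$beta_perm_p)], "pheno004")
  expect_equal(res$best_variant_id[res$phenotype_id == "pheno004"], "var0015")
})

test_that("LD shrinks the fitted effective number of tests below L", {
  n_ph <- 12
  fit_ns <- function(rho, seed0) {
    vapply(seq_len(n_ph), function(i) {
      sim <- make_sim(n_samples = 150, n_variants = 40, n_phenotypes = 1,
                      ld_rho = rho, seed = seed0 + i)
      res <- full_permutation_pass(sim$p, sim$g, scheme = "beta", R = 300,
                                   seed = 7)
      res$n_hat / res$n_variants_tested
    }, numeric(1))
  }
  ratio_ld <- fit_ns(0.9, 700)
  ratio_free <- fit_ns(0, 800)
  expect_lt(median(ratio_ld), 0.6)          # strong LD: far fewer effective tests
  expect_gt(median(ratio_free), 0.75)       # independent variants: n-hat near L
  expect_lt(median(ratio_ld), median(ratio_free))
})
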