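test_that("retention arithmetic and reproducibility of the chain", {
  set.seed(1)
  n <- 60
  F <- cbind(mu = rep(1, n))
  X <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  y <- rnorm(n)
  cfg <- model_config(chain_length = 3000, burn_in = 500, thin = 25,
                      seed = 4, trait_type = "continuous")
  fit <- fit_bayesb(y, F, H = NULL, X = X, config = cfg)
  expect_equal(fit$n_retained, (3000 - 500) %/% 25)   # = 100
  expect_equal(nrow(fit$fixed_draws), 100L)

  fit2 <- fit_bayesb(y, F, H = NULL, X = X, config = cfg)
  expect_identical(fit$fixed_draws, fit2$fixed_draws)
  expect_identical(fit$snp_draws, fit2$snp_draws)

  # the full-scale protocol retains floor((90000 - 2000) / 100) draws
  big <- model_config(chain_length = 90000, burn_in = 2000, thin = 100,
                      seed = 1)
  expect_equal((big$chain_length - big$burn_in) %/% big$thin, 880L)
})

test_that("a constant response yields null SNP effects and the constant", {
  set.seed(2)
  n <- 80
  F <- cbind(mu = rep(1, n))
  X <- matrix(rbinom(n * 40, 2, 0.4), n, 40)
  y <- rep(5, n)
  cfg <- model_config(chain_length = 2000, burn_in = 500, thin = 5,
                      seed = 7, trait_type = "continuous")
  fit <- fit_bayesb(y, F, H = NULL, X = X, config = cfg)
  expect_lt(max(abs(colMeans(fit$snp_draws))), 1e-3)
  expect_lt(abs(mean(fit$fixed_draws[, "mu"]) - 5), 1e-3)
})

test_that("a planted SNP effect matches its least-squares estimate", {
  set.seed(3)
  n <- 500; p <- 200
  X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)[rep(1:p, each = n)]),
              n, p)
  beta <- 0.5; j <- 42
  y <- X[, j] * beta + rnorm(n, 0, 1)
  F <- cbind(mu = rep(1, n))
  cfg <- model_config(chain_length = 6000, burn_in = 1000, thin = 5,
                      seed = 12, trait_type = "continuous")
  fit <- fit_bayesb(y, F, H = NULL, X = X, config = cfg)
  ols <- unname(coef(lm(y ~ X[, j]))[2L])        # single-marker oracle
  post_mean <- mean(fit$snp_draws[, j])
  post_sd <- sd(fit$snp_draws[, j])
  expect_lt(abs(post_mean - ols), 2 * post_sd)
  # the planted locus dominates the posterior inclusion profile
  expect_equal(which.max(fit$delta_mean), j)
})

test_that("with pi near 1 the fixed effects converge to least squares", {
  set.seed(4)
  n <- 300
  cg <- factor(rep(1:3, each = 100))
  F <- model.matrix(~ 0 + cg)
  age <- rnorm(n)
  F <- cbind(F, age = age)
  H <- matrix(rbinom(n * 3, 1, 0.4), n, 3,
              dimnames = list(NULL, c("1", "2", "3")))
  X <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
  y <- F %*% c(1, 2, 3, 0.5) + H %*% c(0, 1, -1) + rnorm(n)
  cfg <- model_config(pi = 1 - 1e-9, chain_length = 4000, burn_in = 1000,
                      thin = 5, seed = 5, trait_type = "continuous")
  fit <- fit_bayesb(y, F, H, X, cfg)
  ols <- lm(y ~ 0 + cbind(F, H[, -1L]))
  comb <- cbind(fit$fixed_draws, fit$hap_draws[, -1L, drop = FALSE])
  post <- colMeans(comb)
  psd <- apply(comb, 2, sd)
  expect_true(all(abs(post - coef(ols)) < 4 * psd))
  # no SNP ever enters the model at this pi
  expect_equal(max(fit$delta_mean), 0)
})

test_that("posterior inclusion of null SNPs tracks 1 - pi", {
  set.seed(6)
  n <- 150; p <- 400
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  y <- rnorm(n)
  cfg <- model_config(pi = 0.99, chain_length = 3000, burn_in = 1000,
                      thin = 5, seed = 8, trait_type = "continuous")
  fit <- fit_bayesb(y, cbind(mu = rep(1, n)), NULL, X, cfg)
  expect_lt(abs(mean(fit$delta_mean) - 0.01), 0.01)
})

test_that("liability draws respect the threshold in every retained draw", {
  set.seed(9)
  n <- 120
  X <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  eta <- 0.8 * scale(X[, 5])[, 1]
  y <- as.integer(eta + rnorm(n) > 0)
  cfg <- model_config(chain_length = 1500, burn_in = 500, thin = 10,
                      seed = 10, trait_type = "binary")
  fit <- fit_bayesb(y, cbind(mu = rep(1, n)), NULL, X, cfg,
                    keep_liab = TRUE)
  expect_equal(fit$sigma_e_draws, rep(1, fit$n_retained))  # fixed at 1
  L <- fit$liab_draws
  for (r in seq_len(nrow(L))) {
    expect_true(all(L[r, y == 1] > 0))
    expect_true(all(L[r, y == 0] <= 0))
  }
})

test_that("rank-deficient fixed designs are rejected with the culprits named", {
  n <- 40
  F <- cbind(a = rep(1, n), b = rep(1, n))   # aliased
  X <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  cfg <- model_config(seed = 2, trait_type = "continuous")
  expect_error(fit_bayesb(rnorm(n), F, NULL, X, cfg), "rank deficient")
})

test_that("posterior summaries agree with direct order statistics", {
  draws <- matrix(c(rep(4, 100), 1:100), ncol = 2,
                  dimnames = list(NULL, c("const", "ramp")))
  s <- posterior_summary(draws)
  expect_equal(unname(s["const", "mean"]), 4)
  expect_equal(unname(s["const", "sd"]), 0)
  expect_equal(unname(s["ramp", "mean"]), 50.5)
  sorted <- sort(draws[, "ramp"])
  # type-1 quantile: smallest order statistic with F(x) >= p
  expect_equal(unname(s["ramp", "q05"]), sorted[ceiling(0.05 * 100)])
  expect_equal(unname(s["ramp", "q95"]), sorted[ceiling(0.95 * 100)])
  expect_error(posterior_summary(draws[1:5, , drop = FALSE]),
               "at least 10")
})
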