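# Growth statistics: age interpolation, Gompertz fits, beta regression,
# Pearson correlation.

test_that("age interpolation is linear between the anchors and refuses to extrapolate", {
  a <- mass_age_anchors(c(1, 42), c(55, 2300))
  expect_equal(interpolate_age(55, a), 1)
  expect_equal(interpolate_age(2300, a), 42)
  expect_equal(interpolate_age((55 + 2300) / 2, a), 21.5)
  expect_error(interpolate_age(2301, a), "out of range")
  expect_error(interpolate_age(54, a), "out of range")
  masses <- seq(55, 2300, length.out = 20)
  expect_true(all(diff(interpolate_age(masses, a)) > 0))  # monotone
  expect_error(mass_age_anchors(c(1, 42), c(100, 50)), "increasing")
})

test_that("duck age classes follow the juvenile / sub-adult / adult bounds", {
  expect_identical(age_class(c(1, 42, 43, 182, 200), "duck"),
                   c("juvenile", "juvenile", "sub-adult", "sub-adult",
                     "adult"))
  expect_identical(age_class(c(15, 42), "pheasant"),
                   c("juvenile", "juvenile"))
})

test_that("noise-free Gompertz data are recovered to 1e-4 relative", {
  t <- seq(0, 60, length.out = 20)
  y <- 100 * exp(-4 * exp(-0.1 * t))
  fit <- fit_gompertz(t, y)
  cf <- coef(fit)
  expect_lt(abs(cf[["A"]] - 100) / 100, 1e-4)
  expect_lt(abs(cf[["b"]] - 4) / 4, 1e-4)
  expect_lt(abs(cf[["k"]] - 0.1) / 0.1, 1e-4)
})

test_that("growth-rate curve has the closed-form maximum", {
  cf <- c(A = 100, b = 4, k = 0.1)
  tt <- seq(0, 60, by = 0.001)
  rates <- growth_rate(cf, tt)
  expect_lt(abs(tt[which.max(rates)] - log(4) / 0.1), 0.002)
  expect_lt(abs(max(rates) - 100 * 0.1 / exp(1)), 1e-6)
  expect_true(all(rates >= 0))
  expect_lt(growth_rate(cf, 1e4), 1e-12)
  # fitted object carries the same quantities
  t <- seq(0, 60, length.out = 15)
  fit <- fit_gompertz(t, 100 * exp(-4 * exp(-0.1 * t)))
  expect_equal(fit$t_infl, log(coef(fit)[["b"]]) / coef(fit)[["k"]])
  expect_equal(fit$max_rate, coef(fit)[["A"]] * coef(fit)[["k"]] / exp(1))
})

test_that("degenerate growth data raise fit errors", {
  expect_error(fit_gompertz(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_gompertz(1:10, rep(5, 10)), "constant")
  expect_error(fit_gompertz(1:10, c(-1, 2:10)), "positive")
})

test_that("the fitted Gompertz curve is monotone and the band covers it", {
  t <- seq(0, 50, length.out = 25)
  set.seed(8)
  y <- 80 * exp(-3 * exp(-0.12 * t)) * exp(rnorm(25, 0, 0.02))
  fit <- fit_gompertz(t, y)
  tt <- seq(0, 50, by = 0.5)
  pred <- predict(fit, tt, interval = "confidence")
  expect_true(all(diff(pred[, "fit"]) > 0))
  expect_true(all(pred[, "lwr"] <= pred[, "fit"]))
  expect_true(all(pred[, "upr"] >= pred[, "fit"]))
})

test_that("beta regression matches an independent likelihood maximiser", {
  skip_if_not_installed("glmmTMB")
  set.seed(2)
  n <- 200
  x <- runif(n)
  mu <- plogis(-1 + 2 * x)
  y <- rbeta(n, mu * 50, (1 - mu) * 50)
  d <- data.frame(y = y, x = x)
  fit <- beta_reg(y ~ x, d)
  ref <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::beta_family("logit"),
                          data = d)
  expect_equal(unname(coef(fit)), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-4)
  expect_equal(fit$phi, glmmTMB::sigma(ref), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("intercept-only fit matches the profile-likelihood grid oracle", {
  set.seed(3)
  y <- rbeta(80, 2, 5)
  fit <- beta_reg(y ~ 1, data.frame(y = y))
  mu_hat <- plogis(coef(fit)[[1]])
  expect_lt(abs(mu_hat - beta_intercept_oracle(y)), 1e-3)
})

test_that("simulated beta-regression parameters are recovered within 3 sigma", {
  set.seed(17)
  n <- 500
  x <- runif(n, 0, 10)
  mu <- plogis(-1 + 0.05 * x)
  y <- rbeta(n, mu * 50, (1 - mu) * 50)
  fit <- beta_reg(y ~ x, data.frame(y = y, x = x))
  se <- sqrt(diag(fit$vcov))[1:2]
  expect_lt(abs(coef(fit)[[1]] - (-1)) / se[1], 3)
  expect_lt(abs(coef(fit)[[2]] - 0.05) / se[2], 3)
  # ML optimality: fitted log-likelihood at least that of the truth
  ll_true <- sum(dbeta(y, mu * 50, (1 - mu) * 50, log = TRUE))
  expect_gte(fit$logLik, ll_true - 1e-6)
})

test_that("pseudo R-squared approaches 1 in the noise-free limit", {
  set.seed(5)
  n <- 100
  x <- seq(0, 1, length.out = n)
  mu <- plogis(-2 + 4 * x)
  y <- rbeta(n, mu * 1e4, (1 - mu) * 1e4)
  fit <- beta_reg(y ~ x, data.frame(y = y, x = x))
  expect_gte(fit$pseudo_r2, 0.999)
})

test_that("pseudo R-squared is invariant to affine covariate rescaling", {
  set.seed(6)
  n <- 120
  x <- runif(n)
  mu <- plogis(-0.5 + 1.5 * x)
  y <- rbeta(n, mu * 40, (1 - mu) * 40)
  f1 <- beta_reg(y ~ x, data.frame(y = y, x = x))
  f2 <- beta_reg(y ~ x2, data.frame(y = y, x2 = 100 * x - 7))
  expect_equal(f1$pseudo_r2, f2$pseudo_r2, tolerance = 1e-6)
})

test_that("boundary proportions are shrunk, invalid ones rejected", {
  y <- c(0, 0.2, 0.5, 0.9, 1)
  expect_message(fit <- beta_reg(y ~ 1, data.frame(y = y)), "shrunk")
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  expect_error(beta_reg(y ~ 1, data.frame(y = c(0.2, 1.3))), "\\[0, 1\\]")
})

test_that("likelihood-ratio test behaves at its boundaries", {
  set.seed(7)
  y <- rbeta(60, 3, 4)
  x <- runif(60)
  d <- data.frame(y = y, x = x)
  full <- beta_reg(y ~ x, d)
  null <- beta_reg(y ~ 1, d)
  lt <- lr_test(full, null)
  expect_gte(lt$statistic, 0)
  expect_identical(lt$df, 1L)
  self <- lr_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  expect_error(lr_test(null, full), "nested")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(3, 10)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("permutation p-values agree with the analytic Pearson test", {
  set.seed(19)
  x <- rnorm(10)
  y <- 0.6 * x + rnorm(10, 0, 0.8)
  res <- pearson_r(x, y)
  nperm <- 4000
  robs <- abs(cor(x, y))
  rperm <- replicate(nperm, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(rperm >= robs)) / (nperm + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_perm - res$p.value), max(0.02, 4 * mc_se))
})
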