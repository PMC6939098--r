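test_that("squeeze transform: fixed point, examples, and affine order preservation", {
  expect_equal(squeeze_transform(0.5, n = 17), 0.5)
  expect_equal(squeeze_transform(0, n = 533), 0.5 / 533, tolerance = 1e-12)
  expect_equal(squeeze_transform(0, n = 2), 0.25)
  y <- c(0, 0.001, 0.2, 0.7, 0.99)
  s <- squeeze_transform(y, n = 100)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) > 0))
  # affine: equal spacing preserved up to a common factor
  expect_equal(diff(s) / diff(y), rep((100 - 1) / 100, 4), tolerance = 1e-12)
  expect_error(squeeze_transform(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(squeeze_transform(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  # a=10 (x=0,y=1), b=20 (x=0,y=0), c=30 (x=1,y=1), d=40 (x=1,y=0)
  df <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 20, 30, 40)),
                   x = rep(c(0, 0, 1, 1), c(10, 20, 30, 40)))
  fit <- fit_logistic(df, "y", "x", covariates = character())
  # OR on the original binary scale: estimate is per-SD, rescale by sd(x)
  or_raw <- exp(fit$effect$estimate / stats::sd(df$x))
  expect_equal(or_raw, (30 / 40) / (10 / 20), tolerance = 1e-6)
})

test_that("logistic degenerate outcomes and separation raise errors", {
  df <- data.frame(y = rep(0, 50), x = rnorm(50))
  expect_error(fit_logistic(df, "y", "x", covariates = character()),
               "degenerate")
  sep <- data.frame(y = rep(c(0, 1), each = 25), x = c(rnorm(25), 10 + rnorm(25)))
  expect_error(fit_logistic(sep, "y", "x", covariates = character()),
               "separation")
})

test_that("linear model: perfect fit, permutation null, rank deficiency", {
  df <- data.frame(y = 1:40 + 0, x = 1:40 + 0)
  fit <- suppressWarnings(fit_linear(df, "y", "x", covariates = character()))
  expect_equal(fit$effect$estimate, 1, tolerance = 1e-10)  # standardized
  expect_lt(fit$effect$ci_hi - fit$effect$ci_lo, 1e-8)
  set.seed(30)
  df2 <- data.frame(y = rnorm(200), x = rnorm(200))
  f2 <- fit_linear(df2, "y", "x", covariates = character())
  expect_true(f2$effect$ci_lo < 0 && f2$effect$ci_hi > 0)
  df3 <- data.frame(y = rnorm(20), x = rnorm(20))
  df3$x2 <- df3$x
  expect_error(fit_linear(df3, "y", "x", covariates = "x2"), "rank")
})

test_that("beta regression: symmetric intercept-only fit and optimality", {
  set.seed(31)
  y <- rbeta(400, 5, 5)  # symmetric around 0.5
  df <- data.frame(y = y, x = rnorm(400))
  fit <- fit_beta_regression(df, "y", "x", covariates = character())
  b0 <- fit$coefficients[fit$coefficients$term == "(Intercept)", ]
  expect_lt(abs(b0$estimate), 2 * b0$se + 0.05)
  # optimality: the reported optimum beats a +/-0.05 grid perturbation
  X <- cbind(1, scale(df$x)[, 1])
  ll <- function(b) -pvsmorph:::betareg_nll(c(b, log(fit$phi)), y, X)
  bhat <- fit$coefficients$estimate[1:2]
  for (d1 in c(-0.05, 0.05)) for (d2 in c(-0.05, 0, 0.05))
    expect_gte(ll(bhat), ll(bhat + c(d1, d2)) - 1e-9)
})

test_that("beta regression recovers simulated coefficients", {
  errs <- phis <- c()
  for (seed in 1:3) {
    set.seed(seed)
    n <- 2000
    x <- rnorm(n); xs <- (x - mean(x)) / sd(x)
    mu <- plogis(-2 + 0.4 * xs)
    y <- rbeta(n, mu * 10, (1 - mu) * 10)
    df <- data.frame(y = y, x = x)
    fit <- fit_beta_regression(df, "y", "x", covariates = character())
    errs <- c(errs, fit$effect$estimate - 0.4)
    phis <- c(phis, fit$phi)
  }
  expect_lt(max(abs(errs)), 0.1)
  expect_lt(abs(mean(phis) - 10) / 10, 0.2)
})

test_that("beta regression refuses boundary responses with guidance", {
  df <- data.frame(y = c(0, runif(50, 0.1, 0.9)), x = rnorm(51))
  expect_error(fit_beta_regression(df, "y", "x", covariates = character()),
               "squeeze_transform")
})

test_that("polyserial correlation: null, recovery, and attenuation ordering", {
  set.seed(33)
  n <- 5000
  # null
  r0 <- polyserial_corr(sample(0:4, n, TRUE), rnorm(n))
  expect_lt(abs(r0$rho), 0.03)
  # latent rho = 0.6 discretized to 5 levels
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  ordv <- findInterval(z2, cuts)
  ps <- polyserial_corr(ordv, z1)
  expect_lt(abs(ps$rho - 0.6), 0.05)
  expect_true(ps$ci[1] < 0.6 && ps$ci[2] > 0.6 - 0.05)
  # polyserial exceeds the attenuated Pearson on the discretized data
  expect_gt(ps$rho, pearson_corr(z1, ordv)$r)
  expect_error(polyserial_corr(rep(2, 100), rnorm(100)), "2 observed levels")
})

test_that("pearson, welch and chi-squared behave on the canonical cases", {
  x <- rnorm(50)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "zero-variance")
  w <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(w$t, 0, tolerance = 1e-12)
  # 2x2 table (10,20,30,40): chi-squared without correction = 0.7937
  tab <- matrix(c(10, 30, 20, 40), 2)
  cs <- chi_sq(tab, correct = FALSE)
  expect_equal(cs$chisq, 100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-10)
  expect_equal(cs$chisq, 0.7937, tolerance = 1e-4)
  expect_length(cs$prop_diff_ci, 2)
})

test_that("model comparison: identity, BIC penalty, mismatched n", {
  set.seed(34)
  df <- data.frame(y = rnorm(1000), x = rnorm(1000), junk = rnorm(1000))
  f1 <- fit_linear(df, "y", "x", covariates = character())
  f2 <- fit_linear(df, "y", "x", covariates = "junk")
  cmpsame <- compare_models(list(ref = f1, same = f1))
  expect_equal(cmpsame$dAIC[2], 0)
  expect_equal(cmpsame$dBIC[2], 0)
  expect_false(cmpsame$practical_improvement[2])
  # one pure-noise extra parameter costs ~ln(n) of BIC
  cmp2 <- compare_models(list(ref = f1, bigger = f2))
  expect_equal(cmp2$dBIC[2], log(1000), tolerance = 1.5)
  f3 <- fit_linear(df[1:500, ], "y", "x", covariates = character())
  expect_error(compare_models(list(f1, f3)), "sample sizes")
})

test_that("covariate exclusion rule drops the outcome from its own covariates", {
  expect_identical(covariates_for("hypertension"), c("age", "sex"))
  expect_identical(covariates_for("age"), c("sex", "hypertension"))
  expect_identical(covariates_for("stroke"), c("age", "sex", "hypertension"))
})

test_that("designed simulation flags the size model over the count model", {
  # WMH depends on PVS size directly; count is only a noisy proxy of size
  hits <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    set.seed(200 + seed)
    n <- 533
    size <- rnorm(n)
    count <- 0.5 * size + sqrt(1 - 0.25) * rnorm(n)
    mu <- plogis(-4.6 + 0.43 * size)
    df <- data.frame(pvs_mean_size = size, pvs_count = count,
                     wmh = rbeta(n, mu * 50, (1 - mu) * 50))
    fsize <- fit_beta_regression(df, "wmh", "pvs_mean_size",
                                 covariates = character())
    fcount <- fit_beta_regression(df, "wmh", "pvs_count",
                                  covariates = character())
    cmp <- compare_models(list(count = fcount, size = fsize),
                          reference = "count")
    if (cmp$practical_improvement[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.8)
})
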