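# z-scaling, collinearity screen, flat-prior fits, Bayes factors, temporal
# scale selection, and evidence classification.

test_that("zscale standardizes and errors on constant columns", {
  z <- zscale(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  set.seed(1)
  x <- rnorm(200, 5, 3)
  z <- zscale(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  z2 <- zscale(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  expect_error(zscale(rep(3, 10), "crown"), "crown")
})

test_that("collinearity screen flags |r| at the threshold and spares independence", {
  set.seed(2)
  x <- rnorm(100)
  m <- cbind(a = x, b = 2 * x, c = -x, d = rnorm(100))
  fl <- collinearity_screen(m)
  key <- paste(fl$var1, fl$var2)
  expect_true(all(c("a b", "a c", "b c") %in% key))
  expect_equal(fl$r[key == "a b"], 1)
  expect_equal(fl$r[key == "a c"], -1)
  expect_false(any(grepl("d", key)))
  big <- matrix(rnorm(1e4 * 4), ncol = 4,
                dimnames = list(NULL, letters[1:4]))
  expect_equal(nrow(collinearity_screen(big)), 0)
})

test_that("noiseless data recover the exact coefficients", {
  tab <- toy_model_table(sigma = 0)
  fit <- fit_flat_prior_lm(tab, c("x1", "x2", "x3"))
  expect_equal(unname(fit$beta_hat), c(6, 0.5, -0.8, 0.3), tolerance = 1e-10)
})

test_that("flat-prior posterior means equal the least-squares solution", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    p <- sample(1:5, 1)
    tab <- data.frame(matrix(rnorm(n * p), n))
    names(tab) <- paste0("x", 1:p)
    tab$nocturnality <- rnorm(n, 6, 2)
    fit <- fit_flat_prior_lm(tab, paste0("x", 1:p), scale_predictors = FALSE)
    X <- cbind(1, as.matrix(tab[paste0("x", 1:p)]))
    expect_equal(unname(fit$beta_hat), oracle_ols(X, tab$nocturnality),
                 tolerance = 1e-8)
  }
})

test_that("rank deficiency and tiny samples raise informative errors", {
  tab <- toy_model_table(n = 30)
  tab$x_dup <- tab$x1 * 2
  expect_error(fit_flat_prior_lm(tab, c("x1", "x_dup"), "nocturnality"),
               "singular")
  expect_error(fit_flat_prior_lm(tab[1:3, ], c("x1", "x2", "x3")),
               "insufficient")
})

test_that("the Gibbs sampler agrees with the analytic posterior and converges", {
  tab <- toy_model_table(n = 150)
  an <- fit_flat_prior_lm(tab, c("x1", "x2", "x3"))
  sa <- fit_flat_prior_lm(tab, c("x1", "x2", "x3"), method = "sampling",
                          chains = 4, iterations = 6000, burn_in = 1000,
                          seed = 123)
  expect_true(all(sa$rhat < 1.1))
  n_draws <- nrow(sa$draws)
  for (j in seq_along(an$beta_hat)) {
    s <- sd(sa$draws[, j])
    expect_lt(abs(mean(sa$draws[, j]) - an$beta_hat[j]),
              5 * s / sqrt(n_draws))
    # 97.5% quantile MC se is about 2.7 * sd / sqrt(n) for a t-like marginal
    ci_a <- credible_interval(an, 0.95, names(an$beta_hat)[j])
    ci_s <- credible_interval(sa, 0.95, names(an$beta_hat)[j])
    expect_lt(max(abs(ci_a - ci_s)), 3 * 2.7 * s / sqrt(n_draws))
  }
})

test_that("credible intervals are symmetric, nested, and match t quantiles", {
  tab <- toy_model_table(n = 60)
  fit <- fit_flat_prior_lm(tab, c("x1", "x2", "x3"))
  for (cf in c("x1", "x2")) {
    ci90 <- credible_interval(fit, 0.90, cf)
    ci95 <- credible_interval(fit, 0.95, cf)
    j <- match(cf, names(fit$beta_hat))
    expect_equal(mean(ci90), unname(fit$beta_hat[j]), tolerance = 1e-10)
    expect_true(ci95[1] < ci90[1] && ci90[2] < ci95[2])
    # independent quantile arithmetic
    expect_equal(unname(ci95),
                 unname(fit$beta_hat[j] + qt(c(0.025, 0.975), fit$df) *
                          fit$se[j]), tolerance = 1e-12)
  }
  expect_error(credible_interval(fit, 0.9, "nope"), "unknown")
})

test_that("the Bayes factor matches the BIC arithmetic on a toy table", {
  tab <- data.frame(nocturnality = c(5.1, 6.2, 7.3, 6.8, 5.9, 7.7),
                    x = c(0.2, 0.5, 0.9, 0.8, 0.4, 1.0))
  got <- bayes_factor_vs_null(tab, "x")
  # independent arithmetic: BIC = n log(2 pi rss/n) + n + k log n
  y <- tab$nocturnality
  z <- (tab$x - mean(tab$x)) / sd(tab$x)
  f <- lm(y ~ z)
  rss1 <- sum(resid(f)^2)
  rss0 <- sum((y - mean(y))^2)
  n <- 6
  bic1 <- n * (log(2 * pi * rss1 / n) + 1) + 3 * log(n)
  bic0 <- n * (log(2 * pi * rss0 / n) + 1) + 2 * log(n)
  expect_equal(got, exp((bic0 - bic1) / 2), tolerance = 1e-10)
})

test_that("Bayes factors separate signal from noise", {
  set.seed(31)
  bf_null <- replicate(200, {
    tab <- data.frame(nocturnality = rnorm(10000), x = rnorm(10000))
    bayes_factor_vs_null(tab, "x")
  })
  expect_gte(mean(bf_null < 1), 0.95)
  bf_alt <- replicate(100, {
    x <- rnorm(500)
    tab <- data.frame(nocturnality = x + rnorm(500), x = x)
    bayes_factor_vs_null(tab, "x")
  })
  expect_gte(mean(bf_alt > 1), 0.99)
})

test_that("scale selection takes the best scale only when its BF exceeds 1", {
  set.seed(12)
  n <- 800
  zs <- matrix(rnorm(3 * n), n,
               dimnames = list(NULL, c("daily_count", "weekly_rate",
                                       "monthly_rate")))
  tab <- data.frame(zs, nocturnality = 6 + 0.5 * zs[, "weekly_rate"] +
                      rnorm(n, 0, 2))
  sel <- scale_analysis(tab, species = "sp")
  expect_s3_class(sel, "scale_selection")
  expect_equal(sel$chosen, "weekly")
  expect_equal(unname(sel$bayes_factors["weekly"]),
               max(sel$bayes_factors))
  # pure noise at large n: every BF below 1 -> no human term
  tab0 <- data.frame(zs, nocturnality = rnorm(n, 6, 2))
  expect_equal(scale_analysis(tab0)$chosen, "none")
  # deterministic tie-break: identical columns resolve daily > weekly
  tabt <- data.frame(daily_count = zs[, 1], weekly_rate = zs[, 1],
                     monthly_rate = rnorm(n),
                     nocturnality = 6 + 0.5 * zs[, 1] + rnorm(n, 0, 2))
  expect_equal(scale_analysis(tabt)$chosen, "daily")
})

# a flatfit with prescribed marginals, for checking classification logic
# against printed interval endpoints
fake_fit <- function(mean, se, df = 30) {
  structure(list(beta_hat = c(b = mean), se = c(b = se), df = df,
                 method = "analytic", ci_levels = c(0.90, 0.95),
                 draws = NULL), class = "flatfit")
}

test_that("evidence tiers reproduce the printed interval classifications", {
  # 95% CI = (0.46, 1.17): strong positive
  f <- fake_fit(0.815, (1.17 - 0.46) / 2 / qt(0.975, 30))
  cl <- classify_evidence(f, "b")
  expect_equal(cl$tier, "strong")
  expect_equal(cl$sign, "positive")
  expect_equal(unname(cl$ci95), c(0.46, 1.17), tolerance = 1e-10)
  # 90% CI = (0.04, 0.65) with the 95% CI straddling zero: moderate positive
  f <- fake_fit(0.345, (0.65 - 0.04) / 2 / qt(0.95, 30))
  cl <- classify_evidence(f, "b")
  expect_equal(cl$tier, "moderate")
  expect_equal(cl$sign, "positive")
  expect_lt(cl$ci95[1], 0)
  expect_equal(unname(cl$ci90), c(0.04, 0.65), tolerance = 1e-10)
  # 90% CI = (-0.1, 0.2): no clear evidence
  f <- fake_fit(0.05, (0.2 + 0.1) / 2 / qt(0.95, 30))
  expect_equal(classify_evidence(f, "b")$tier, "none")
})

test_that("a 90% CI excluding zero implies sign probability of at least 0.95", {
  f <- fake_fit(0.345, (0.65 - 0.04) / 2 / qt(0.95, 30))
  expect_gte(posterior_sign_probability(f, "b"), 0.95)
})

test_that("true effects are promoted, never demoted, as samples grow", {
  set.seed(55)
  prop_evidence <- vapply(c(100, 500, 2000), function(n) {
    hits <- replicate(30, {
      x <- rnorm(n)
      tab <- data.frame(nocturnality = 6 + 0.25 * scale(x)[, 1] +
                          rnorm(n, 0, 2), x = x)
      fit <- fit_flat_prior_lm(tab, "x")
      fit$coefficients$evidence[2] != "none"
    })
    mean(hits)
  }, 0)
  expect_gte(prop_evidence[3], prop_evidence[1])
  expect_gte(prop_evidence[3], 0.9)  # beta 0.25, sigma 2, n 2000: t ~ 5.6
})
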