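test_that("single-covariate fit reproduces the closed-form simple regression test", {
  set.seed(9)
  n <- 40
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  fit <- fit_glm(data.frame(y = y, x = x), "y", "x")
  # closed form: F = r^2 (n-2) / (1 - r^2)
  r2 <- cor(x, y)^2
  expect_equal(fit$anova["x", "F value"], r2 * (n - 2) / (1 - r2),
               tolerance = 1e-10)
  b <- bf_ols(cbind(1, x), y)
  expect_equal(unname(fit$coefficients), as.vector(b), tolerance = 1e-10)
})

test_that("balanced two-group fit equals the pooled-variance t-test squared", {
  set.seed(10)
  g <- factor(rep(c("A", "H"), each = 15))
  y <- rnorm(30) + 0.8 * (g == "H")
  fit <- fit_glm(data.frame(y = y, g = g), "y", "g")
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(fit$anova["g", "F value"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(term_p(fit, "g"), tt$p.value, tolerance = 1e-10)
})

test_that("sequential SS decomposition sums to total SS and matches normal equations", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(20:50, 1)
    d <- data.frame(y = rnorm(n), x = rnorm(n),
                    f = factor(sample(letters[1:3], n, replace = TRUE)),
                    g = factor(sample(c("A", "H"), n, replace = TRUE)))
    fit <- fit_glm(d, "y", c("x", "f", "g"))
    tot <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$anova[, "Sum Sq"]), tot, tolerance = 1e-8 * tot)
    X <- model.matrix(~ x + f + g, d)
    b <- bf_ols(X, d$y)
    expect_equal(unname(fit$coefficients), as.vector(b), tolerance = 1e-8)
    # sequential property: each term's SS is the drop in residual SS
    rss0 <- sum(lm(y ~ x + f, d)$residuals^2)
    rss1 <- sum((d$y - X %*% b)^2)
    expect_equal(fit$anova["g", "Sum Sq"], rss0 - rss1, tolerance = 1e-8)
  }
})

test_that("genotype p-values are uniform under a simulated null", {
  set.seed(77)
  ps <- replicate(300, {
    d <- data.frame(y = rnorm(40), x = rnorm(40),
                    g = factor(sample(c("A", "H"), 40, replace = TRUE)))
    term_p(fit_glm(d, "y", c("x", "g")), "g")
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("degenerate designs are handled: single-level terms drop, rank deficiency flags", {
  d <- data.frame(y = rnorm(20), x = rnorm(20), f = factor(rep("a", 20)),
                  g = factor(rep(c("A", "H"), 10)))
  expect_warning(fit <- fit_glm(d, "y", c("x", "f", "g")), "fewer than 2")
  expect_true("f" %in% fit$dropped)
  d2 <- data.frame(y = rnorm(20), f = factor(rep(c("a", "b"), each = 10)),
                   g = factor(rep(c("A", "H"), each = 10)))  # g aliased with f
  expect_warning(fit2 <- fit_glm(d2, "y", c("f", "g")), "rank-deficient")
  expect_true(fit2$aliased)
})

test_that("Cohen's D matches its formula and handles the stated cases", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0, 1, 2); h <- c(1, 2, 3)  # means 1 and 2, both SD = 1
  expect_equal(cohens_d(a, h), 1)
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(9, 1)
    sp <- sqrt((7 * var(x) + 8 * var(y)) / 15)
    expect_equal(cohens_d(x, y), (mean(y) - mean(x)) / sp, tolerance = 1e-12)
  }
  expect_warning(d0 <- cohens_d(c(1, 1, 1), c(2, 2)), "zero pooled SD")
  expect_true(is.na(d0))
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("LSD contrasts agree with emmeans on a balanced no-covariate design", {
  skip_if_not_installed("emmeans")
  set.seed(15)
  d <- data.frame(y = rnorm(60), g = factor(rep(c("a", "b", "c"), each = 20)))
  fit <- fit_glm(d, "y", "g")
  am <- adjusted_means(fit, "g")
  ct <- lsd_contrast(am[["a"]], am[["b"]], 20, 20, fit$mse, fit$df_residual)
  em <- emmeans::emmeans(lm(y ~ g, d), "g")
  pr <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
  row <- pr[pr$contrast == "a - b", ]
  expect_equal(ct$diff, row$estimate, tolerance = 1e-10)
  expect_equal(ct$p, row$p.value, tolerance = 1e-10)
})

test_that("adjusted means recenter covariate-imbalanced groups", {
  set.seed(16)
  n <- 200
  g <- factor(rep(c("A", "H"), each = n / 2))
  bw <- rnorm(n, 31, 3) + 2 * (g == "H")  # H mice heavier
  y <- 0.1 * bw + rnorm(n, 0, 0.01)       # y depends only on bw
  fit <- fit_glm(data.frame(y = y, bw = bw, g = g), "y", c("bw", "g"))
  am <- adjusted_means(fit, "g")
  expect_lt(abs(am[["H"]] - am[["A"]]), 0.02)  # raw gap would be ~0.2
})
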