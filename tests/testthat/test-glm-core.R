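test_that("gaussian fits reproduce exact and closed-form solutions", {
  # exact linear relationship: zero residual, recovered line
  x <- c(0, 1, 2, 3, 4, 5)
  y <- 2 + 3 * x
  f <- fit_glm("gaussian", cbind(1, x), y)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_true(f$converged)

  # fixed 8x2 toy design: coefficients equal the normal-equations solution
  set.seed(42)
  X <- cbind(1, matrix(rnorm(16), 8, 2))
  y <- rnorm(8)
  f <- fit_glm("gaussian", X, y)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f$coefficients), drop(beta_oracle), tolerance = 1e-10)
  # and the reported loglik matches the independent profile-MLE formula
  expect_equal(f$loglik, oracle_gauss_loglik(y - X %*% beta_oracle),
               tolerance = 1e-10)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
})

test_that("binomial intercept-only fit gives the empirical logit", {
  y <- c(1, 1, 1, 0, 0, 0)
  f <- fit_glm("binomial", matrix(1, 6, 1), y)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
})

test_that("fit_glm validates input and handles rank deficiency", {
  expect_error(fit_glm("gaussian", matrix(numeric(0), 0, 1), numeric(0)),
               "zero rows")
  expect_error(fit_glm("gaussian", matrix(1, 3, 1), 1:2), "response length")
  expect_error(fit_glm("gaussian", matrix(NA_real_, 3, 1), 1:3), "missing")
  # duplicated column: later-entered one is dropped, fit still valid
  set.seed(1)
  x <- rnorm(10)
  X <- cbind(`(Intercept)` = 1, a = x, b = x)
  y <- 1 + 2 * x + rnorm(10, sd = 0.1)
  f <- fit_glm("gaussian", X, y)
  expect_identical(f$dropped, "b")
  expect_identical(names(f$coefficients), c("(Intercept)", "a"))
  expect_equal(f$k, 2L)
})

test_that("aic identity holds across random fits of both families", {
  expect_identical(aic(-10, 3), 26)
  expect_identical(aic(0, 1), 2)
  set.seed(7)
  for (i in 1:10) {
    X <- cbind(1, matrix(rnorm(60), 20, 3))
    fam <- if (i %% 2) "gaussian" else "binomial"
    y <- if (fam == "gaussian") rnorm(20) else rbinom(20, 1, 0.5)
    f <- fit_glm(fam, X, y)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
    expect_equal(f$k, length(f$coefficients))
  }
})

test_that("univariate association matches its definitions and oracle", {
  y <- c(0.3, 1.2, -0.5, 2.2, 0.1, -1.4, 0.8, 1.9, -0.2, 0.6)
  expect_equal(univariate_association("gaussian", y, y), 1.0)
  expect_equal(univariate_association("gaussian", rep(2, 10), y), 0)
  expect_equal(univariate_association("binomial", rep(2, 10),
                                      rep(c(0, 1), 5)), 0)
  expect_error(univariate_association("gaussian", 1:3, 1:4), "length")

  # fixed 10-observation logistic problem against a brute-force MLE oracle
  x <- c(-1.2, 0.5, 1.7, -0.3, 0.9, -2.1, 1.1, 0.2, -0.8, 1.5)
  yb <- c(0, 1, 0, 0, 1, 0, 1, 1, 1, 1)
  z_pkg <- univariate_association("binomial", x, yb)
  z_oracle <- oracle_logistic_wald_z(x, yb)
  expect_equal(z_pkg, z_oracle, tolerance = 1e-4)
  # a perfectly separated covariate cannot be scored: falls to 0
  expect_identical(univariate_association("binomial", x,
                                          as.numeric(x > 0)), 0)
})

test_that("gaussian association is invariant to sign flip and affine rescaling", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(30)
    y <- rnorm(30)
    s <- univariate_association("gaussian", x, y)
    expect_equal(univariate_association("gaussian", -x, y), s)
    expect_equal(univariate_association("gaussian", 3.7 * x - 2, y), s,
                 tolerance = 1e-12)
  }
})

test_that("forward selection handles trivial and empty candidate sets", {
  set.seed(3)
  x <- rnorm(20)
  sel <- forward_select("gaussian", matrix(x, dimnames = list(NULL, "x")), x)
  expect_identical(sel$selected_terms, "x")
  sel0 <- forward_select("gaussian", NULL, x)
  expect_identical(sel0$selected_terms, character(0))
  expect_identical(names(sel0$fit$coefficients), "(Intercept)")
  # final AIC never exceeds the intercept-only AIC
  expect_lte(sel$fit$aic, sel0$fit$aic)
})

test_that("forward selection reproduces the exhaustive forward-path oracle", {
  # fixed 12x4 gaussian toy problem
  set.seed(123)
  C <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, paste0("c", 1:4)))
  y <- 0.8 * C[, 2] - 0.6 * C[, 4] + rnorm(12, sd = 0.5)
  sel <- forward_select("gaussian", C, y)
  expect_identical(sel$selected_terms, oracle_forward_path("gaussian", C, y))
  # AIC path decreases monotonically
  expect_true(all(diff(sel$aic_path) < 0))

  # binomial case, cross-checked against the oracle and MASS::stepAIC
  set.seed(99)
  Cb <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("c", 1:4)))
  yb <- rbinom(50, 1, plogis(1.5 * Cb[, 1] - Cb[, 3]))
  selb <- forward_select("binomial", Cb, yb)
  expect_identical(selb$selected_terms, oracle_forward_path("binomial", Cb, yb))
  df <- data.frame(y = yb, Cb)
  step_fit <- MASS::stepAIC(
    glm(y ~ 1, data = df, family = binomial()),
    scope = list(lower = ~1, upper = ~ c1 + c2 + c3 + c4),
    direction = "forward", trace = 0)
  expect_setequal(selb$selected_terms,
                  setdiff(names(coef(step_fit)), "(Intercept)"))
})

test_that("forward selection is invariant to candidate order without ties", {
  set.seed(31)
  for (i in 1:5) {
    C <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("c", 1:6)))
    y <- C[, 2] - 0.5 * C[, 5] + rnorm(25, sd = 0.7)
    sel <- forward_select("gaussian", C, y)
    perm <- sample(6)
    sel_p <- forward_select("gaussian", C[, perm], y)
    expect_identical(sel_p$selected_terms, sel$selected_terms)
  }
})
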