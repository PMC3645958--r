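# Independent oracles used to cross-check the fitting engine. These
# deliberately avoid the package's own code paths: base lm/glm/optim only.

# profile-MLE gaussian log-likelihood from residuals
oracle_gauss_loglik <- function(resid) {
  n <- length(resid)
  -0.5 * n * (log(2 * pi * sum(resid^2) / n) + 1)
}

oracle_binom_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# brute-force logistic MLE for intercept + one covariate via optim on the
# Bernoulli likelihood; Wald z from the numerically computed Hessian
oracle_logistic_wald_z <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log(1 + exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  se <- sqrt(diag(solve(opt$hessian)))
  abs(opt$par[2]) / se[2]
}

# exhaustive forward-path selection oracle: at each step refits every
# remaining candidate with stats::lm / stats::glm and compares AICs under
# the package's convention (profile-MLE gaussian loglik, k = n coefficients)
oracle_forward_path <- function(family, C, y) {
  remaining <- colnames(C)
  selected <- character(0)
  model_aic <- function(vars) {
    df <- data.frame(y = y, C[, vars, drop = FALSE], check.names = FALSE)
    if (family == "gaussian") {
      f <- lm(y ~ ., data = df)
      ll <- oracle_gauss_loglik(residuals(f))
    } else {
      f <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      ll <- oracle_binom_loglik(y, fitted(f))
    }
    -2 * ll + 2 * (length(vars) + 1)
  }
  cur_aic <- model_aic(character(0))
  repeat {
    if (length(remaining) == 0) break
    aics <- vapply(remaining, function(v) model_aic(c(selected, v)), 1)
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    cur_aic <- aics[best]
  }
  selected
}

# module-structured binary classification problem used by several tests:
# independent train and test draws from the same design, each dichotomized
# at its own median
make_sim_problem <- function(n_train, n_genes, seed, n_test = 0,
                             noise_sd = 0.5) {
  tr <- simulate_expression(sim_design(n_samples = n_train, n_genes = n_genes,
                                       outcome_noise_sd = noise_sd,
                                       seed = seed))
  out <- list(x = tr$x, y = dichotomize_median(tr$y_cont),
              module = tr$module)
  if (n_test > 0) {
    te <- simulate_expression(sim_design(n_samples = n_test,
                                         n_genes = n_genes,
                                         outcome_noise_sd = noise_sd,
                                         seed = seed + 100000L))
    out$x_test <- te$x
    out$y_test <- dichotomize_median(te$y_cont)
  }
  out
}
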