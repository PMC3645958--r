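#' @useDynLib rglmens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm.fit gaussian binomial plogis qlogis cor median sd
NULL

.FAMILIES <- c("gaussian", "binomial")

check_family <- function(family) {
  family <- match.arg(family, .FAMILIES)
  family
}

family_code <- function(family) match(family, .FAMILIES) - 1L

#' Akaike information criterion
#'
#' `AIC = -2 loglik + 2 k`, where `k` counts the estimated coefficients
#' (including the intercept). For gaussian models the log-likelihood uses the
#' profile maximum-likelihood error variance, so AIC differences are
#' comparable across fits on the same observations.
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param k Number of estimated parameters (>= 1).
#' @return The AIC value.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 1)
  -2 * loglik + 2 * k
}

gaussian_loglik <- function(residuals) {
  n <- length(residuals)
  s2 <- max(sum(residuals^2) / n, 1e-300)
  -0.5 * n * (log(2 * pi * s2) + 1)
}

binomial_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit a generalized linear model (gaussian or binomial)
#'
#' Maximum-likelihood fit of a GLM on an explicit design matrix (the caller
#' supplies the intercept column). A fast compiled least-squares / IRLS path
#' is used; rank-deficient designs fall back to [stats::glm.fit()], whose
#' pivoted QR drops later-entered aliased columns, which are then removed
#' from the result and reported in `$dropped`.
#'
#' @param family `"gaussian"` or `"binomial"`.
#' @param design Numeric design matrix, one row per observation. Include an
#'   intercept column explicitly if one is wanted.
#' @param response Numeric response vector; 0/1 for binomial.
#' @param maxit Maximum IRLS iterations (binomial).
#' @param tol Relative deviance-change convergence tolerance.
#' @return An object of class `rglm_fit`: list with `coefficients` (named),
#'   `loglik`, `aic`, `converged`, `n_obs`, `k` and `dropped` (names of
#'   aliased columns removed from the fit).
#' @export
fit_glm <- function(family, design, response, maxit = 25L, tol = 1e-8) {
  family <- check_family(family)
  design <- as.matrix(design)
  if (nrow(design) == 0L) stop("empty design: zero rows")
  if (nrow(design) != length(response)) {
    stop("design rows (", nrow(design), ") != response length (",
         length(response), ")")
  }
  if (anyNA(design) || anyNA(response)) stop("missing values are not allowed")
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)", paste0("V", seq_len(ncol(design) - 1L)))[
      seq_len(ncol(design))]
  }
  fit <- cpp_glm_fit(design, as.numeric(response), family_code(family),
                     as.integer(maxit), tol)
  dropped <- character(0)
  if (isTRUE(fit$ok)) {
    beta <- as.numeric(fit$coefficients)
    names(beta) <- colnames(design)
    loglik <- fit$loglik
    converged <- isTRUE(fit$converged)
  } else {
    # collinear design: let glm.fit's pivoted QR alias the later columns
    fam <- if (family == "gaussian") gaussian() else binomial()
    gf <- suppressWarnings(glm.fit(design, as.numeric(response), family = fam,
                                   control = list(maxit = maxit)))
    beta <- gf$coefficients
    dropped <- names(beta)[is.na(beta)]
    beta <- beta[!is.na(beta)]
    if (family == "gaussian") {
      loglik <- gaussian_loglik(gf$residuals * sqrt(gf$weights))
      converged <- TRUE
    } else {
      loglik <- binomial_loglik(as.numeric(response), gf$fitted.values)
      converged <- isTRUE(gf$converged) &&
        max(abs(gf$linear.predictors)) <= 30
    }
  }
  k <- length(beta)
  structure(list(coefficients = beta,
                 loglik = loglik,
                 aic = aic(loglik, k),
                 converged = converged,
                 n_obs = nrow(design),
                 k = k,
                 family = family,
                 dropped = dropped),
            class = "rglm_fit")
}

#' Univariate association between a covariate and the outcome
#'
#' The screening score used to rank candidate covariates within a bag:
#' for a continuous outcome the absolute Pearson correlation, for a binary
#' outcome the absolute Wald z statistic of the slope in a univariate
#' logistic regression. Degenerate covariates (zero variance) and failed or
#' separated logistic fits score 0, i.e. rank last.
#'
#' @inheritParams fit_glm
#' @param covariate Numeric covariate vector.
#' @return A non-negative scalar score.
#' @export
univariate_association <- function(family, covariate, response) {
  family <- check_family(family)
  if (length(covariate) != length(response)) {
    stop("covariate and response lengths differ")
  }
  if (length(response) < 3L) stop("need at least 3 observations")
  as.numeric(association_scores(family, matrix(covariate, ncol = 1),
                                as.numeric(response)))
}

# Vectorized scores for the columns of `covariates`.
association_scores <- function(family, covariates, response) {
  if (family == "gaussian") {
    sds <- apply(covariates, 2L, sd)
    sc <- suppressWarnings(as.numeric(cor(covariates, response)))
    sc <- abs(sc)
    sc[!is.finite(sc) | sds < 1e-12] <- 0
    sc
  } else {
    as.numeric(cpp_univariate_wald(covariates, as.numeric(response), 25L, 1e-8))
  }
}

#' Forward stepwise selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' covariate that most decreases the AIC, stopping when no addition strictly
#' decreases it (or candidates are exhausted). Candidates whose augmented
#' fit fails or does not converge are treated as AIC = +Inf for that step.
#' Ties are broken by candidate order (stable).
#'
#' @inheritParams fit_glm
#' @param candidates Numeric matrix of candidate covariates (one per column,
#'   named), or a named list of vectors.
#' @return An object of class `rglm_selected`: list with `selected_terms`
#'   (names in selection order), `fit` (the final [fit_glm()] result),
#'   `candidate_terms` and `aic_path` (AIC after each step, starting with
#'   the intercept-only model).
#' @export
forward_select <- function(family, candidates, response, maxit = 25L,
                           tol = 1e-8) {
  family <- check_family(family)
  if (is.list(candidates) && !is.matrix(candidates)) {
    candidates <- do.call(cbind, candidates)
  }
  y <- as.numeric(response)
  n <- length(y)
  if (!is.null(candidates) && ncol(candidates) > 0 && nrow(candidates) != n) {
    stop("candidate rows != response length")
  }
  intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit0 <- fit_glm(family, intercept, y, maxit = maxit, tol = tol)
  if (is.null(candidates) || ncol(candidates) == 0) {
    return(structure(list(selected_terms = character(0), fit = fit0,
                          candidate_terms = character(0),
                          aic_path = fit0$aic),
                     class = "rglm_selected"))
  }
  if (is.null(colnames(candidates))) {
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  }
  cand_names <- colnames(candidates)
  remaining <- seq_len(ncol(candidates))
  selected <- integer(0)
  cur <- intercept
  cur_aic <- fit0$aic
  cur_beta <- unname(fit0$coefficients) # warm start for candidate IRLS
  aic_path <- cur_aic
  while (length(remaining) > 0) {
    aics <- cpp_forward_step(cur, candidates[, remaining, drop = FALSE], y,
                             family_code(family), as.integer(maxit), tol,
                             cur_beta)
    best <- which.min(aics) # first minimum: stable tie-break by candidate order
    if (!is.finite(aics[best]) || aics[best] >= cur_aic) break
    sel <- remaining[best]
    selected <- c(selected, sel)
    cur <- cbind(cur, candidates[, sel, drop = FALSE])
    remaining <- remaining[-best]
    cur_aic <- aics[best]
    aic_path <- c(aic_path, cur_aic)
    cf <- cpp_glm_fit(cur, y, family_code(family), as.integer(maxit), tol)
    cur_beta <- if (isTRUE(cf$ok)) as.numeric(cf$coefficients) else numeric(0)
  }
  fit <- fit_glm(family, cur, y, maxit = maxit, tol = tol)
  structure(list(selected_terms = cand_names[selected], fit = fit,
                 candidate_terms = cand_names, aic_path = aic_path),
            class = "rglm_selected")
}
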