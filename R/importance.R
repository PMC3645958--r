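# Ensemble variable importance and importance-based predictor thinning.

#' Variable importance of a random GLM ensemble
#'
#' Three tallies per term across bags: how often it was a screening
#' candidate (`times_selected_as_candidates`), how often forward selection
#' kept it (`times_selected_by_forward_regression`), and the sum of the
#' absolute fitted coefficients over the bags that kept it
#' (`sum_abs_coef_by_forward_regression`). Both counts are bounded by the
#' number of bags. At `level = "feature"` the tallies of every term
#' containing an original feature are summed into that feature's record.
#'
#' @param model A trained `rglm` model.
#' @param level `"term"` (default) or `"feature"`.
#' @return A data frame sorted by `times_selected_by_forward_regression`
#'   (decreasing, stable ties), with columns `term`, `order` and the three
#'   measures. At feature level `term` is the feature name and `order` 1.
#' @export
rglm_importance <- function(model, level = c("term", "feature")) {
  level <- match.arg(level)
  tally <- new.env(parent = emptyenv())
  bump <- function(key, term, what, amount = 1L) {
    rec <- get0(key, envir = tally,
                ifnotfound = list(term = term, cand = 0L, sel = 0L, coef = 0))
    rec[[what]] <- rec[[what]] + amount
    assign(key, rec, envir = tally)
  }
  for (bag in model$bags) {
    for (t in bag$candidate_terms) bump(term_key(t), t, "cand")
    if (length(bag$selected_terms) > 0) {
      coefs <- bag$coefficients[-1L]
      for (i in seq_along(bag$selected_terms)) {
        t <- bag$selected_terms[[i]]
        bump(term_key(t), t, "sel")
        bump(term_key(t), t, "coef", abs(coefs[[i]]))
      }
    }
  }
  keys <- ls(tally)
  recs <- lapply(keys, get, envir = tally)
  if (level == "feature") {
    feat <- new.env(parent = emptyenv())
    for (rec in recs) {
      for (f in unique(rec$term)) {
        fr <- get0(as.character(f), envir = feat,
                   ifnotfound = list(term = f, cand = 0L, sel = 0L, coef = 0))
        fr$cand <- fr$cand + rec$cand
        fr$sel <- fr$sel + rec$sel
        fr$coef <- fr$coef + rec$coef
        assign(as.character(f), fr, envir = feat)
      }
    }
    recs <- lapply(ls(feat), get, envir = feat)
    labels <- vapply(recs, function(r) model$feature_names[r$term], character(1))
    orders <- rep(1L, length(recs))
  } else {
    labels <- vapply(recs, function(r) term_label(r$term, model$feature_names),
                     character(1))
    orders <- vapply(recs, function(r) length(r$term), integer(1))
  }
  df <- data.frame(
    term = labels,
    order = orders,
    times_selected_by_forward_regression = vapply(recs, `[[`, integer(1), "sel"),
    times_selected_as_candidates = vapply(recs, `[[`, integer(1), "cand"),
    sum_abs_coef_by_forward_regression = vapply(recs, `[[`, numeric(1), "coef"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$times_selected_by_forward_regression, df$term), ,
           drop = FALSE]
  rownames(df) <- NULL
  attr(df, "term_indices") <- recs
  df
}

# term-level selection tallies as a named (by term key) integer vector
selection_tally <- function(model) {
  tally <- integer(0)
  for (bag in model$bags) {
    for (t in bag$selected_terms) {
      key <- term_key(t)
      tally[key] <- if (key %in% names(tally)) tally[[key]] + 1L else 1L
    }
  }
  tally
}

#' Thin a random GLM ensemble by selection frequency
#'
#' Removes every term whose ensemble-wide selection tally
#' (`times_selected_by_forward_regression`) falls below `threshold`, then
#' refits each bag's GLM -- a plain fit, no new forward selection -- on its
#' surviving originally-selected terms using its own bag rows. Bags with no
#' surviving terms become intercept-only. A threshold of 0 reproduces the
#' unthinned model exactly; a threshold above the number of bags leaves the
#' constant "naive" predictor.
#'
#' @param model A trained `rglm` model.
#' @param threshold Integer in `[0, n_bags + 1]`.
#' @param x,y The training data the model was built on.
#' @return Object of class `c("rglm_thinned", "rglm")`; same structure as
#'   the base model plus `threshold` and `removed_terms`, so [predict.rglm()]
#'   and [rglm_oob()] apply unchanged.
#' @export
rglm_thin <- function(model, threshold, x, y) {
  stopifnot(inherits(model, "rglm"))
  if (threshold < 0 || threshold > model$config$n_bags + 1) {
    stop("threshold must lie in [0, n_bags + 1]")
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) == model$n_samples)
  tally <- selection_tally(model)
  removed <- names(tally)[tally < threshold]
  bags <- model$bags
  for (b in seq_along(bags)) {
    bag <- bags[[b]]
    if (length(bag$selected_terms) == 0) next
    keys <- vapply(bag$selected_terms, term_key, character(1))
    keep <- !(keys %in% removed)
    y_bag <- y[bag$bag]
    if (!any(keep)) {
      bag$selected_terms <- list()
      bag$coefficients <- intercept_only_bag_fit(model$config$family, y_bag)
    } else {
      surv <- bag$selected_terms[keep]
      design <- cbind(`(Intercept)` = 1,
                      term_matrix(x[bag$bag, , drop = FALSE], surv))
      fit <- tryCatch(fit_glm(model$config$family, design, y_bag),
                      error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(fit$coefficients))) {
        bag$selected_terms <- list()
        bag$coefficients <- intercept_only_bag_fit(model$config$family, y_bag)
      } else {
        kept_keys <- setdiff(names(fit$coefficients), "(Intercept)")
        names(surv) <- colnames(design)[-1L]
        bag$selected_terms <- unname(surv[kept_keys])
        bag$coefficients <- fit$coefficients
      }
    }
    bags[[b]] <- bag
  }
  out <- model
  out$bags <- bags
  out$threshold <- as.integer(threshold)
  out$removed_terms <- removed
  class(out) <- c("rglm_thinned", "rglm")
  out
}

#' Expected proportion of features surviving thinning
#'
#' Empirical curve relating the thinning threshold to the expected fraction
#' of features left in the thinned ensemble:
#' `F(x) = exp(-e * (e*x)^(0.775 * n_bags^(0.0468 * (1 - log(x)))))` for
#' `0 < x <= 1` and `F(0) = 1`, where `x = threshold / n_bags`, `e` is
#' Euler's constant and `log` is natural. Monotonically decreasing in `x`.
#'
#' @param x Thinning threshold divided by the number of bags, in `[0, 1]`
#'   (vectorized).
#' @param n_bags Number of bags (>= 1).
#' @return Value(s) of F in `[0, 1]`.
#' @export
expected_proportion_left <- function(x, n_bags) {
  stopifnot(n_bags >= 1)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  out <- ifelse(x == 0, 1,
                exp(-exp(1) * (exp(1) * x)^(0.775 *
                      n_bags^(0.0468 * (1 - log(x))))))
  pmin(pmax(out, 0), 1)
}

#' Observed proportion of features surviving thinning
#'
#' Number of distinct original features appearing in the thinned model's
#' surviving selected terms, divided by the count in the base model's
#' selected terms.
#'
#' @param model The base `rglm` model.
#' @param thinned The result of [rglm_thin()] on `model`.
#' @return A proportion in `[0, 1]`, or `NA` if the base model selected no
#'   terms at all.
#' @export
observed_proportion_left <- function(model, thinned) {
  distinct_features <- function(m) {
    unique(unlist(lapply(m$bags, function(b) lapply(b$selected_terms, unique))))
  }
  base <- distinct_features(model)
  if (length(base) == 0) {
    warning("base model has no selected terms")
    return(NA_real_)
  }
  length(distinct_features(thinned)) / length(base)
}
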