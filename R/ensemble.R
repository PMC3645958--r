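# RGLM ensemble construction: bagging, random subspaces, interaction
# expansion, candidate screening, per-bag forward selection, aggregation.

#' Draw one bootstrap bag
#'
#' Samples `n_samples` indices with replacement; the out-of-bag (OOB) set is
#' the complement of the drawn set. Uses the current RNG state.
#'
#' @param n_samples Number of training samples (>= 1).
#' @return List with `bag` (length `n_samples`, with replacement) and `oob`
#'   (indices never drawn).
#' @export
draw_bag <- function(n_samples) {
  stopifnot(n_samples >= 1)
  bag <- sample.int(n_samples, n_samples, replace = TRUE)
  list(bag = bag, oob = setdiff(seq_len(n_samples), bag))
}

#' Sample a random feature subspace
#'
#' Uniform sample without replacement of `n_features_in_bag` distinct
#' feature indices, returned sorted. Uses the current RNG state.
#'
#' @param n_features Total number of features.
#' @param n_features_in_bag Subspace size, in `[1, n_features]`.
#' @return Sorted integer vector of feature indices.
#' @export
sample_subspace <- function(n_features, n_features_in_bag) {
  if (n_features_in_bag > n_features || n_features_in_bag < 1) {
    stop("n_features_in_bag must lie in [1, n_features]")
  }
  sort(sample.int(n_features, n_features_in_bag))
}

# combinations of size k from v, with repetition allowed (i <= j <= ...)
combn_rep <- function(v, k) {
  if (k == 1L) return(lapply(v, identity))
  out <- list()
  recurse <- function(prefix, start) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq(start, length(v))) recurse(c(prefix, v[i]), i)
  }
  recurse(integer(0), 1L)
  out
}

#' Expand a feature subspace into interaction terms
#'
#' Generates every product term of up to `order` features from the
#' subspace, in deterministic order: main effects first, then 2-way, then
#' 3-way terms, lexicographically within each order. With
#' `include_self = TRUE` (the default) products may repeat a feature
#' (squares, cubes, ...), which lets the base GLMs express radially
#' curved class boundaries; with `FALSE` only products of distinct
#' features are generated.
#'
#' @param subspace Integer vector of feature indices.
#' @param order Maximum interaction order (1, 2 or 3).
#' @param include_self Allow self-products (repeated indices)?
#' @return List of integer vectors (each sorted), one per term.
#' @export
expand_interactions <- function(subspace, order, include_self = TRUE) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  subspace <- sort(as.integer(subspace))
  terms <- lapply(subspace, identity)
  for (k in seq_len(order)[-1]) {
    if (include_self) {
      terms <- c(terms, combn_rep(subspace, k))
    } else if (length(subspace) >= k) {
      terms <- c(terms, apply(utils::combn(subspace, k), 2L, identity,
                              simplify = FALSE))
    }
  }
  terms
}

term_key <- function(term) paste(term, collapse = ".")

term_label <- function(term, feature_names) {
  paste(feature_names[term], collapse = "*")
}

# samples x terms matrix of product covariates
term_matrix <- function(x, terms) {
  m <- matrix(0, nrow(x), length(terms))
  for (j in seq_along(terms)) {
    t <- terms[[j]]
    v <- x[, t[1L]]
    for (i in seq_along(t)[-1L]) v <- v * x[, t[i]]
    m[, j] <- v
  }
  colnames(m) <- vapply(terms, term_key, character(1))
  m
}

#' Screen candidate terms by univariate association
#'
#' Ranks terms by the univariate association of their product covariate
#' with the outcome (computed on the bag rows only) and keeps the top
#' `n_candidate_covariates`. Ties are broken by term order
#' (lexicographic, since term expansion is lexicographic).
#'
#' @param terms List of terms (integer index vectors).
#' @param x_bag Bag-row feature matrix.
#' @param y_bag Bag-row outcome.
#' @param n_candidate_covariates Maximum number of terms kept.
#' @param family `"gaussian"` or `"binomial"`.
#' @return The selected terms, in rank order.
#' @export
screen_candidates <- function(terms, x_bag, y_bag, n_candidate_covariates,
                              family) {
  stopifnot(length(terms) > 0)
  family <- check_family(family)
  tm <- term_matrix(x_bag, terms)
  scores <- association_scores(family, tm, y_bag)
  keep <- order(-scores)[seq_len(min(n_candidate_covariates, length(terms)))]
  terms[keep]
}

resolve_config <- function(n_features, n_bags, n_features_in_bag,
                           n_candidate_covariates, max_interaction_order,
                           include_self_interactions, family,
                           classify_threshold, seed) {
  stopifnot(n_bags >= 1, n_candidate_covariates >= 1,
            max_interaction_order %in% 1:3,
            classify_threshold > 0, classify_threshold < 1)
  if (identical(n_features_in_bag, "auto")) {
    n_features_in_bag <- resolve_n_features_in_bag(n_features,
                                                   max_interaction_order)
  }
  n_features_in_bag <- as.integer(n_features_in_bag)
  if (n_features_in_bag < 1 || n_features_in_bag > n_features) {
    stop("n_features_in_bag must lie in [1, number of features]")
  }
  list(n_bags = as.integer(n_bags),
       n_features_in_bag = n_features_in_bag,
       n_candidate_covariates = as.integer(n_candidate_covariates),
       max_interaction_order = as.integer(max_interaction_order),
       include_self_interactions = isTRUE(include_self_interactions),
       family = check_family(family),
       classify_threshold = classify_threshold,
       seed = as.integer(seed))
}

clipped_logit <- function(p) qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

intercept_only_bag_fit <- function(family, y_bag) {
  b <- if (family == "binomial") clipped_logit(mean(y_bag)) else mean(y_bag)
  names(b) <- "(Intercept)"
  b
}

#' Fit one bag of the ensemble
#'
#' Composes one ensemble member: bootstrap draw, random feature subspace,
#' interaction expansion, univariate screening and forward AIC selection,
#' all on the bag rows. A binomial bag containing a single outcome class
#' skips selection and stores an intercept-only model at the (clipped)
#' bag prevalence. Uses the current RNG state for the random draws.
#'
#' @param x Training feature matrix (samples x features).
#' @param y Outcome vector.
#' @param config Resolved configuration list (see [rglm()]).
#' @return A list describing the bag: `bag`, `oob`, `subspace`,
#'   `candidate_terms`, `selected_terms` (both lists of index vectors),
#'   `coefficients` (named: intercept first, then selected term keys, in
#'   selection order) and `aic`.
#' @export
fit_bag <- function(x, y, config) {
  drawn <- draw_bag(nrow(x))
  subspace <- sample_subspace(ncol(x), config$n_features_in_bag)
  terms <- expand_interactions(subspace, config$max_interaction_order,
                               config$include_self_interactions)
  x_bag <- x[drawn$bag, , drop = FALSE]
  y_bag <- y[drawn$bag]
  if (config$family == "binomial" && length(unique(y_bag)) < 2L) {
    warning("single-class bootstrap bag: storing intercept-only model")
    return(list(bag = drawn$bag, oob = drawn$oob, subspace = subspace,
                candidate_terms = list(), selected_terms = list(),
                coefficients = intercept_only_bag_fit(config$family, y_bag),
                aic = NA_real_))
  }
  cand <- screen_candidates(terms, x_bag, y_bag,
                            config$n_candidate_covariates, config$family)
  cm <- term_matrix(x_bag, cand)
  sel <- forward_select(config$family, cm, y_bag)
  key2term <- cand
  names(key2term) <- colnames(cm)
  kept <- setdiff(sel$selected_terms, sel$fit$dropped)
  list(bag = drawn$bag, oob = drawn$oob, subspace = subspace,
       candidate_terms = cand,
       selected_terms = unname(key2term[kept]),
       coefficients = sel$fit$coefficients,
       aic = sel$fit$aic)
}

#' Fit a random GLM ensemble
#'
#' Trains `n_bags` generalized linear models, each on a bootstrap sample of
#' the training data restricted to a random feature subspace (optionally
#' expanded with interaction terms), with candidate covariates screened by
#' univariate association and then selected by forward stepwise AIC.
#' Predictions are aggregated across bags by averaging (predicted
#' probabilities for a binary outcome -- the adjusted majority vote -- or
#' predicted values for a continuous one).
#'
#' Every random draw derives from `seed` via one substream per bag, so
#' results are reproducible and independent of bag execution order.
#'
#' @param x Numeric matrix, samples x features, without missing values.
#' @param y Outcome: 0/1 (binomial) or numeric (gaussian).
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to infer from `y`.
#' @param n_bags Number of bootstrap bags (default 100).
#' @param n_features_in_bag Features sampled per bag, or `"auto"` for the
#'   default rule of [resolve_n_features_in_bag()].
#' @param n_candidate_covariates Terms passed to forward selection per bag
#'   (default 50).
#' @param max_interaction_order Highest interaction order (1, 2 or 3;
#'   default 1).
#' @param include_self_interactions Allow squared (and higher self-product)
#'   terms when `max_interaction_order > 1` (default `TRUE`).
#' @param classify_threshold Probability threshold for class prediction
#'   (binomial; default 0.5).
#' @param seed Master seed (default 1).
#' @return Object of class `rglm` with elements `config`, `bags`,
#'   `n_samples`, `n_features`, `feature_names` and `y_summary`.
#' @examples
#' sim <- make_benchmark("twonorm", n = 120, d = 10, seed = 7)
#' fit <- rglm(sim$x, sim$y, n_bags = 10, seed = 7)
#' mean(predict(fit, sim$x, type = "class") == sim$y)
#' @export
rglm <- function(x, y, family = NULL, n_bags = 100L,
                 n_features_in_bag = "auto", n_candidate_covariates = 50L,
                 max_interaction_order = 1L,
                 include_self_interactions = TRUE,
                 classify_threshold = 0.5, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("no features")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  if (length(unique(y)) < 2L) stop("constant outcome")
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- check_family(family)
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial outcome must be coded 0/1")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  config <- resolve_config(ncol(x), n_bags, n_features_in_bag,
                           n_candidate_covariates, max_interaction_order,
                           include_self_interactions, family,
                           classify_threshold, seed)
  bag_seeds <- derive_seeds(config$seed, config$n_bags)
  bags <- vector("list", config$n_bags)
  for (b in seq_len(config$n_bags)) {
    bags[[b]] <- with_seed(bag_seeds[b], fit_bag(x, y, config))
  }
  structure(list(config = config, bags = bags,
                 n_samples = nrow(x), n_features = ncol(x),
                 feature_names = colnames(x),
                 y_summary = mean(y)),
            class = "rglm")
}

# linear predictor of one bag on new data
bag_linear_predictor <- function(bag, x) {
  lp <- rep(bag$coefficients[["(Intercept)"]], nrow(x))
  if (length(bag$selected_terms) > 0) {
    tm <- term_matrix(x, bag$selected_terms)
    lp <- lp + as.numeric(tm %*% bag$coefficients[-1L])
  }
  lp
}

# samples x bags matrix of per-bag predictions (probability scale for
# binomial, response scale for gaussian)
bag_prediction_matrix <- function(model, x) {
  out <- matrix(0, nrow(x), length(model$bags))
  for (b in seq_along(model$bags)) {
    lp <- bag_linear_predictor(model$bags[[b]], x)
    out[, b] <- if (model$config$family == "binomial") plogis(lp) else lp
  }
  out
}

#' Predict from a random GLM ensemble
#'
#' @param object An `rglm` (or thinned) model.
#' @param newdata Matrix with the training feature count.
#' @param type `"response"` (default): mean prediction across bags, on the
#'   probability scale for binomial models; `"prob"`: alias for the
#'   binomial probability; `"class"`: 0/1 at the configured threshold
#'   (probability >= threshold predicts 1).
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.rglm <- function(object, newdata,
                         type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  }
  if (object$config$family == "gaussian" && type != "response") {
    stop("type '", type, "' applies to binomial models only")
  }
  agg <- rowMeans(bag_prediction_matrix(object, newdata))
  if (type == "class") {
    as.integer(agg >= object$config$classify_threshold)
  } else {
    agg
  }
}

#' @export
print.rglm <- function(x, ...) {
  cfg <- x$config
  cat("Random GLM ensemble (", cfg$family, ")\n", sep = "")
  cat("  bags:", cfg$n_bags,
      " features/bag:", cfg$n_features_in_bag, "of", x$n_features,
      " candidates:", cfg$n_candidate_covariates,
      " interaction order:", cfg$max_interaction_order, "\n")
  nsel <- vapply(x$bags, function(b) length(b$selected_terms), integer(1))
  cat("  selected terms per bag: median", median(nsel),
      "range", min(nsel), "-", max(nsel), "\n")
  invisible(x)
}

#' Out-of-bag predictions and accuracy
#'
#' Aggregates, for each training sample, the predictions of only the bags
#' in which the sample is out-of-bag, giving a nearly unbiased estimate of
#' test accuracy without a held-out set. Samples that are in-bag everywhere
#' get `NA` and are excluded from the accuracy.
#'
#' @param model A trained `rglm` model.
#' @param x,y The training data the model was built on.
#' @return List of class `rglm_oob`: `predictions` (response scale, `NA`
#'   where never OOB), `oob_accuracy` (1 - misclassification at the class
#'   threshold for binomial; Pearson correlation with `y` for gaussian)
#'   and `n_missing`.
#' @export
rglm_oob <- function(model, x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == model$n_samples, length(y) == nrow(x))
  pm <- bag_prediction_matrix(model, x)
  w <- matrix(FALSE, nrow(x), length(model$bags))
  for (b in seq_along(model$bags)) w[model$bags[[b]]$oob, b] <- TRUE
  pred <- rep(NA_real_, nrow(x))
  cover <- rowSums(w)
  has <- cover > 0
  pred[has] <- rowSums(pm * w)[has] / cover[has]
  acc <- if (model$config$family == "binomial") {
    cls <- as.integer(pred[has] >= model$config$classify_threshold)
    mean(cls == y[has])
  } else {
    suppressWarnings(cor(pred[has], y[has]))
  }
  structure(list(predictions = pred, oob_accuracy = acc,
                 n_missing = sum(!has)),
            class = "rglm_oob")
}
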