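test_that("bootstrap bags partition samples into bag and out-of-bag", {
  set.seed(1)
  expect_identical(draw_bag(1), list(bag = 1L, oob = integer(0)))
  for (i in 1:20) {
    d <- draw_bag(37)
    expect_length(d$bag, 37)
    expect_setequal(union(d$bag, d$oob), 1:37)
    expect_length(intersect(d$bag, d$oob), 0)
  }
})

test_that("bootstrap unique-sample fraction matches the analytic value", {
  n <- 100
  set.seed(5)
  frac <- replicate(2000, length(unique(draw_bag(n)$bag)) / n)
  expect_equal(mean(frac), 1 - (1 - 1 / n)^n, tolerance = 0.005)
})

test_that("feature subspaces are uniform samples without replacement", {
  set.seed(2)
  expect_identical(sample_subspace(5, 5), 1:5)
  s <- sample_subspace(100, 20)
  expect_length(s, 20)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 1 & s <= 100))
  expect_error(sample_subspace(5, 6), "n_features_in_bag")
  # empirical inclusion frequency = 3/10 for each feature
  counts <- integer(10)
  for (i in 1:3000) {
    s <- sample_subspace(10, 3)
    counts[s] <- counts[s] + 1L
  }
  expect_equal(counts / 3000, rep(0.3, 10), tolerance = 0.09)
})

test_that("interaction expansion enumerates the expected term sets", {
  # distinct-feature expansion: all subsets of size 1..order
  t2 <- expand_interactions(c(1, 2, 3), 2, include_self = FALSE)
  expect_identical(t2, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_identical(expand_interactions(7, 3, include_self = FALSE), list(7L))
  for (m in c(4, 6)) {
    for (ord in 1:3) {
      got <- expand_interactions(seq_len(m), ord, include_self = FALSE)
      expect_length(got, effective_feature_count(m, ord))
    }
  }
  # self-interactions add squared (and repeated-index) products
  t2s <- expand_interactions(c(1, 2), 2, include_self = TRUE)
  expect_identical(t2s, list(1L, 2L, c(1L, 1L), c(1L, 2L), c(2L, 2L)))
  expect_length(expand_interactions(1:5, 2, include_self = TRUE),
                5 + choose(6, 2))
})

test_that("candidate screening reproduces an independent rank oracle", {
  set.seed(8)
  x <- matrix(rnorm(40 * 8), 40, 8)
  y <- x[, 3] + rnorm(40, sd = 0.2)
  terms <- expand_interactions(1:8, 1)
  top <- screen_candidates(terms, x, y, 3, "gaussian")
  scores <- abs(cor(x, y))
  expect_identical(unlist(top), as.integer(order(-scores)[1:3]))
  # a term identical to the outcome ranks first
  y2 <- x[, 5]
  top1 <- screen_candidates(terms, x, y2, 1, "gaussian")
  expect_identical(top1[[1]], 5L)
  # fewer terms than the cap: all returned, in rank order
  expect_length(screen_candidates(terms, x, y, 50, "gaussian"), 8)
})

test_that("bag models respect the candidate containment chain", {
  prob <- make_sim_problem(60, 40, seed = 4)
  config <- list(n_bags = 1L, n_features_in_bag = 20L,
                 n_candidate_covariates = 10L, max_interaction_order = 2L,
                 include_self_interactions = TRUE, family = "binomial",
                 classify_threshold = 0.5, seed = 1L)
  set.seed(9)
  bag <- fit_bag(prob$x, prob$y, config)
  expect_lte(length(bag$candidate_terms), 10)
  all_terms <- expand_interactions(bag$subspace, 2)
  key <- function(l) vapply(l, paste, "", collapse = ".")
  expect_true(all(key(bag$candidate_terms) %in% key(all_terms)))
  expect_true(all(key(bag$selected_terms) %in% key(bag$candidate_terms)))
  expect_true(all(unlist(bag$selected_terms) %in% bag$subspace))
  # repeated draw under the same seed is bit-identical
  set.seed(9)
  bag2 <- fit_bag(prob$x, prob$y, config)
  expect_identical(bag, bag2)
})

test_that("training is deterministic and order-independent given the seed", {
  prob <- make_sim_problem(50, 30, seed = 6)
  f1 <- rglm(prob$x, prob$y, n_bags = 8, seed = 123)
  f2 <- rglm(prob$x, prob$y, n_bags = 8, seed = 123)
  expect_identical(f1, f2)
  # the first bags of a larger ensemble coincide with the smaller one's
  f3 <- rglm(prob$x, prob$y, n_bags = 4, seed = 123)
  expect_identical(f1$bags[1:4], f3$bags)
})

test_that("ensemble predictions aggregate per-bag votes exactly", {
  prob <- make_sim_problem(60, 30, seed = 2)
  fit <- rglm(prob$x, prob$y, n_bags = 12, seed = 7)
  newx <- prob$x[1:10, ]
  p <- predict(fit, newx)
  # independent aggregation from the serialized per-bag coefficients
  manual <- rowMeans(vapply(fit$bags, function(b) {
    lp <- rep(b$coefficients[["(Intercept)"]], nrow(newx))
    for (i in seq_along(b$selected_terms)) {
      t <- b$selected_terms[[i]]
      v <- newx[, t[1]]
      for (j in seq_along(t)[-1]) v <- v * newx[, t[j]]
      lp <- lp + b$coefficients[[i + 1]] * v
    }
    plogis(lp)
  }, numeric(nrow(newx))))
  expect_equal(p, manual, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, newx, type = "class"),
                   as.integer(p >= 0.5))
  # single-bag ensemble equals its base model
  f1 <- rglm(prob$x, prob$y, n_bags = 1, seed = 3)
  p1 <- predict(f1, newx)
  b <- f1$bags[[1]]
  lp <- rep(b$coefficients[["(Intercept)"]], nrow(newx))
  for (i in seq_along(b$selected_terms)) {
    t <- b$selected_terms[[i]]
    v <- newx[, t[1]]
    for (j in seq_along(t)[-1]) v <- v * newx[, t[j]]
    lp <- lp + b$coefficients[[i + 1]] * v
  }
  expect_equal(p1, plogis(lp), tolerance = 1e-14)
  expect_error(predict(fit, newx[, 1:5]), "features")
})

test_that("self-interaction terms are what capture radial class structure", {
  # ringnorm's classes differ by scale; ||x||^2 needs squared terms, which
  # cross-products of distinct features cannot represent
  tr <- make_benchmark("ringnorm", n = 300, d = 20, seed = 51)
  te <- make_benchmark("ringnorm", n = 1000, d = 20, seed = 52)
  acc <- function(include_self) {
    fit <- rglm(tr$x, tr$y, n_bags = 50, max_interaction_order = 2,
                include_self_interactions = include_self, seed = 6)
    mean(predict(fit, te$x, type = "class") == te$y)
  }
  expect_gte(acc(TRUE), acc(FALSE) + 0.15)
})

test_that("input validation rejects degenerate training problems", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(rglm(x, rep(1, 10)), "constant")
  expect_error(rglm(x, c(rep(0, 5), rep(2, 5)), family = "binomial"), "0/1")
  expect_error(rglm(x[, 0], rbinom(10, 1, 0.5)), "features")
})

test_that("out-of-bag aggregation uses only bags excluding each sample", {
  prob <- make_sim_problem(40, 25, seed = 12)
  f1 <- rglm(prob$x, prob$y, n_bags = 1, seed = 5)
  oob1 <- rglm_oob(f1, prob$x, prob$y)
  in_bag <- unique(f1$bags[[1]]$bag)
  expect_true(all(is.na(oob1$predictions[in_bag])))
  expect_true(all(!is.na(oob1$predictions[f1$bags[[1]]$oob])))
  # with many bags every sample is out-of-bag somewhere
  f <- rglm(prob$x, prob$y, n_bags = 50, seed = 5)
  oob <- rglm_oob(f, prob$x, prob$y)
  expect_identical(oob$n_missing, 0L)
  expect_true(all(!is.na(oob$predictions)))
})

test_that("a perfectly separable signal yields near-perfect OOB accuracy", {
  set.seed(14)
  n <- 100
  x <- matrix(rnorm(n * 20), n, 20)
  y <- as.integer(x[, 7] > 0)
  fit <- rglm(x, y, n_bags = 30, seed = 2)
  oob <- rglm_oob(fit, x, y)
  expect_gt(oob$oob_accuracy, 0.95)
})

test_that("models survive a JSON round trip with bit-identical predictions", {
  prob <- make_sim_problem(50, 30, seed = 3)
  fit <- rglm(prob$x, prob$y, n_bags = 10, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_rglm(fit, path)
  fit2 <- read_rglm(path)
  expect_identical(predict(fit2, prob$x), predict(fit, prob$x))
  expect_identical(fit2$config, fit$config)
  expect_identical(fit2$bags[[3]]$selected_terms, fit$bags[[3]]$selected_terms)
})
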