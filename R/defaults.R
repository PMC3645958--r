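#' Effective number of features for a given interaction order
#'
#' Number of distinct covariates obtainable from `N` original features when
#' all interaction products of up to `order` distinct features are added:
#' order 1 gives `N`, order 2 gives `N + N(N-1)/2`, order 3 gives
#' `(N^3 + 5N)/6` (= N + C(N,2) + C(N,3)). This count drives the default
#' per-bag feature fraction; it deliberately counts distinct combinations
#' only, regardless of whether self-products are generated.
#'
#' @param N Number of original features (>= 1).
#' @param order Maximum interaction order, 1, 2 or 3.
#' @return The effective feature count N*.
#' @export
effective_feature_count <- function(N, order) {
  stopifnot(N >= 1)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  N <- as.numeric(N)
  switch(order,
         N,
         N + N * (N - 1) / 2,
         (N^3 + 5 * N) / 6)
}

#' Default fraction of features sampled per bag
#'
#' Piecewise rule in the effective feature count `n_star`: 1 for
#' `n_star <= 10`, the interpolation line `1.0276 - 0.00276 * n_star` for
#' `10 < n_star <= 300`, and 0.2 beyond. The constants are stored exactly
#' as printed so resolved defaults match the published table digit for
#' digit; they come from the line through (10, 1) and (300, 0.2).
#'
#' @param n_star Effective feature count (>= 1); may be a vector.
#' @return Fraction(s) in (0, 1].
#' @export
default_fraction <- function(n_star) {
  stopifnot(all(n_star >= 1))
  ifelse(n_star <= 10, 1,
         ifelse(n_star <= 300, 1.0276 - 0.00276 * n_star, 0.2))
}

#' Resolve the default number of features sampled per bag
#'
#' `round(default_fraction(N*) * N)` (half-up), clamped to `[1, N]`, where
#' `N*` is [effective_feature_count()] at the requested interaction order.
#'
#' @inheritParams effective_feature_count
#' @return Integer count in `[1, N]`.
#' @export
resolve_n_features_in_bag <- function(N, order) {
  stopifnot(N >= 1)
  frac <- default_fraction(effective_feature_count(N, order))
  as.integer(min(max(floor(frac * N + 0.5), 1), N))
}

#' Line through two points
#'
#' Exact two-point interpolation line; used to verify and regenerate the
#' default-fraction constants from the anchor points (10, 1) and (300, 0.2).
#'
#' @param p1,p2 Numeric length-2 vectors `(x, y)` with distinct x.
#' @return Named numeric vector `c(intercept, slope)`.
#' @export
interpolation_line <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  if (p1[1] == p2[1]) stop("degenerate: equal x coordinates")
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  c(intercept = p1[2] - slope * p1[1], slope = slope)
}
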