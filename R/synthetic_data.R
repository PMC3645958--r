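# Seeded generators: module-structured gene expression with a modular
# outcome, and the classical Gaussian two-class benchmarks.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# per-stream child seeds derived from one master seed (order-independent use)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

#' Simulation design for module-structured expression data
#'
#' Describes a gene-expression simulation with 5 gene modules (clusters) of
#' which 2 drive the outcome, and a fraction of unstructured background
#' genes. Module genes load on a latent module eigengene with per-gene
#' correlations drawn uniformly from `within_module_cor_range`; the
#' continuous outcome is the equal-weight sum of the two causal eigengenes
#' plus gaussian noise.
#'
#' @param n_samples,n_genes Dimensions of the simulated matrix.
#' @param n_modules Number of gene modules (default 5).
#' @param n_causal_modules Number of modules whose eigengenes drive the
#'   outcome (default 2).
#' @param background_fraction Fraction of genes with no module structure
#'   (default 0.45).
#' @param within_module_cor_range Range the per-gene module correlation is
#'   drawn from (default `c(0.3, 0.9)`).
#' @param outcome_noise_sd Standard deviation of the outcome noise
#'   (default 0.5; each causal eigengene is standard normal).
#' @param seed Integer seed making the draw reproducible.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_samples = 200L, n_genes = 500L, n_modules = 5L,
                       n_causal_modules = 2L, background_fraction = 0.45,
                       within_module_cor_range = c(0.3, 0.9),
                       outcome_noise_sd = 0.5, seed = 1L) {
  stopifnot(n_genes >= 20, n_samples >= 10,
            n_causal_modules <= n_modules,
            background_fraction >= 0, background_fraction < 1,
            length(within_module_cor_range) == 2,
            all(within_module_cor_range > 0),
            all(within_module_cor_range < 1),
            outcome_noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 n_causal_modules = as.integer(n_causal_modules),
                 background_fraction = background_fraction,
                 within_module_cor_range = within_module_cor_range,
                 outcome_noise_sd = outcome_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate module-structured gene expression with a modular outcome
#'
#' Each module has a latent standard-normal eigengene; module gene g equals
#' `r_g * eigengene + sqrt(1 - r_g^2) * noise` with `r_g` drawn from the
#' design's correlation range, so module genes correlate with their
#' eigengene by about `r_g`. Background genes are iid standard normal. The
#' continuous outcome is the sum of the causal-module eigengenes plus
#' `N(0, outcome_noise_sd^2)` noise. Deterministic given the design seed.
#'
#' @param design A [sim_design()] object.
#' @return List with `x` (samples x genes matrix), `y_cont` (continuous
#'   outcome), `module` (per-gene integer module label, 0 = background) and
#'   `eigengenes` (samples x modules matrix of latent module drivers).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    n <- design$n_samples
    G <- design$n_genes
    n_bg <- round(design$background_fraction * G)
    n_mod_genes <- G - n_bg
    sizes <- rep(n_mod_genes %/% design$n_modules, design$n_modules)
    extra <- n_mod_genes - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    module <- c(rep(seq_len(design$n_modules), times = sizes), rep(0L, n_bg))
    eig <- matrix(rnorm(n * design$n_modules), n, design$n_modules)
    x <- matrix(0, n, G)
    r <- numeric(G)
    for (g in seq_len(G)) {
      if (module[g] == 0L) {
        x[, g] <- rnorm(n)
      } else {
        r[g] <- stats::runif(1, design$within_module_cor_range[1],
                             design$within_module_cor_range[2])
        x[, g] <- r[g] * eig[, module[g]] + sqrt(1 - r[g]^2) * rnorm(n)
      }
    }
    colnames(x) <- paste0("gene", seq_len(G))
    y <- rowSums(eig[, seq_len(design$n_causal_modules), drop = FALSE]) +
      rnorm(n, sd = design$outcome_noise_sd)
    list(x = x, y_cont = y, module = module, eigengenes = eig)
  })
}

#' Dichotomize a continuous outcome at its median
#'
#' Returns 1 for values strictly above the median, 0 otherwise (ties at the
#' median are assigned 0). With an even number of distinct values this
#' yields exactly balanced classes.
#'
#' @param y_cont Numeric vector with at least two distinct values.
#' @return Integer 0/1 vector.
#' @export
dichotomize_median <- function(y_cont) {
  if (length(unique(y_cont)) < 2L) stop("constant outcome cannot be dichotomized")
  as.integer(y_cont > median(y_cont))
}

#' Classical Gaussian two-class benchmark generators
#'
#' Equal-prior two-class mixtures in `d` dimensions, after Breiman's
#' classical definitions: `ringnorm` -- class 0 ~ N(0, 4I), class 1 ~
#' N(a 1, I) with `a = 1/sqrt(d)`; `twonorm` -- classes ~ N(+/- a 1, I)
#' with `a = 2/sqrt(d)`; `threenorm` -- class 0 an equal mixture of
#' N(a 1, I) and N(-a 1, I), class 1 ~ N((a, -a, a, -a, ...), I) with
#' `a = 2/sqrt(d)`.
#'
#' @param name One of `"ringnorm"`, `"twonorm"`, `"threenorm"`.
#' @param n Number of samples (>= 2).
#' @param d Number of features (default 20).
#' @param seed Integer seed.
#' @return List with `x` (n x d matrix) and `y` (integer 0/1 labels).
#' @export
make_benchmark <- function(name = c("ringnorm", "twonorm", "threenorm"),
                           n, d = 20L, seed = 1L) {
  name <- match.arg(name)
  stopifnot(n >= 2, d >= 1)
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    x <- matrix(rnorm(n * d), n, d)
    if (name == "ringnorm") {
      a <- 1 / sqrt(d)
      x[y == 0L, ] <- 2 * x[y == 0L, , drop = FALSE]
      x[y == 1L, ] <- x[y == 1L, , drop = FALSE] + a
    } else if (name == "twonorm") {
      a <- 2 / sqrt(d)
      x[y == 0L, ] <- x[y == 0L, , drop = FALSE] - a
      x[y == 1L, ] <- x[y == 1L, , drop = FALSE] + a
    } else {
      a <- 2 / sqrt(d)
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      alt <- rep_len(c(a, -a), d)
      for (i in seq_len(n)) {
        x[i, ] <- x[i, ] + if (y[i] == 0L) sgn[i] * a else alt
      }
    }
    colnames(x) <- paste0("x", seq_len(d))
    list(x = x, y = as.integer(y))
  })
}
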