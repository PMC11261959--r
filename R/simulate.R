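#' Simulation scenario configuration
#'
#' Describes one data-generating condition: pair counts per zygosity, the
#' generating model family, its structural parameters, mixing proportions
#' (mixture families), the class-count rule and the root seed.
#'
#' Class counts per zygosity are either drawn multinomially from the mixing
#' proportions (`method = "multinomial"`, the default) or fixed to exact
#' quotas (`method = "quota"`, largest-remainder rounding), which reproduces
#' designs that merge one dataset per class, e.g. "25% of each of the four
#' classes".
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs (>= 0).
#' @param params a [doc_params()].
#' @param weights a [mixture_weights()]; required for `mix4`, ignored for
#'   single-class families.
#' @param family generating family: `"mix4"`, `"doc_xy"`, `"doc_yx"` or
#'   `"doc_bidir"`.
#' @param method class-count rule, `"multinomial"` or `"quota"`.
#' @param seed integer root seed; per-zygosity/per-class streams are derived
#'   from it by fixed offsets.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_mz, n_dz, params, weights = NULL,
                            family = c("mix4", "doc_xy", "doc_yx",
                                       "doc_bidir"),
                            method = c("multinomial", "quota"), seed = 1) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (n_mz < 0 || n_dz < 0) stop("pair counts must be non-negative")
  validate_doc_params(params)
  if (family == "mix4") {
    if (is.null(weights)) stop("mix4 scenarios require mixture_weights")
    stopifnot(inherits(weights, "mixture_weights"))
  }
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 params = params, weights = weights, family = family,
                 method = method, seed = as.integer(seed)),
            class = "scenario_config")
}

scenario_components <- function(cfg) {
  spec <- model_spec(if (cfg$family == "mix4") "mix4" else cfg$family)
  model_components(spec, cfg$params, cfg$weights)
}

class_counts <- function(n, omega, method, seed) {
  if (n == 0L) return(integer(length(omega)))
  if (method == "quota") {
    raw <- n * omega
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    as.integer(counts)
  } else {
    as.integer(with_seed(seed, stats::rmultinom(1, n, omega)[, 1]))
  }
}

# Draw n rows from N(mu, sigma) via the Cholesky factor.
rmvn_chol <- function(n, mu, sigma, seed) {
  R <- chol(sigma)
  Z <- with_seed(seed, matrix(stats::rnorm(n * 4), n, 4))
  sweep(Z %*% R, 2, mu, `+`)
}

assemble_dataset <- function(blocks, cfg) {
  df <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(zygosity = character(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0))
  if (nrow(df))
    df <- df[with_seed(cfg$seed + 997L, sample.int(nrow(df))), ]
  rownames(df) <- NULL
  twin_data(df)
}

#' Simulate a twin-pair dataset from class moments
#'
#' For each zygosity group, splits the pairs over the generating classes
#' (see [scenario_config()]) and draws each pair from the 4-variate Gaussian
#' implied by its class's [expected_pair_moments()].  Rows are shuffled.
#' Fully reproducible from the scenario seed; the caller's RNG state is
#' untouched.
#'
#' @param cfg a [scenario_config()].
#' @return A [twin_data()] dataset (empty when both pair counts are zero).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  comps <- scenario_components(cfg)
  blocks <- list()
  for (zi in 1:2) {
    z <- c("MZ", "DZ")[zi]
    n <- if (z == "MZ") cfg$n_mz else cfg$n_dz
    comp <- comps[[z]]
    counts <- class_counts(n, comp$omega, cfg$method,
                           seed = cfg$seed + 100L * zi)
    for (ci in seq_along(counts)) {
      if (counts[ci] == 0L) next
      vals <- rmvn_chol(counts[ci], comp$mus[, ci], comp$sigmas[, , ci],
                        seed = cfg$seed + 100L * zi + ci)
      blocks[[length(blocks) + 1L]] <-
        data.frame(zygosity = z, x1 = vals[, 1], y1 = vals[, 2],
                   x2 = vals[, 3], y2 = vals[, 4])
    }
  }
  assemble_dataset(blocks, cfg)
}

# Latent-factor covariance for one source across the pair: within-twin
# cross-trait correlation r, cross-twin same-trait correlation alpha,
# cross-twin cross-trait alpha * r.
latent_cov <- function(r, alpha) {
  R <- matrix(c(1, r, r, 1), 2, 2)
  rbind(cbind(R, alpha * R), cbind(alpha * R, R))
}

#' Simulate a twin-pair dataset through the latent structural model
#'
#' Validation path for [simulate_dataset()]: instead of drawing from the
#' implied class moments, draws the latent A, C and E factor scores per
#' trait and twin (twin correlations 1/0.5, 1 and 0; cross-trait
#' correlations `r_a`, `r_c`, `r_e`), weights them by the path loadings and
#' solves the phenotypes through the reduced form
#' `(I - B)^{-1} (nu + loadings %*% latents)`.  The two paths agree in
#' distribution; their large-sample moments coincide.
#'
#' @param cfg a [scenario_config()].
#' @return A [twin_data()] dataset.
#' @export
structural_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$params
  spec <- model_spec(if (cfg$family == "mix4") "mix4" else cfg$family)
  labels <- switch(spec$family,
    mix4 = mixture_classes(),
    doc_xy = mixture_classes()["con_xy"],
    doc_yx = mixture_classes()["con_yx"],
    doc_bidir = list(bidir = class_label("both", "both")))
  load_mat <- function(l_x, l_y) diag(c(l_x, l_y, l_x, l_y))
  chol_or_zero <- function(M) {
    # latent factor covariances can be singular when |r| = 1
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  blocks <- list()
  for (zi in 1:2) {
    z <- c("MZ", "DZ")[zi]
    alpha <- twin_alpha(z)
    n <- if (z == "MZ") cfg$n_mz else cfg$n_dz
    omega <- if (spec$family == "mix4") cfg$weights[[z]] else 1
    counts <- class_counts(n, omega, cfg$method, seed = cfg$seed + 100L * zi)
    roots <- list(A = chol_or_zero(latent_cov(p$r_a, alpha)),
                  C = chol_or_zero(latent_cov(p$r_c, 1)),
                  E = chol_or_zero(latent_cov(p$r_e, 0)))
    loads <- list(A = load_mat(p$a_x, p$a_y),
                  C = load_mat(p$c_x, p$c_y),
                  E = load_mat(p$e_x, p$e_y))
    for (ci in seq_along(counts)) {
      if (counts[ci] == 0L) next
      nc <- counts[ci]
      lab <- labels[[ci]]
      u <- matrix(0, nc, 4)
      seeds <- cfg$seed + 100L * zi + 10L * ci + 1:3
      for (k in 1:3) {
        src <- c("A", "C", "E")[k]
        Z <- with_seed(seeds[k], matrix(stats::rnorm(nc * 4), nc, 4))
        u <- u + Z %*% t(roots[[src]]) %*% loads[[src]]
      }
      inv <- solve(diag(4) - causal_matrix(lab, p$b_xy, p$b_yx))
      vals <- sweep(u, 2, intercept_vector(p, lab), `+`) %*% t(inv)
      blocks[[length(blocks) + 1L]] <-
        data.frame(zygosity = z, x1 = vals[, 1], y1 = vals[, 2],
                   x2 = vals[, 3], y2 = vals[, 4])
    }
  }
  assemble_dataset(blocks, cfg)
}
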