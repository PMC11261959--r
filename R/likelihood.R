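#' Log-density of one twin pair under a pair model
#'
#' Exact 4-variate Gaussian log-density of an observed pair vector
#' (x1, y1, x2, y2) at the model-implied mean and covariance.
#'
#' @param y4 numeric vector of length 4.
#' @param model a `pair_model` from [expected_pair_moments()] or
#'   [cholesky_ace_moments()].
#' @return The log-density (scalar).
#' @export
pair_log_density <- function(y4, model) {
  if (length(y4) != 4L || any(!is.finite(y4)))
    stop("y4 must be a finite length-4 vector")
  R <- tryCatch(chol(model$sigma),
                error = function(e) stop("pair model covariance is not positive definite"))
  z <- backsolve(R, y4 - model$mu, transpose = TRUE)
  -0.5 * (4 * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
}

# Lean version of expected_pair_moments for inner optimization loops: no
# re-validation, no eigenvalue check (the Cholesky in the density kernel
# rejects non-PD covariances).
pair_moments_fast <- function(params, label, zygosity) {
  B <- causal_matrix(label, params$b_xy, params$b_yx)
  inv <- solve(diag(4) - B)
  sigma <- inv %*% psi_matrix(params, zygosity) %*% t(inv)
  list(mu = as.numeric(inv %*% intercept_vector(params, label)),
       sigma = (sigma + t(sigma)) / 2)
}

# Class-specific pair models for a model spec, one set per zygosity.
# Returns list(MZ = list(mus, sigmas, omega, labels), DZ = ...), where mus is
# 4 x C, sigmas is 4 x 4 x C and omega the class prior probabilities.
model_components <- function(spec, params, weights = NULL, fast = FALSE) {
  if (spec$family == "cholesky") {
    comp1 <- function(z) {
      m <- cholesky_ace_moments(params, z)
      list(mus = matrix(m$mu, 4, 1), sigmas = array(m$sigma, c(4, 4, 1)),
           omega = 1, labels = "cholesky")
    }
    return(list(MZ = comp1("MZ"), DZ = comp1("DZ")))
  }
  labels <- switch(spec$family,
    mix4 = mixture_classes(),
    mix2 = mixture_classes()[c("con_xy", "con_yx")],
    doc_xy = mixture_classes()["con_xy"],
    doc_yx = mixture_classes()["con_yx"],
    doc_bidir = list(bidir = class_label("both", "both")))
  C <- length(labels)
  per_zyg <- function(z) {
    mus <- matrix(0, 4, C)
    sigmas <- array(0, c(4, 4, C))
    for (i in seq_len(C)) {
      m <- if (fast) pair_moments_fast(params, labels[[i]], z) else
        tryCatch(expected_pair_moments(params, labels[[i]], z),
                 error = function(e)
                   stop("class '", names(labels)[i], "' (", z, "): ",
                        conditionMessage(e)))
      mus[, i] <- m$mu
      sigmas[, , i] <- m$sigma
    }
    omega <- if (C == 1L) 1 else {
      if (is.null(weights)) stop("mixture family requires mixture_weights")
      w <- weights[[z]]
      if (spec$family == "mix2") {
        if (w[3] > 1e-10)
          stop("mix2 requires discordant proportions fixed at 0")
        w[1:2] / sum(w[1:2])
      } else w
    }
    list(mus = mus, sigmas = sigmas, omega = omega, labels = names(labels))
  }
  list(MZ = per_zyg("MZ"), DZ = per_zyg("DZ"))
}

# Row-wise log-sum-exp of an N x C matrix.
row_logsumexp <- function(M) {
  if (ncol(M) == 1L) return(M[, 1])
  m <- do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
  m + log(rowSums(exp(M - m)))
}

# N x C matrix of per-class pair log-densities for rows of a twin_data
# subset, given one zygosity's components.
class_log_densities <- function(values, comp) {
  cpp_class_logdens(values, comp$mus, comp$sigmas)
}

#' Minus twice the mixture log-likelihood of a twin dataset
#'
#' Evaluates `-2 * sum_pairs log sum_classes omega_c Phi_c(pair)`, where each
#' class density is the 4-variate Gaussian implied by the model family, the
#' pair's zygosity selects the class moments and mixing proportions, and the
#' inner sum is computed with log-sum-exp stabilization.  Single-class
#' families reduce to the plain Gaussian log-likelihood; `weights` is then
#' ignored.
#'
#' @param data a [twin_data()] dataset.
#' @param spec a [model_spec()].
#' @param params a [doc_params()] (or [chol_ace_params()] for the cholesky
#'   family).
#' @param weights a [mixture_weights()] for mixture families.
#' @param missing `"fail"` (default: any `NA` is an error; pairs are
#'   complete cases) or `"marginal"`: partially observed pairs contribute
#'   the Gaussian marginal density of their observed entries (per class).
#' @return `-2` times the log-likelihood (scalar).
#' @export
minus2_loglik <- function(data, spec, params, weights = NULL,
                          missing = c("fail", "marginal")) {
  stopifnot(inherits(data, "twin_data"))
  missing <- match.arg(missing)
  comps <- model_components(spec, params, weights)
  values <- split_values(data)
  if (missing == "fail" && (anyNA(values$MZ) || anyNA(values$DZ)))
    stop("dataset contains missing trait values; use missing = 'marginal' ",
         "or complete cases")
  minus2ll_from_comps(values, comps)
}

# Per-zygosity data matrices, extracted once so repeated likelihood
# evaluations during optimization skip the data-frame subsetting.
split_values <- function(data) {
  vals <- as.matrix(data[c("x1", "y1", "x2", "y2")])
  list(MZ = vals[data$zygosity == "MZ", , drop = FALSE],
       DZ = vals[data$zygosity == "DZ", , drop = FALSE])
}

minus2ll_from_comps <- function(values, comps) {
  total <- 0
  for (z in c("MZ", "DZ")) {
    X <- values[[z]]
    if (nrow(X) == 0L) next
    logw <- log(pmax(comps[[z]]$omega, 1e-300))
    if (!anyNA(X)) {
      total <- total + cpp_mix_loglik(X, comps[[z]]$mus, comps[[z]]$sigmas,
                                      logw)
      next
    }
    # marginalize each missingness pattern over its observed entries
    pattern <- apply(!is.na(X), 1, function(r)
      paste(as.integer(r), collapse = ""))
    for (pat in unique(pattern)) {
      obs <- which(strsplit(pat, "")[[1]] == "1")
      rows <- X[pattern == pat, obs, drop = FALSE]
      if (length(obs) == 0L) next  # nothing observed, no contribution
      total <- total + cpp_mix_loglik(
        rows, comps[[z]]$mus[obs, , drop = FALSE],
        comps[[z]]$sigmas[obs, obs, , drop = FALSE], logw)
    }
  }
  -2 * total
}

#' Akaike Information Criterion
#'
#' `AIC = -2LL + 2k`, the convention under which the model-comparison tables
#' in this package are computed (minus twice the log-likelihood plus twice
#' the number of free parameters; lowest value preferred).
#'
#' @param minus2ll minus twice the maximized log-likelihood.
#' @param k number of free parameters (non-negative integer).
#' @return The AIC value.
#' @export
aic <- function(minus2ll, k) {
  stopifnot(is.numeric(minus2ll), length(minus2ll) == 1L, k >= 0)
  minus2ll + 2 * k
}
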