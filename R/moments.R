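#' Structural causal-path matrix for a twin pair
#'
#' Builds the 4 x 4 matrix B of causal regression paths among the pair
#' vector (x1, y1, x2, y2).  Each twin contributes a 2 x 2 block with the
#' path of its causal direction: X-causes-Y puts `b_xy` in the (y <- x)
#' cell, Y-causes-X puts `b_yx` in the (x <- y) cell, and the bidirectional
#' model (`direction = "both"`) sets both within the same twin.
#'
#' @param label a [class_label()].
#' @param b_xy,b_yx causal coefficients.
#' @return A 4 x 4 matrix B such that `(I - B)` is invertible.
#' @export
causal_matrix <- function(label, b_xy, b_yx) {
  stopifnot(inherits(label, "class_label"))
  if (label$twin1 == "both" || label$twin2 == "both") {
    if (abs(b_xy * b_yx - 1) < 1e-12)
      stop("bidirectional paths with b_xy * b_yx = 1 give a singular reduced form")
  }
  B <- matrix(0, 4, 4)
  fill <- function(B, dir, ix, iy) {
    if (dir %in% c("xy", "both")) B[iy, ix] <- b_xy
    if (dir %in% c("yx", "both")) B[ix, iy] <- b_yx
    B
  }
  B <- fill(B, label$twin1, 1L, 2L)
  B <- fill(B, label$twin2, 3L, 4L)
  B
}

# 4x4 covariance of the pre-causal residuals u = a*A + c*C + e*E for the
# pair vector (x1, y1, x2, y2).  Cross-twin correlation of A is 1 (MZ) or
# 0.5 (DZ), of C is 1, of E is 0; cross-trait latent correlations r_a, r_c,
# r_e apply within twin and, scaled by the factor's twin correlation,
# across twins.
psi_matrix <- function(params, zygosity) {
  alpha <- twin_alpha(zygosity)
  with(params, {
    within <- matrix(c(
      a_x^2 + c_x^2 + e_x^2,
      r_a * a_x * a_y + r_c * c_x * c_y + r_e * e_x * e_y,
      r_a * a_x * a_y + r_c * c_x * c_y + r_e * e_x * e_y,
      a_y^2 + c_y^2 + e_y^2), 2, 2)
    cross <- matrix(c(
      alpha * a_x^2 + c_x^2,
      alpha * r_a * a_x * a_y + r_c * c_x * c_y,
      alpha * r_a * a_x * a_y + r_c * c_x * c_y,
      alpha * a_y^2 + c_y^2), 2, 2)
    rbind(cbind(within, cross), cbind(cross, within))
  })
}

twin_alpha <- function(zygosity) {
  if (!zygosity %in% c("MZ", "DZ"))
    stop("zygosity must be 'MZ' or 'DZ'")
  if (zygosity == "MZ") 1 else 0.5
}

# Structural intercept vector nu for the pair under a class label.
intercept_vector <- function(params, label) {
  nu_for <- function(dir) {
    switch(dir,
           xy = c(params$nu_x_xy, params$nu_y_xy),
           yx = c(params$nu_x_yx, params$nu_y_yx),
           both = c(params$nu_x_xy, params$nu_y_xy))
  }
  c(nu_for(label$twin1), nu_for(label$twin2))
}

#' Expected mean and covariance of a twin pair
#'
#' Computes the model-implied 4-vector mean and 4 x 4 covariance of the pair
#' vector (x1, y1, x2, y2) for one causal-direction class and zygosity,
#' using the reduced form of the path model:
#' `sigma = (I - B)^{-1} Psi (I - B)^{-T}` and `mu = (I - B)^{-1} nu`,
#' where B holds the causal paths, Psi the covariance of the pre-causal ACE
#' residuals, and nu the structural intercepts of each twin's class.
#'
#' @param params a [doc_params()] object.
#' @param label a [class_label()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A `pair_model`: list with `mu` (length 4) and `sigma` (4 x 4
#'   symmetric positive definite).
#' @export
expected_pair_moments <- function(params, label, zygosity) {
  validate_doc_params(params)
  B <- causal_matrix(label, params$b_xy, params$b_yx)
  Imb <- diag(4) - B
  inv <- solve(Imb)
  psi <- psi_matrix(params, zygosity)
  sigma <- inv %*% psi %*% t(inv)
  sigma <- (sigma + t(sigma)) / 2
  mu <- as.numeric(inv %*% intercept_vector(params, label))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop(sprintf(
      "expected covariance for class (%s, %s), %s is not positive definite",
      label$twin1, label$twin2, zygosity))
  structure(list(mu = mu, sigma = sigma), class = "pair_model")
}

#' Expected pair moments under the Cholesky bivariate ACE model
#'
#' Within-twin 2 x 2 covariance block is the sum of the three factor
#' contributions `L_k L_k'`; the cross-twin block scales the A contribution
#' by the twin correlation (1 for MZ, 0.5 for DZ) and keeps the full C
#' contribution.
#'
#' @param chol_params a [chol_ace_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A `pair_model` (see [expected_pair_moments()]).
#' @export
cholesky_ace_moments <- function(chol_params, zygosity) {
  stopifnot(inherits(chol_params, "chol_ace_params"))
  alpha <- twin_alpha(zygosity)
  A <- tcrossprod(chol_params$L_a)
  C <- tcrossprod(chol_params$L_c)
  E <- tcrossprod(chol_params$L_e)
  within <- A + C + E
  cross <- alpha * A + C
  sigma <- rbind(cbind(within, cross), cbind(cross, within))
  structure(list(mu = rep(chol_params$mean, 2), sigma = sigma),
            class = "pair_model")
}

#' Number of free parameters of a model family
#'
#' Counts: `mix4` has 8 structural parameters (six loadings, two causal
#' paths), 4 class intercepts and 2 free mixing proportions per zygosity
#' group (after the sum-to-one and discordant-equality constraints), giving
#' 16; `mix2` drops the discordant classes (1 free proportion per group),
#' giving 14; `doc_xy`/`doc_yx` have 9 (six loadings, one path, two
#' intercepts); `doc_bidir` 10; `cholesky` 11 (three lower-triangular 2 x 2
#' factors and two means).  Freeing `r_a` adds one.
#'
#' @param spec a [model_spec()].
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  n_zyg <- if (spec$proportions_by_zygosity) 2L else 1L
  k <- switch(spec$family,
              mix4 = 12L + 2L * n_zyg,
              mix2 = 12L + 1L * n_zyg,
              doc_xy = 9L,
              doc_yx = 9L,
              doc_bidir = 10L,
              cholesky = 11L,
              stop("unknown model family: ", spec$family))
  if (spec$confound_ra_free) k <- k + 1L
  k
}

#' Degrees of freedom of a fitted model
#'
#' Raw-data (FIML) accounting: df equals the number of observed data points
#' (4 per complete twin pair) minus the number of free parameters.
#'
#' @param spec a [model_spec()].
#' @param n_datapoints total number of observed (non-missing) trait values.
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec, n_datapoints) {
  k <- count_free_parameters(spec)
  df <- as.integer(n_datapoints) - k
  if (df <= 0)
    stop("model has ", k, " free parameters but only ", n_datapoints,
         " data points: over-parameterized")
  df
}
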