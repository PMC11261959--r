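# Bijective maps between each family's natural-scale parameters and an
# unconstrained optimization vector.  Conventions: unique-environment
# loadings and Cholesky E-factor diagonals via log (strict positivity);
# other loadings and factor diagonals via the abs convention (identity
# forward, absolute value back -- the non-negative representative of a
# sign-indeterminate loading); correlations via atanh/tanh; mixing
# proportions via multinomial logits relative to the discordant class, so
# that equal quarters map to logits (0, 0) and omega3 = omega4 by
# construction; causal paths, intercepts and means untouched.

doc_structural_names <- function(spec) {
  base <- c("a_x", "c_x", "e_x", "a_y", "c_y", "e_y")
  extra <- switch(spec$family,
    mix4 = c("b_xy", "b_yx", "nu_x_xy", "nu_y_xy", "nu_x_yx", "nu_y_yx"),
    mix2 = c("b_xy", "b_yx", "nu_x_xy", "nu_y_xy", "nu_x_yx", "nu_y_yx"),
    doc_xy = c("b_xy", "nu_x_xy", "nu_y_xy"),
    doc_yx = c("b_yx", "nu_x_yx", "nu_y_yx"),
    doc_bidir = c("b_xy", "b_yx", "nu_x_xy", "nu_y_xy"))
  out <- c(base, extra)
  if (spec$confound_ra_free) out <- c(out, "r_a")
  out
}

weight_par_names <- function(spec) {
  if (!is_mixture_family(spec)) return(character(0))
  zyg <- if (spec$proportions_by_zygosity) c("MZ", "DZ") else "all"
  per <- if (spec$family == "mix4") c("w1", "w2") else "w1"
  as.vector(t(outer(zyg, per, function(z, p) paste(p, z, sep = "."))))
}

par_names <- function(spec) {
  if (spec$family == "cholesky")
    return(c("la11", "la21", "la22", "lc11", "lc21", "lc22",
             "le11", "le21", "le22", "m_x", "m_y"))
  c(doc_structural_names(spec), weight_par_names(spec))
}

#' Map natural-scale parameters to the unconstrained optimization scale
#'
#' @param spec a [model_spec()].
#' @param params a [doc_params()] or [chol_ace_params()] matching the family.
#' @param weights a [mixture_weights()] for mixture families.
#' @return Named numeric vector on the unconstrained scale; the inverse is
#'   [untransform_parameters()] and the round trip is exact to numerical
#'   precision.
#' @export
transform_parameters <- function(spec, params, weights = NULL) {
  if (spec$family == "cholesky") {
    stopifnot(inherits(params, "chol_ace_params"))
    v <- c(la11 = params$L_a[1, 1], la21 = params$L_a[2, 1],
           la22 = params$L_a[2, 2],
           lc11 = params$L_c[1, 1], lc21 = params$L_c[2, 1],
           lc22 = params$L_c[2, 2],
           le11 = params$L_e[1, 1], le21 = params$L_e[2, 1],
           le22 = params$L_e[2, 2],
           m_x = params$mean[1], m_y = params$mean[2])
    if (any(v[c("la11", "la22", "lc11", "lc22")] < 0))
      stop("diagonal factor loadings must be non-negative")
    if (any(v[c("le11", "le22")] <= 0))
      stop("E-factor diagonal must be strictly positive")
    v[c("le11", "le22")] <- log(v[c("le11", "le22")])
    return(v)
  }
  validate_doc_params(params)
  nm <- doc_structural_names(spec)
  v <- unlist(params)[nm]
  v[c("e_x", "e_y")] <- log(v[c("e_x", "e_y")])
  if (spec$confound_ra_free) {
    if (abs(params$r_a) >= 1) stop("r_a must lie strictly inside (-1, 1)")
    v["r_a"] <- atanh(params$r_a)
  }
  if (is_mixture_family(spec)) {
    if (is.null(weights)) stop("mixture family requires mixture_weights")
    wnm <- weight_par_names(spec)
    wv <- numeric(0)
    zygs <- if (spec$proportions_by_zygosity) c("MZ", "DZ") else "all"
    for (z in zygs) {
      o <- if (z == "all") weights$MZ else weights[[z]]
      if (spec$family == "mix4") {
        if (any(o[1:3] <= 0))
          stop("mix4 proportions must be strictly positive to transform")
        wv <- c(wv, log(o[1] / o[3]), log(o[2] / o[3]))
      } else {
        if (o[1] <= 0 || o[2] <= 0)
          stop("mix2 concordant proportions must be strictly positive")
        wv <- c(wv, log(o[1] / o[2]))
      }
    }
    names(wv) <- wnm
    v <- c(v, wv)
  }
  v
}

#' Map an unconstrained vector back to natural-scale parameters
#'
#' @param spec a [model_spec()].
#' @param u named numeric vector as produced by [transform_parameters()].
#' @return A list with elements `params` (a [doc_params()] or
#'   [chol_ace_params()]) and `weights` (a [mixture_weights()] or `NULL`).
#' @export
untransform_parameters <- function(spec, u) {
  nm <- par_names(spec)
  if (length(u) != length(nm))
    stop("expected ", length(nm), " parameters for family ", spec$family)
  names(u) <- nm
  if (spec$family == "cholesky") {
    L <- function(d1, o, d2) matrix(c(d1, o, 0, d2), 2, 2)
    params <- chol_ace_params(
      L_a = L(abs(u["la11"]), u["la21"], abs(u["la22"])),
      L_c = L(abs(u["lc11"]), u["lc21"], abs(u["lc22"])),
      L_e = L(exp(u["le11"]), u["le21"], exp(u["le22"])),
      mean = c(u["m_x"], u["m_y"]))
    return(list(params = params, weights = NULL))
  }
  get0n <- function(key) if (key %in% nm) unname(u[key]) else 0
  params <- doc_params(
    a_x = abs(u["a_x"]), c_x = abs(u["c_x"]), e_x = exp(u["e_x"]),
    a_y = abs(u["a_y"]), c_y = abs(u["c_y"]), e_y = exp(u["e_y"]),
    b_xy = get0n("b_xy"), b_yx = get0n("b_yx"),
    nu_x_xy = get0n("nu_x_xy"), nu_y_xy = get0n("nu_y_xy"),
    nu_x_yx = get0n("nu_x_yx"), nu_y_yx = get0n("nu_y_yx"),
    r_a = if (spec$confound_ra_free) tanh(unname(u["r_a"])) else 0)
  weights <- NULL
  if (is_mixture_family(spec)) {
    omega_from <- function(wv) {
      if (spec$family == "mix4") {
        d <- exp(wv[1]) + exp(wv[2]) + 2
        c(exp(wv[1]) / d, exp(wv[2]) / d, 1 / d, 1 / d)
      } else {
        p1 <- stats::plogis(wv[1])
        c(p1, 1 - p1, 0, 0)
      }
    }
    per <- if (spec$family == "mix4") 2L else 1L
    wstart <- length(doc_structural_names(spec))
    if (spec$proportions_by_zygosity) {
      o_mz <- omega_from(unname(u[wstart + seq_len(per)]))
      o_dz <- omega_from(unname(u[wstart + per + seq_len(per)]))
    } else {
      o_mz <- o_dz <- omega_from(unname(u[wstart + seq_len(per)]))
    }
    weights <- mixture_weights(o_mz, o_dz)
  }
  list(params = params, weights = weights)
}
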