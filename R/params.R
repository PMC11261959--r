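#' Structural parameters of a Direction-of-Causation twin model
#'
#' Bundles every structural parameter of one DoC model variant: ACE path
#' loadings for each trait, causal regression coefficients in both
#' directions, structural intercepts for each causal-direction class, and
#' latent cross-trait confounding correlations.
#'
#' Loadings are on the trait standard-deviation scale and constrained
#' non-negative (they are sign-indeterminate, so the non-negative solution is
#' taken as canonical); the unique-environment loadings must be strictly
#' positive so every class density is proper.  In the base mixture model all
#' three confounding correlations are fixed at zero; the extended variant
#' frees `r_a` (equated across classes).
#'
#' Intercepts are *structural*: the observed class means are obtained by
#' propagating them through the reduced form, e.g. for a twin in the X-causes-Y
#' class, `E[x] = nu_x_xy` and `E[y] = nu_y_xy + b_xy * nu_x_xy`.  For
#' single-class model families (`doc_xy`, `doc_yx`, `doc_bidir`) the `_xy`
#' slots hold the single pair of intercepts.
#'
#' @param a_x,c_x,e_x additive-genetic, shared-environment and
#'   unique-environment path loadings for trait X (non-negative; `e_x > 0`).
#' @param a_y,c_y,e_y the same loadings for trait Y.
#' @param b_xy causal regression of Y on X (effect of X on Y).
#' @param b_yx causal regression of X on Y (effect of Y on X).
#' @param nu_x_xy,nu_y_xy structural intercepts of X and Y in the
#'   X-causes-Y class.
#' @param nu_x_yx,nu_y_yx structural intercepts in the Y-causes-X class.
#' @param r_a,r_c,r_e latent cross-trait correlations of the A, C and E
#'   factors, each in `[-1, 1]`.
#' @return An object of class `doc_params` (a named list).
#' @seealso [expected_pair_moments()], [intercepts_for_class_means()]
#' @examples
#' p <- doc_params(a_x = sqrt(0.7), c_x = 0, e_x = sqrt(0.3),
#'                 a_y = sqrt(0.1), c_y = sqrt(0.6), e_y = sqrt(0.3),
#'                 b_xy = 0.5, b_yx = 0.5)
#' expected_pair_moments(p, class_label("xy", "xy"), "MZ")$sigma
#' @export
doc_params <- function(a_x, c_x, e_x, a_y, c_y, e_y,
                       b_xy = 0, b_yx = 0,
                       nu_x_xy = 0, nu_y_xy = 0,
                       nu_x_yx = 0, nu_y_yx = 0,
                       r_a = 0, r_c = 0, r_e = 0) {
  p <- list(a_x = a_x, c_x = c_x, e_x = e_x,
            a_y = a_y, c_y = c_y, e_y = e_y,
            b_xy = b_xy, b_yx = b_yx,
            nu_x_xy = nu_x_xy, nu_y_xy = nu_y_xy,
            nu_x_yx = nu_x_yx, nu_y_yx = nu_y_yx,
            r_a = r_a, r_c = r_c, r_e = r_e)
  p <- lapply(p, as.numeric)
  class(p) <- "doc_params"
  validate_doc_params(p)
  p
}

validate_doc_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                 logical(1))
  if (!all(num1)) stop("all doc_params fields must be finite scalars")
  loadings <- c("a_x", "c_x", "e_x", "a_y", "c_y", "e_y")
  if (any(unlist(p[loadings]) < 0))
    stop("path loadings must be non-negative (sign convention)")
  if (p$e_x <= 0 || p$e_y <= 0)
    stop("unique-environment loadings e_x and e_y must be strictly positive")
  rs <- unlist(p[c("r_a", "r_c", "r_e")])
  if (any(rs < -1 | rs > 1))
    stop("confounding correlations r_a, r_c, r_e must lie in [-1, 1]")
  invisible(p)
}

#' @export
print.doc_params <- function(x, ...) {
  cat("Direction-of-causation twin model parameters\n")
  cat(sprintf("  loadings X (a,c,e): %.3f %.3f %.3f   Y: %.3f %.3f %.3f\n",
              x$a_x, x$c_x, x$e_x, x$a_y, x$c_y, x$e_y))
  cat(sprintf("  causal paths: b_xy = %.3f, b_yx = %.3f\n", x$b_xy, x$b_yx))
  cat(sprintf("  intercepts X->Y class: (%.3f, %.3f)  Y->X class: (%.3f, %.3f)\n",
              x$nu_x_xy, x$nu_y_xy, x$nu_x_yx, x$nu_y_yx))
  cat(sprintf("  confounding: r_a = %.3f, r_c = %.3f, r_e = %.3f\n",
              x$r_a, x$r_c, x$r_e))
  invisible(x)
}

#' Causal-direction class label for a twin pair
#'
#' A twin pair belongs to one of four causal-direction classes: both twins
#' X-causes-Y, both Y-causes-X, or one of the two discordant orderings.
#' Directions are coded `"xy"` (X causes Y) and `"yx"` (Y causes X);
#' `"both"` is used internally for the bidirectional single-class family.
#'
#' @param direction_twin1,direction_twin2 `"xy"`, `"yx"` or `"both"`.
#' @return An object of class `class_label`.
#' @export
class_label <- function(direction_twin1, direction_twin2) {
  ok <- c("xy", "yx", "both")
  if (!(direction_twin1 %in% ok) || !(direction_twin2 %in% ok))
    stop("directions must be one of 'xy', 'yx', 'both'")
  structure(list(twin1 = direction_twin1, twin2 = direction_twin2),
            class = "class_label")
}

#' The four mixture classes, in canonical order
#'
#' Class 1: concordant X-causes-Y; class 2: concordant Y-causes-X;
#' classes 3 and 4: the two discordant orderings.  Twin ordering within a
#' pair is arbitrary, so the discordant classes share parameters and mixing
#' proportion.
#'
#' @return A named list of four [class_label()] objects.
#' @export
mixture_classes <- function() {
  list(con_xy = class_label("xy", "xy"),
       con_yx = class_label("yx", "yx"),
       dis_xy_yx = class_label("xy", "yx"),
       dis_yx_xy = class_label("yx", "xy"))
}

#' Cholesky bivariate ACE parameters
#'
#' The saturated comparison model: each of the A, C and E variance sources
#' contributes to the two traits through a lower-triangular 2 x 2 factor, and
#' the trait means are free (equal across twins and zygosities).  The
#' unidirectional DoC models are nested within this family.
#'
#' @param L_a,L_c,L_e lower-triangular 2 x 2 factor matrices for the A, C and
#'   E sources; diagonal of `L_e` must be strictly positive.
#' @param mean length-2 vector of trait means (x, y).
#' @return An object of class `chol_ace_params`.
#' @export
chol_ace_params <- function(L_a, L_c, L_e, mean = c(0, 0)) {
  chk <- function(L, nm) {
    L <- as.matrix(L)
    if (!all(dim(L) == c(2L, 2L))) stop(nm, " must be 2 x 2")
    if (abs(L[1, 2]) > 0) stop(nm, " must be lower triangular")
    L
  }
  L_a <- chk(L_a, "L_a"); L_c <- chk(L_c, "L_c"); L_e <- chk(L_e, "L_e")
  if (any(diag(L_e) <= 0)) stop("diagonal of L_e must be strictly positive")
  structure(list(L_a = L_a, L_c = L_c, L_e = L_e, mean = as.numeric(mean)),
            class = "chol_ace_params")
}

#' Model-family specification
#'
#' Names one of the six model families compared in the simulation study and
#' its constraint set.
#'
#' Families: `mix4` (four causal-direction classes per zygosity group, the
#' full mixture), `mix2` (concordant classes only; discordant proportions
#' fixed at zero), `doc_xy` / `doc_yx` (homogeneous unidirectional DoC),
#' `doc_bidir` (homogeneous bidirectional DoC), `cholesky` (saturated
#' bivariate ACE with all three cross-trait correlations estimated).
#'
#' @param family one of `"mix4"`, `"mix2"`, `"doc_xy"`, `"doc_yx"`,
#'   `"doc_bidir"`, `"cholesky"`.
#' @param confound_ra_free logical; the extended variant in which the
#'   additive-genetic cross-trait correlation `r_a` is freely estimated
#'   (equated across classes).  Not applicable to the Cholesky family, which
#'   always estimates all three correlations.
#' @param proportions_by_zygosity logical; if `TRUE` (default) the mixing
#'   proportions are free per zygosity group, if `FALSE` they are equated
#'   across MZ and DZ.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("mix4", "mix2", "doc_xy", "doc_yx",
                                  "doc_bidir", "cholesky"),
                       confound_ra_free = FALSE,
                       proportions_by_zygosity = TRUE) {
  family <- match.arg(family)
  if (family == "cholesky" && confound_ra_free)
    stop("confound_ra_free is not applicable to the cholesky family, ",
         "which always estimates r_a, r_c and r_e")
  structure(list(family = family,
                 confound_ra_free = isTRUE(confound_ra_free),
                 proportions_by_zygosity = isTRUE(proportions_by_zygosity)),
            class = "model_spec")
}

is_mixture_family <- function(spec) spec$family %in% c("mix4", "mix2")

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("mixdoc model spec: family = %s%s%s\n", x$family,
              if (x$confound_ra_free) ", r_a free" else "",
              if (is_mixture_family(x) && !x$proportions_by_zygosity)
                ", proportions equated across zygosity" else ""))
  invisible(x)
}

#' Mixing proportions for the causal-direction classes
#'
#' Per-zygosity prior class probabilities over the four classes in the order
#' of [mixture_classes()].  Each vector must sum to one and the two
#' discordant proportions must be equal, because twin ordering within a pair
#' is arbitrary.
#'
#' @param omega_mz,omega_dz length-4 non-negative vectors summing to 1 with
#'   `omega[3] == omega[4]`.  `omega_dz` defaults to `omega_mz`.
#' @return An object of class `mixture_weights`.
#' @export
mixture_weights <- function(omega_mz, omega_dz = omega_mz) {
  w <- list(MZ = as.numeric(omega_mz), DZ = as.numeric(omega_dz))
  for (z in names(w)) {
    o <- w[[z]]
    if (length(o) != 4L || any(!is.finite(o)) || any(o < -1e-12))
      stop("each omega vector must be 4 non-negative proportions")
    if (abs(sum(o) - 1) > 1e-8)
      stop("omega vector for ", z, " must sum to 1")
    if (abs(o[3] - o[4]) > 1e-8)
      stop("discordant class proportions (omega[3], omega[4]) must be equal")
    w[[z]] <- pmax(o, 0) / sum(pmax(o, 0))
  }
  structure(w, class = "mixture_weights")
}

#' Structural intercepts that yield given phenotypic class means
#'
#' Class separation in the mixture is usually described in terms of observed
#' (phenotypic) trait means per causal-direction class.  Because the model
#' parameterizes structural intercepts that are propagated through the
#' reduced form, this helper inverts that map: it returns the intercepts for
#' which the X-causes-Y class has phenotypic means `mean_xy` and the
#' Y-causes-X class has means `mean_yx`.
#'
#' @param mean_xy,mean_yx length-2 vectors `(E[x], E[y])` of phenotypic means
#'   for the two concordant classes.
#' @param b_xy,b_yx causal coefficients of the model.
#' @return A named list with the four `nu_*` intercepts.
#' @export
intercepts_for_class_means <- function(mean_xy, mean_yx, b_xy, b_yx) {
  list(nu_x_xy = mean_xy[1],
       nu_y_xy = mean_xy[2] - b_xy * mean_xy[1],
       nu_x_yx = mean_yx[1] - b_yx * mean_yx[2],
       nu_y_yx = mean_yx[2])
}
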