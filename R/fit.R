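# Maximum-likelihood fitting of the six model families: quasi-Newton
# optimization (nlminb/PORT) on the unconstrained scale with multiple
# perturbed starts around method-of-moments initial values.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Crude univariate ACE variance split from MZ/DZ cross-twin covariances,
# clipped away from the boundary so initial covariances are proper.
uni_ace_init <- function(t1, t2, zyg) {
  v <- stats::var(c(t1, t2))
  mz <- zyg == "MZ"; dz <- zyg == "DZ"
  if (sum(mz) > 2 && sum(dz) > 2) {
    cmz <- stats::cov(t1[mz], t2[mz])
    cdz <- stats::cov(t1[dz], t2[dz])
    a2 <- 2 * (cmz - cdz); c2 <- 2 * cdz - cmz
  } else {
    a2 <- c2 <- v / 4
  }
  a2 <- min(max(a2, 0.02 * v), 0.9 * v)
  c2 <- min(max(c2, 0.02 * v), 0.9 * v)
  if (a2 + c2 > 0.9 * v) {
    s <- 0.9 * v / (a2 + c2); a2 <- a2 * s; c2 <- c2 * s
  }
  c(a = sqrt(a2), c = sqrt(c2), e = sqrt(v - a2 - c2))
}

# Method-of-moments initial values: univariate ACE splits per trait, causal
# paths from pooled cross-trait regressions, class means from a provisional
# 2-means clustering of the pair averages (mixture families only).
init_values <- function(data, spec, seed = 1) {
  x <- c(data$x1, data$x2); y <- c(data$y1, data$y2)
  ax <- uni_ace_init(data$x1, data$x2, data$zygosity)
  ay <- uni_ace_init(data$y1, data$y2, data$zygosity)
  cxy <- stats::cov(x, y)
  b_xy0 <- cxy / stats::var(x)
  b_yx0 <- cxy / stats::var(y)
  if (spec$family == "cholesky") {
    ind <- rbind(cbind(data$x1, data$y1), cbind(data$x2, data$y2))
    Sw <- stats::cov(ind)
    cross_cov <- function(z) {
      sel <- data$zygosity == z
      if (sum(sel) < 3) return(Sw / 3)
      M <- stats::cov(cbind(data$x1, data$y1)[sel, , drop = FALSE],
                      cbind(data$x2, data$y2)[sel, , drop = FALSE])
      (M + t(M)) / 2
    }
    Smz <- cross_cov("MZ"); Sdz <- cross_cov("DZ")
    pd_clip <- function(M, floor) {
      e <- eigen((M + t(M)) / 2, symmetric = TRUE)
      e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
    }
    A <- pd_clip(2 * (Smz - Sdz), 1e-3)
    C <- pd_clip(2 * Sdz - Smz, 1e-3)
    E <- pd_clip(Sw - A - C, 0.05 * mean(diag(Sw)))
    lower <- function(M) t(chol(M))
    return(list(params = chol_ace_params(lower(A), lower(C), lower(E),
                                         mean = colMeans(ind)),
                weights = NULL))
  }
  shrink <- if (is_mixture_family(spec)) 0.7 else 1
  b_xy0 <- shrink * b_xy0; b_yx0 <- shrink * b_yx0
  if (is_mixture_family(spec)) {
    km <- with_seed(seed, stats::kmeans(cbind((data$x1 + data$x2) / 2,
                                              (data$y1 + data$y2) / 2),
                                        centers = 2, nstart = 5))
    ord <- order(km$centers[, 1], decreasing = TRUE)
    m_xy <- km$centers[ord[1], ]; m_yx <- km$centers[ord[2], ]
    nus <- intercepts_for_class_means(m_xy, m_yx, b_xy0, b_yx0)
    weights <- mixture_weights(if (spec$family == "mix4")
      c(0.3, 0.3, 0.2, 0.2) else c(0.5, 0.5, 0, 0))
  } else {
    mx <- mean(x); my <- mean(y)
    nus <- switch(spec$family,
      doc_xy = list(nu_x_xy = mx, nu_y_xy = my - b_xy0 * mx,
                    nu_x_yx = 0, nu_y_yx = 0),
      doc_yx = list(nu_x_xy = 0, nu_y_xy = 0,
                    nu_x_yx = mx - b_yx0 * my, nu_y_yx = my),
      doc_bidir = {
        det0 <- 1 - 0.25 * b_xy0 * b_yx0
        list(nu_x_xy = mx - 0.5 * b_yx0 * my, nu_y_xy = my - 0.5 * b_xy0 * mx,
             nu_x_yx = 0, nu_y_yx = 0)
      })
    weights <- NULL
  }
  use_b_xy <- spec$family %in% c("mix4", "mix2", "doc_xy", "doc_bidir")
  use_b_yx <- spec$family %in% c("mix4", "mix2", "doc_yx", "doc_bidir")
  params <- doc_params(
    a_x = ax["a"], c_x = ax["c"], e_x = ax["e"],
    a_y = ay["a"], c_y = ay["c"], e_y = ay["e"],
    b_xy = if (use_b_xy) b_xy0 else 0,
    b_yx = if (use_b_yx) b_yx0 else 0,
    nu_x_xy = nus$nu_x_xy, nu_y_xy = nus$nu_y_xy,
    nu_x_yx = nus$nu_x_yx, nu_y_yx = nus$nu_y_yx)
  list(params = params, weights = weights)
}

# Central-difference gradient of f at u.
num_gradient <- function(f, u, h = 1e-5) {
  vapply(seq_along(u), function(i) {
    hi <- h * (1 + abs(u[i]))
    up <- u; up[i] <- up[i] + hi
    dn <- u; dn[i] <- dn[i] - hi
    (f(up) - f(dn)) / (2 * hi)
  }, numeric(1))
}

#' Fit a twin model family by maximum likelihood
#'
#' Minimizes `-2LL` with a quasi-Newton optimizer (PORT routines via
#' [stats::nlminb()]) on the unconstrained parameter scale, over `n_starts`
#' starting points: the first is a method-of-moments initial value (sample
#' ACE splits, cross-trait regressions, and a provisional 2-means clustering
#' of the pair averages for mixture class means), the rest are random
#' perturbations of it.  The best local optimum wins; ties go to the lowest
#' start index, so results are deterministic given `(data, seed)`.
#'
#' Convergence is declared when the optimizer reports relative-tolerance
#' convergence and the central-difference gradient norm at the optimum is
#' below `1e-5 * (1 + |minus2ll|)` on the transformed scale.
#'
#' @param data a [twin_data()] dataset.
#' @param spec a [model_spec()].
#' @param n_starts number of starting points (>= 1).
#' @param seed integer seed controlling start perturbations (the caller's RNG
#'   state is preserved).
#' @param init optional list `(params, weights)` overriding the
#'   method-of-moments initial values.
#' @return A `mixdoc_fit` object: estimates (`params`, `weights`), `minus2ll`,
#'   `k` (free parameters), `df`, `aic`, `converged`, `grad_norm`,
#'   `n_starts_used`, `best_start` and per-start statuses.
#' @export
fit_model <- function(data, spec, n_starts = 10, seed = 1, init = NULL) {
  stopifnot(inherits(data, "twin_data"), inherits(spec, "model_spec"))
  if (nrow(data) == 0L) stop("cannot fit a model to an empty dataset")
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (is.null(init)) init <- init_values(data, spec, seed = seed)
  u0 <- transform_parameters(spec, init$params, init$weights)
  values <- split_values(data)
  obj <- function(u) {
    p <- tryCatch(untransform_parameters(spec, u), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    val <- tryCatch({
      comps <- model_components(spec, p$params, p$weights, fast = TRUE)
      minus2ll_from_comps(values, comps)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  n_par <- length(u0)
  perturb <- with_seed(seed, matrix(stats::rnorm((n_starts - 1) * n_par,
                                                 sd = 0.25), ncol = n_par))
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    us <- if (s == 1L) u0 else u0 + perturb[s - 1L, ] * (1 + abs(u0))
    res <- tryCatch(
      stats::nlminb(us, obj,
                    control = list(rel.tol = 1e-10, iter.max = 500,
                                   eval.max = 4000)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = us))
    starts[[s]] <- res
  }
  vals <- vapply(starts, function(r) r$objective, numeric(1))
  best <- which.min(vals)  # first minimum wins on exact ties
  opt <- starts[[best]]
  if (!is.finite(opt$objective))
    stop("no start converged to a finite likelihood; statuses: ",
         paste(vapply(starts, function(r) r$message %||% "?", ""),
               collapse = "; "))
  est <- untransform_parameters(spec, opt$par)
  g <- num_gradient(obj, opt$par)
  k <- count_free_parameters(spec)
  m2ll <- opt$objective
  structure(list(
    spec = spec,
    params = est$params,
    weights = est$weights,
    minus2ll = m2ll,
    k = k,
    df = model_df(spec, n_datapoints(data)),
    aic = aic(m2ll, k),
    converged = opt$convergence == 0 &&
      sqrt(sum(g^2)) < 1e-5 * (1 + abs(m2ll)),
    grad_norm = sqrt(sum(g^2)),
    n_starts_used = n_starts,
    best_start = best,
    start_minus2ll = vals,
    n_pairs = nrow(data),
    seed = seed), class = "mixdoc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mixdoc_fit <- function(x, ...) {
  cat(sprintf("mixdoc fit: family %s\n", x$spec$family))
  cat(sprintf("  -2LL = %.4f  k = %d  df = %d  AIC = %.4f\n",
              x$minus2ll, x$k, x$df, x$aic))
  cat(sprintf("  converged: %s (best of %d starts: #%d, |grad| = %.2e)\n",
              x$converged, x$n_starts_used, x$best_start, x$grad_norm))
  if (!is.null(x$weights))
    cat(sprintf("  omega MZ: %s\n  omega DZ: %s\n",
                paste(sprintf("%.3f", x$weights$MZ), collapse = " "),
                paste(sprintf("%.3f", x$weights$DZ), collapse = " ")))
  invisible(x)
}

#' Fit all six model families to one dataset
#'
#' Fits, in order: the 4-class mixture, the 2-class (concordant-only)
#' mixture, the two unidirectional DoC models, the bidirectional DoC model,
#' and the Cholesky bivariate ACE model, and tabulates df, -2LL and AIC.
#' A family whose fit fails is kept as a flagged row; the set never aborts.
#'
#' @param data a [twin_data()] dataset.
#' @param n_starts starting points per family.
#' @param seed integer seed.
#' @param confound_ra_free logical; fit the extended (r_a free) variants of
#'   the mixture and DoC families.
#' @return A `mixdoc_model_set`: list with `table` (one row per family) and
#'   `fits` (the underlying `mixdoc_fit` objects, `NULL` where failed).
#' @export
fit_model_set <- function(data, n_starts = 4, seed = 1,
                          confound_ra_free = FALSE) {
  families <- c("mix4", "mix2", "doc_xy", "doc_yx", "doc_bidir", "cholesky")
  fits <- vector("list", length(families))
  names(fits) <- families
  rows <- vector("list", length(families))
  for (i in seq_along(families)) {
    fam <- families[i]
    spec <- model_spec(fam, confound_ra_free = confound_ra_free &&
                         fam != "cholesky")
    f <- tryCatch(fit_model(data, spec, n_starts = n_starts, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(model = fam, k = count_free_parameters(spec),
                              df = NA_integer_, minus2ll = NA_real_,
                              aic = NA_real_, converged = FALSE,
                              error = conditionMessage(f))
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(model = fam, k = f$k, df = f$df,
                              minus2ll = f$minus2ll, aic = f$aic,
                              converged = f$converged, error = NA_character_)
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits),
            class = "mixdoc_model_set")
}

#' @export
print.mixdoc_model_set <- function(x, ...) {
  cat("Model comparison (lowest AIC preferred)\n")
  tab <- x$table
  tab$minus2ll <- round(tab$minus2ll, 2)
  tab$aic <- round(tab$aic, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
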