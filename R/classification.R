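#' Posterior class-membership probabilities
#'
#' Bayes-rule posterior probability that each twin pair belongs to each
#' causal-direction class, given a fitted mixture model:
#' `p_ic = omega_c Phi_c(pair_i) / sum_k omega_k Phi_k(pair_i)`, evaluated in
#' log space.  Each pair's zygosity selects the class moments and prior
#' weights.
#'
#' @param data a [twin_data()] dataset.
#' @param fit a `mixdoc_fit` for a mixture family ([fit_model()]), or a list
#'   `(spec, params, weights)` with known (e.g. generating) parameter values.
#' @return A `posterior_matrix`: list with `p` (N x C matrix, rows aligned
#'   with `data`, rows summing to 1), `zygosity`, and `class_names`.
#' @export
posterior_probabilities <- function(data, fit) {
  stopifnot(inherits(data, "twin_data"))
  if (!is_mixture_family(fit$spec))
    stop("posterior probabilities require a mixture family (mix4 or mix2); ",
         "single-class fits have no latent classes")
  comps <- model_components(fit$spec, fit$params, fit$weights)
  C <- ncol(comps$MZ$mus)
  p <- matrix(NA_real_, nrow(data), C)
  for (z in c("MZ", "DZ")) {
    rows <- which(data$zygosity == z)
    if (!length(rows)) next
    values <- as.matrix(data[rows, c("x1", "y1", "x2", "y2")])
    ld <- class_log_densities(values, comps[[z]])
    lw <- sweep(ld, 2, log(pmax(comps[[z]]$omega, 1e-300)), `+`)
    p[rows, ] <- exp(lw - row_logsumexp(lw))
  }
  p <- p / rowSums(p)
  colnames(p) <- comps$MZ$labels
  structure(list(p = p, zygosity = data$zygosity,
                 class_names = comps$MZ$labels),
            class = "posterior_matrix")
}

as_posterior_matrix <- function(post) {
  if (inherits(post, "posterior_matrix")) return(post$p)
  p <- as.matrix(post)
  if (any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-8))
    stop("posterior rows must be probabilities summing to 1")
  p
}

#' Relative entropy index of a posterior classification
#'
#' `Ent = 1 - sum_i sum_c (-p_ic ln p_ic) / (N ln C)`, with `0 ln 0 = 0`.
#' Ranges from 0 (all posteriors uniform: classification is uninformative)
#' to 1 (all posteriors degenerate at one class: perfect classification).
#' By default all pairs are pooled across zygosity groups (the sampling unit
#' is the pair and classes align across groups); `by_zygosity = TRUE`
#' returns the index per group instead.
#'
#' @param post a `posterior_matrix` from [posterior_probabilities()] or a
#'   plain N x C matrix of posterior probabilities.
#' @param by_zygosity logical; split the index by zygosity group (requires a
#'   `posterior_matrix`).
#' @return The entropy index in `[0, 1]` (a named length-2 vector when
#'   `by_zygosity = TRUE`).
#' @export
relative_entropy <- function(post, by_zygosity = FALSE) {
  p <- as_posterior_matrix(post)
  if (nrow(p) == 0L) stop("cannot compute entropy of an empty classification")
  if (ncol(p) < 2L) stop("entropy requires at least two classes")
  ent_of <- function(pm) {
    h <- -pm * log(pm)
    h[pm <= 0] <- 0
    1 - sum(h) / (nrow(pm) * log(ncol(pm)))
  }
  if (!by_zygosity) return(ent_of(p))
  if (!inherits(post, "posterior_matrix"))
    stop("by_zygosity requires a posterior_matrix with zygosity labels")
  c(MZ = ent_of(p[post$zygosity == "MZ", , drop = FALSE]),
    DZ = ent_of(p[post$zygosity == "DZ", , drop = FALSE]))
}

#' Hard class assignment from posterior probabilities
#'
#' Assigns each pair to its maximum-posterior class; exact ties are broken
#' toward the lower class index and reported with a warning.
#'
#' @param post a `posterior_matrix` or plain probability matrix.
#' @return Integer vector of class indices (named by class where available).
#' @export
assign_classes <- function(post) {
  p <- as_posterior_matrix(post)
  lab <- max.col(p, ties.method = "first")
  n_tie <- sum(rowSums(p == p[cbind(seq_len(nrow(p)), lab)]) > 1L)
  if (n_tie > 0)
    warning(n_tie, " pair(s) had tied posteriors; ties broken toward the ",
            "lower class index")
  if (!is.null(colnames(p))) names(lab) <- colnames(p)[lab]
  lab
}

#' Write a posterior matrix to CSV
#'
#' One row per pair with the zygosity label and one column per class.
#'
#' @param post a `posterior_matrix`.
#' @param path output file path.
#' @export
write_posteriors <- function(post, path) {
  stopifnot(inherits(post, "posterior_matrix"))
  df <- data.frame(zygosity = post$zygosity, post$p, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
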