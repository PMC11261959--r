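# Shared fixture builders: a generic parameter set with all paths active,
# the study-default parameters, and small simulated datasets.

generic_params <- function(b_xy = 0.4, b_yx = 0.25, r_a = 0, r_c = 0,
                           r_e = 0) {
  doc_params(a_x = 0.8, c_x = 0.3, e_x = 0.52,
             a_y = 0.3, c_y = 0.75, e_y = 0.59,
             b_xy = b_xy, b_yx = b_yx,
             nu_x_xy = 0.4, nu_y_xy = 0.2, nu_x_yx = -0.3, nu_y_yx = -0.5,
             r_a = r_a, r_c = r_c, r_e = r_e)
}

equal_quarters <- function() mixture_weights(c(0.25, 0.25, 0.25, 0.25))

small_mixture_data <- function(n = 300, seed = 42, mean_diff = 1,
                               b = 0.5) {
  p <- study_params(mean_diff_x = mean_diff, mean_diff_y = mean_diff,
                    b_xy = b, b_yx = b)
  simulate_dataset(scenario_config(n, n, p, equal_quarters(),
                                   family = "mix4", method = "quota",
                                   seed = seed))
}

# Independent MVN log-density oracle: explicit determinant and quadratic
# form via solve(), no Cholesky (the implementation path).
mvn_logdens_oracle <- function(y, mu, sigma) {
  d <- length(y)
  -0.5 * (d * log(2 * pi) + log(det(sigma)) +
            drop(t(y - mu) %*% solve(sigma) %*% (y - mu)))
}

# All four class labels in canonical order.
all_labels <- function() mixture_classes()
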