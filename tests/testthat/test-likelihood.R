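test_that("pair log-density matches closed-form Gaussian values", {
  mu <- c(0.3, -0.2, 0.1, 0)
  m_id <- list(mu = mu, sigma = diag(4))
  expect_equal(pair_log_density(mu, m_id), -2 * log(2 * pi))

  # scaling sigma by 4 at the mean changes the density by -0.5 * log(4^4)
  m_sc <- list(mu = mu, sigma = 4 * diag(4))
  expect_equal(pair_log_density(mu, m_sc) - pair_log_density(mu, m_id),
               -0.5 * log(4^4))

  set.seed(9)
  L <- matrix(rnorm(16), 4, 4)
  sigma <- crossprod(L) + diag(4)
  y <- rnorm(4)
  m <- list(mu = mu, sigma = sigma)
  expect_equal(pair_log_density(y, m), mvn_logdens_oracle(y, mu, sigma),
               tolerance = 1e-12)

  expect_error(pair_log_density(c(1, 2, NA, 4), m_id), "finite")
})

test_that("single-class -2LL is the sum of pair log-densities", {
  p <- generic_params(b_xy = 0.5, b_yx = 0)
  d <- simulate_dataset(scenario_config(40, 40, p, family = "doc_xy",
                                        seed = 3))
  spec <- model_spec("doc_xy")
  m_mz <- expected_pair_moments(p, class_label("xy", "xy"), "MZ")
  m_dz <- expected_pair_moments(p, class_label("xy", "xy"), "DZ")
  manual <- 0
  for (i in seq_len(nrow(d))) {
    m <- if (d$zygosity[i] == "MZ") m_mz else m_dz
    manual <- manual + pair_log_density(as.numeric(d[i, c("x1", "y1", "x2",
                                                          "y2")]), m)
  }
  expect_equal(minus2_loglik(d, spec, p), -2 * manual, tolerance = 1e-10)
})

test_that("a mixture of identical components collapses to one class", {
  p <- generic_params(b_xy = 0, b_yx = 0)
  # same intercepts in both directions, no causal paths: all classes share theta
  p$nu_x_xy <- p$nu_x_yx <- 0.2
  p$nu_y_xy <- p$nu_y_yx <- -0.1
  d <- simulate_dataset(scenario_config(30, 30, p, equal_quarters(),
                                        family = "mix4", seed = 4))
  for (w in list(equal_quarters(), mixture_weights(c(0.6, 0.2, 0.1, 0.1)))) {
    expect_equal(minus2_loglik(d, model_spec("mix4"), p, w),
                 minus2_loglik(d, model_spec("doc_xy"), p),
                 tolerance = 1e-9)
  }
})

test_that("two-class toy -2LL matches a hand-computed weighted density sum", {
  p <- generic_params(b_xy = 0.5, b_yx = 0.4)
  d <- twin_data(data.frame(zygosity = c("MZ", "DZ"),
                            x1 = c(0.5, -1), y1 = c(1, 0),
                            x2 = c(-0.2, 0.8), y2 = c(0.1, -0.6)))
  w <- mixture_weights(c(0.5, 0.5, 0, 0))
  manual <- 0
  for (i in 1:2) {
    z <- d$zygosity[i]
    y4 <- as.numeric(d[i, c("x1", "y1", "x2", "y2")])
    m1 <- expected_pair_moments(p, class_label("xy", "xy"), z)
    m2 <- expected_pair_moments(p, class_label("yx", "yx"), z)
    dens <- 0.5 * exp(mvn_logdens_oracle(y4, m1$mu, m1$sigma)) +
      0.5 * exp(mvn_logdens_oracle(y4, m2$mu, m2$sigma))
    manual <- manual + log(dens)
  }
  expect_equal(minus2_loglik(d, model_spec("mix2"), p, w), -2 * manual,
               tolerance = 1e-9)
})

test_that("log-sum-exp stabilization agrees with naive mixture summation", {
  p <- study_params()
  w <- equal_quarters()
  d <- small_mixture_data(n = 25, seed = 8)
  comps <- mixdoc:::model_components(model_spec("mix4"), p, w)
  naive <- 0
  for (i in seq_len(nrow(d))) {
    z <- d$zygosity[i]
    y4 <- as.numeric(d[i, c("x1", "y1", "x2", "y2")])
    cm <- comps[[z]]
    dens <- sum(vapply(1:4, function(c)
      cm$omega[c] * exp(mvn_logdens_oracle(y4, cm$mus[, c],
                                           cm$sigmas[, , c])),
      numeric(1)))
    naive <- naive + log(dens)
  }
  expect_equal(minus2_loglik(d, model_spec("mix4"), p, w), -2 * naive,
               tolerance = 1e-10)
})

test_that("-2LL is invariant to row order and to twin swap when discordant weights are equal", {
  p <- generic_params()
  w <- mixture_weights(c(0.4, 0.2, 0.2, 0.2))
  d <- small_mixture_data(n = 60, seed = 10)
  spec <- model_spec("mix4")
  base <- minus2_loglik(d, spec, p, w)

  shuffled <- twin_data(d[sample(nrow(d)), ])
  expect_equal(minus2_loglik(shuffled, spec, p, w), base, tolerance = 1e-9)

  swapped <- twin_data(data.frame(zygosity = d$zygosity,
                                  x1 = d$x2, y1 = d$y2,
                                  x2 = d$x1, y2 = d$y1))
  expect_equal(minus2_loglik(swapped, spec, p, w), base, tolerance = 1e-9)
})

test_that("adding a pair strictly increases -2LL", {
  p <- generic_params()
  w <- equal_quarters()
  d <- small_mixture_data(n = 20, seed = 12)
  d_more <- twin_data(rbind(as.data.frame(d),
                            data.frame(zygosity = "MZ", x1 = 0.1, y1 = 0.2,
                                       x2 = -0.1, y2 = 0)))
  expect_gt(minus2_loglik(d_more, model_spec("mix4"), p, w),
            minus2_loglik(d, model_spec("mix4"), p, w))
})

test_that("marginal likelihood integrates out missing entries per pair", {
  p <- generic_params(b_xy = 0.5, b_yx = 0.3)
  w <- mixture_weights(c(0.3, 0.3, 0.2, 0.2))
  d <- small_mixture_data(n = 6, seed = 16)
  df <- as.data.frame(d)
  df$y2[1] <- NA
  df$x1[2] <- NA; df$y1[2] <- NA
  dm <- twin_data(df, allow_missing = TRUE)
  expect_error(minus2_loglik(dm, model_spec("mix4"), p, w), "missing")

  comps <- mixdoc:::model_components(model_spec("mix4"), p, w)
  manual <- 0
  for (i in seq_len(nrow(df))) {
    y4 <- as.numeric(df[i, c("x1", "y1", "x2", "y2")])
    obs <- which(!is.na(y4))
    cm <- comps[[df$zygosity[i]]]
    dens <- sum(vapply(1:4, function(c)
      cm$omega[c] * exp(mvn_logdens_oracle(y4[obs], cm$mus[obs, c],
                                           cm$sigmas[obs, obs, c])),
      numeric(1)))
    manual <- manual + log(dens)
  }
  expect_equal(minus2_loglik(dm, model_spec("mix4"), p, w,
                             missing = "marginal"),
               -2 * manual, tolerance = 1e-10)
  # df accounting counts only observed values (n pairs per zygosity)
  expect_identical(mixdoc:::n_datapoints(dm), 4L * nrow(dm) - 3L)
})

test_that("AIC adds twice the parameter count to -2LL", {
  expect_equal(aic(144293.4, 16), 144325.4)
  expect_equal(aic(45933.44, 10), 45953.44)
  expect_equal(aic(123.45, 0), 123.45)
})
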