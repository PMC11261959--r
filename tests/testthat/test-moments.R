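test_that("causal matrix places one path per twin block", {
  B <- causal_matrix(class_label("xy", "xy"), b_xy = 0.5, b_yx = 0.3)
  expected <- matrix(0, 4, 4)
  expected[2, 1] <- 0.5
  expected[4, 3] <- 0.5
  expect_identical(B, expected)

  expect_identical(causal_matrix(class_label("xy", "xy"), 0, 0),
                   matrix(0, 4, 4))

  B_dis <- causal_matrix(class_label("xy", "yx"), b_xy = 0.5, b_yx = 0.3)
  expected_dis <- matrix(0, 4, 4)
  expected_dis[2, 1] <- 0.5
  expected_dis[3, 4] <- 0.3
  expect_identical(B_dis, expected_dis)
})

test_that("bidirectional paths with unit product are rejected as singular", {
  expect_error(causal_matrix(class_label("both", "both"), 2, 0.5),
               "singular")
  expect_silent(causal_matrix(class_label("both", "both"), 0.5, 0.5))
})

test_that("no connecting path means zero cross-trait covariance", {
  p <- generic_params(b_xy = 0, b_yx = 0)
  m <- expected_pair_moments(p, class_label("xy", "xy"), "MZ")
  cross_trait <- c(m$sigma[1, 2], m$sigma[1, 4], m$sigma[3, 2], m$sigma[3, 4])
  expect_equal(cross_trait, rep(0, 4))
  expect_equal(m$sigma[1, 3], p$a_x^2 + p$c_x^2)
  expect_equal(m$sigma[2, 4], p$a_y^2 + p$c_y^2)
})

test_that("cross-twin cross-trait covariance carries the causal signature", {
  # concordant X->Y without confounding: cov(x1, y2) = b_xy * cov(x1, x2)
  p <- generic_params(b_xy = 0.5, b_yx = 0)
  for (z in c("MZ", "DZ")) {
    m <- expected_pair_moments(p, class_label("xy", "xy"), z)
    expect_equal(m$sigma[1, 4], p$b_xy * m$sigma[1, 3], tolerance = 1e-12)
  }
})

test_that("expected moments match a large-n structural simulation", {
  p <- generic_params(b_xy = 0.5, b_yx = 0, r_a = 0.3, r_c = -0.2, r_e = 0.1)
  cfg <- scenario_config(200000, 0, p, family = "doc_xy", seed = 7)
  d <- structural_simulate(cfg)
  vals <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
  m <- expected_pair_moments(p, class_label("xy", "xy"), "MZ")
  expect_equal(unname(colMeans(vals)), m$mu, tolerance = 0.01)
  expect_equal(unname(cov(vals)), m$sigma, tolerance = 0.015)
})

test_that("pair covariance is symmetric positive definite across classes", {
  set.seed(101)
  for (i in 1:20) {
    p <- doc_params(a_x = runif(1, 0.1, 1), c_x = runif(1, 0, 1),
                    e_x = runif(1, 0.3, 1),
                    a_y = runif(1, 0.1, 1), c_y = runif(1, 0, 1),
                    e_y = runif(1, 0.3, 1),
                    b_xy = runif(1, -0.8, 0.8), b_yx = runif(1, -0.8, 0.8),
                    r_a = runif(1, -0.7, 0.7), r_c = runif(1, -0.7, 0.7),
                    r_e = runif(1, -0.7, 0.7))
    for (lab in all_labels()) {
      for (z in c("MZ", "DZ")) {
        m <- expected_pair_moments(p, lab, z)
        expect_equal(m$sigma, t(m$sigma))
        ev <- eigen(m$sigma, symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), 0)
      }
    }
  }
})

test_that("MZ and DZ moments coincide when additive-genetic paths vanish", {
  p <- generic_params()
  p$a_x <- 0; p$a_y <- 0; p$r_a <- 0
  for (lab in all_labels()) {
    mz <- expected_pair_moments(p, lab, "MZ")
    dz <- expected_pair_moments(p, lab, "DZ")
    expect_equal(mz$sigma, dz$sigma)
    expect_equal(mz$mu, dz$mu)
  }
})

test_that("twin-order swap maps one discordant class onto the other", {
  p <- generic_params(r_a = 0.2, r_c = 0.1, r_e = -0.1)
  perm <- c(3, 4, 1, 2)
  for (z in c("MZ", "DZ")) {
    m34 <- expected_pair_moments(p, class_label("xy", "yx"), z)
    m43 <- expected_pair_moments(p, class_label("yx", "xy"), z)
    expect_equal(m34$sigma[perm, perm], m43$sigma)
    expect_equal(m34$mu[perm], m43$mu)
  }
})

test_that("cholesky moments reduce to independent univariate ACE models", {
  cp <- chol_ace_params(L_a = diag(c(0.8, 0.4)), L_c = diag(c(0.3, 0.6)),
                        L_e = diag(c(0.5, 0.7)), mean = c(1, -1))
  m <- cholesky_ace_moments(cp, "DZ")
  expect_equal(m$sigma[1, 2], 0)   # no cross-trait paths
  expect_equal(m$sigma[1, 4], 0)
  expect_equal(m$sigma[1, 1], 0.8^2 + 0.3^2 + 0.5^2)
  expect_equal(m$sigma[1, 3], 0.5 * 0.8^2 + 0.3^2)
  expect_equal(m$mu, c(1, -1, 1, -1))
})

test_that("without familial variance MZ and DZ cholesky moments agree", {
  cp <- chol_ace_params(L_a = matrix(0, 2, 2), L_c = matrix(0, 2, 2),
                        L_e = matrix(c(1, 0.4, 0, 0.9), 2, 2))
  expect_equal(cholesky_ace_moments(cp, "MZ"), cholesky_ace_moments(cp, "DZ"))
})

test_that("generic cholesky moments match structural simulation of factors", {
  cp <- chol_ace_params(L_a = matrix(c(0.7, 0.3, 0, 0.5), 2, 2),
                        L_c = matrix(c(0.4, -0.2, 0, 0.6), 2, 2),
                        L_e = matrix(c(0.5, 0.2, 0, 0.6), 2, 2),
                        mean = c(0.3, -0.2))
  # independent oracle: draw shared/unique factor scores directly
  set.seed(33)
  n <- 200000
  for (z in c("MZ", "DZ")) {
    alpha <- if (z == "MZ") 1 else 0.5
    shared_a <- matrix(rnorm(2 * n), n, 2)
    uniq_a1 <- matrix(rnorm(2 * n), n, 2)
    uniq_a2 <- matrix(rnorm(2 * n), n, 2)
    A1 <- sqrt(alpha) * shared_a + sqrt(1 - alpha) * uniq_a1
    A2 <- sqrt(alpha) * shared_a + sqrt(1 - alpha) * uniq_a2
    Cc <- matrix(rnorm(2 * n), n, 2)
    E1 <- matrix(rnorm(2 * n), n, 2)
    E2 <- matrix(rnorm(2 * n), n, 2)
    t1 <- A1 %*% t(cp$L_a) + Cc %*% t(cp$L_c) + E1 %*% t(cp$L_e)
    t2 <- A2 %*% t(cp$L_a) + Cc %*% t(cp$L_c) + E2 %*% t(cp$L_e)
    emp <- cov(cbind(t1, t2))
    m <- cholesky_ace_moments(cp, z)
    expect_equal(unname(emp), m$sigma, tolerance = 0.02)
  }
})

test_that("unidirectional DoC covariance is reproduced within the cholesky family", {
  set.seed(55)
  for (i in 1:5) {
    p <- doc_params(a_x = runif(1, 0.3, 0.9), c_x = runif(1, 0.1, 0.6),
                    e_x = runif(1, 0.3, 0.8),
                    a_y = runif(1, 0.3, 0.9), c_y = runif(1, 0.1, 0.6),
                    e_y = runif(1, 0.3, 0.8),
                    b_xy = runif(1, -0.8, 0.8))
    G2 <- matrix(c(1, p$b_xy, 0, 1), 2, 2)  # within-twin reduced form
    cp <- chol_ace_params(L_a = G2 %*% diag(c(p$a_x, p$a_y)),
                          L_c = G2 %*% diag(c(p$c_x, p$c_y)),
                          L_e = G2 %*% diag(c(p$e_x, p$e_y)))
    for (z in c("MZ", "DZ")) {
      doc_sigma <- expected_pair_moments(p, class_label("xy", "xy"), z)$sigma
      chol_sigma <- cholesky_ace_moments(cp, z)$sigma
      expect_lt(max(abs(doc_sigma - chol_sigma)), 1e-8)
    }
  }
})

test_that("free-parameter counts and degrees of freedom follow FIML accounting", {
  counts <- c(mix4 = 16L, mix2 = 14L, doc_xy = 9L, doc_yx = 9L,
              doc_bidir = 10L, cholesky = 11L)
  for (fam in names(counts)) {
    expect_identical(count_free_parameters(model_spec(fam)), counts[[fam]])
  }
  expect_identical(count_free_parameters(model_spec("mix4",
                                                    confound_ra_free = TRUE)),
                   17L)
  expect_identical(
    count_free_parameters(model_spec("mix4", proportions_by_zygosity = FALSE)),
    14L)
  expect_identical(model_df(model_spec("mix4"), 120000), 119984L)
  expect_error(model_df(model_spec("mix2"), 0), "over-parameterized")
  expect_error(count_free_parameters(
    structure(list(family = "huh", confound_ra_free = FALSE,
                   proportions_by_zygosity = TRUE), class = "model_spec")),
    "unknown model family")
})

test_that("parameter validation enforces sign and range conventions", {
  expect_error(doc_params(a_x = -0.1, c_x = 0, e_x = 1, a_y = 1, c_y = 0,
                          e_y = 1), "non-negative")
  expect_error(doc_params(a_x = 1, c_x = 0, e_x = 0, a_y = 1, c_y = 0,
                          e_y = 1), "strictly positive")
  expect_error(doc_params(a_x = 1, c_x = 0, e_x = 1, a_y = 1, c_y = 0,
                          e_y = 1, r_a = 1.2), "\\[-1, 1\\]")
})
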