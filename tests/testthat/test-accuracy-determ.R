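test_that("single-reference accuracy: closed forms and genetic-correlation scaling", {
  # r_G = 0 kills the accuracy regardless of relationships
  expect_equal(si_accuracy_single(c(.3, .2), diag(2), r_G = 0,
                                  sigma2_e = 0.1), 0)
  # single reference, g = 1, G = [1], no noise: accuracy = r_G
  expect_equal(si_accuracy_single(1, matrix(1), r_G = 0.7), 0.7)
  # exact linearity in r_G
  set.seed(6)
  g <- runif(10, 0, 0.5)
  G <- crossprod(matrix(rnorm(100), 10)) / 10 + diag(10) * 0.2
  a1 <- si_accuracy_single(g, G, r_G = 1, sigma2_e = 0.05)
  a6 <- si_accuracy_single(g, G, r_G = 0.6, sigma2_e = 0.05)
  expect_identical(a6, 0.6 * a1)
})

test_that("selection-index formula agrees with the b = V^-1 Cov oracle", {
  set.seed(14)
  for (rep in 1:5) {
    nb <- sample(3:8, 1)
    g <- runif(nb, -0.1, 0.5)
    Gb <- crossprod(matrix(rnorm(nb * nb), nb)) / nb + diag(nb) * 0.3
    s2a <- runif(1, 0.3, 2); s2e <- runif(1, 0.1, 1.5)
    rg <- runif(1, 0.1, 1); s2aA <- runif(1, 0.5, 2)
    # oracle: partial regression coefficients on phenotypes, general
    # accuracy formula with covariance between prediction and target
    V <- Gb * s2a + diag(nb) * s2e
    Cov <- rg * sqrt(s2aA * s2a) * g
    b <- solve(V, Cov)
    cov_ahat_a <- sum(b * Cov)
    var_ahat <- drop(t(b) %*% V %*% b)
    r_oracle <- cov_ahat_a / sqrt(s2aA * var_ahat)
    expect_equal(si_accuracy_single(g, Gb, rg, s2a, s2e), r_oracle,
                 tolerance = 1e-10)
    # prediction-target covariance equals prediction variance
    expect_equal(cov_ahat_a, var_ahat, tolerance = 1e-10)
  }
})

test_that("two-reference-population formula reduces and extends correctly", {
  set.seed(21)
  nb <- 5; nc <- 4
  gB <- runif(nb, 0, .4); gC <- runif(nc, 0, .4)
  GB <- crossprod(matrix(rnorm(nb^2), nb)) / nb + diag(nb) * .3
  GC <- crossprod(matrix(rnorm(nc^2), nc)) / nc + diag(nc) * .3
  GBC <- matrix(rnorm(nb * nc, 0, 0.05), nb, nc)
  # decoupled blocks reduce to the single-population formula
  a_dec <- si_accuracy_multi(gB, gC, GB, GC, GBC * 0, r_G_AB = 0.8,
                             r_G_AC = 0, r_G_BC = 1,
                             sigma2_e_B = 0.1, sigma2_e_C = 0.1)
  a_single <- si_accuracy_single(gB, GB, 0.8, sigma2_e = 0.1)
  expect_equal(a_dec, a_single, tolerance = 1e-12)
  # brute-force two-population selection index oracle
  s2aB <- 0.9; s2eB <- 0.4; s2aC <- 1.2; s2eC <- 0.6
  rAB <- 0.7; rAC <- 0.5; rBC <- 0.6
  V <- rbind(cbind(GB * s2aB + diag(nb) * s2eB,
                   rBC * sqrt(s2aB * s2aC) * GBC),
             cbind(rBC * sqrt(s2aB * s2aC) * t(GBC),
                   GC * s2aC + diag(nc) * s2eC))
  Cov <- c(rAB * sqrt(s2aB) * gB, rAC * sqrt(s2aC) * gC)
  b <- solve(V, Cov)
  r_oracle <- sum(b * Cov) / sqrt(drop(t(b) %*% V %*% b))
  got <- si_accuracy_multi(gB, gC, GB, GC, GBC, rAB, rAC, rBC,
                           s2aB, s2eB, s2aC, s2eC)
  expect_equal(got, r_oracle, tolerance = 1e-10)
  # a consistent second population never decreases the accuracy
  a_with <- si_accuracy_multi(gB, gC, GB, GC, GBC * 0, r_G_AB = 0.8,
                              r_G_AC = 0.6, r_G_BC = 0,
                              sigma2_e_B = 0.1, sigma2_e_C = 0.1)
  expect_gte(a_with, a_single - 1e-12)
})

test_that("within-population reduction matches a prediction-error-variance oracle", {
  # candidates from the reference population itself: the relationship-based
  # accuracy equals the PEV-based accuracy from the mixed-model equations
  set.seed(33)
  n <- 12
  W <- matrix(rnorm(n * 60), n)
  G <- tcrossprod(scale(W)) / 60 + diag(n) * 0.05
  s2a <- 1; s2e <- 0.25
  loo <- si_accuracy_loo(G, 1, s2a, s2e)
  for (i in c(1, 5, n)) {
    ref <- setdiff(1:n, i)
    # oracle: joint mixed-model equations over all n animals with the
    # candidate unphenotyped; PEV read off the inverse coefficient matrix
    Z <- diag(n)[ref, ]
    C <- solve(crossprod(Z) / s2e + solve(G) / s2a)
    rel_vr <- 1 - C[i, i] / (G[i, i] * s2a)
    # the relationship-based formula states accuracy on the Var(a)=1 scale;
    # VanRaden's reliability is on the Var(a_i)=G_ii scale
    expect_equal(unname(loo[i]) / sqrt(G[i, i]), sqrt(rel_vr),
                 tolerance = 1e-9)
  }
})

test_that("population-parameter accuracy: substitution, limits, monotonicity", {
  expect_equal(pp_accuracy(1000, 0.3, 300), sqrt(300 / 600))
  expect_equal(pp_accuracy(1000, 0.3, 300), 0.70711, tolerance = 1e-5)
  # N h2 = Me: r = r_G / sqrt(2)
  expect_equal(pp_accuracy(100, 0.5, 50, r_G = 0.8), 0.8 / sqrt(2))
  expect_lt(pp_accuracy(100, 0.5, 1e9), 1e-3)
  expect_equal(pp_accuracy(1e9, 0.5, 100, r_G = 0.9), 0.9, tolerance = 1e-3)
  expect_error(pp_accuracy(100, 0.5, -1), "positive")
  set.seed(8)
  for (i in 1:20) {
    N <- runif(1, 10, 5000); h2 <- runif(1, .05, 1); Me <- runif(1, 10, 5e4)
    expect_gt(pp_accuracy(N * 1.5, h2, Me), pp_accuracy(N, h2, Me))
    expect_gt(pp_accuracy(N, min(1, h2 * 1.2), Me), pp_accuracy(N, h2, Me))
    expect_lt(pp_accuracy(N, h2, Me * 2), pp_accuracy(N, h2, Me))
  }
})

test_that("progeny-based reliability formula", {
  drp <- drp_reliability(285, 0.25)
  expect_equal(drp$reliability, 71.25 / 75, tolerance = 1e-12)
  expect_equal(drp$reliability, 0.95)
  expect_equal(drp_reliability(1, 1)$accuracy, 0.5)
  expect_equal(drp_reliability(1e9, 0.25)$accuracy, 1, tolerance = 1e-4)
})

test_that("phenotypic covariance assembly matches elementwise construction", {
  G <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(build_phenotypic_covariance(list(B = G), 2, 0), G * 2)
  expect_equal(build_phenotypic_covariance(list(B = diag(2)), 0.5, 0.5),
               diag(2))
  GC <- matrix(c(1.1, .2, .2, .9), 2)
  GBC <- matrix(c(.05, -.02, .01, .03), 2)
  V <- build_phenotypic_covariance(list(B = G, C = GC, BC = GBC),
                                   sigma2_a = c(1.2, 0.8),
                                   sigma2_e = c(0.3, 0.4), r_G_BC = 0.6)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(V[i, j], G[i, j] * 1.2 + (i == j) * 0.3)
    expect_equal(V[i, 2 + j], 0.6 * sqrt(1.2 * 0.8) * GBC[i, j])
    expect_equal(V[2 + i, 2 + j], GC[i, j] * 0.8 + (i == j) * 0.4)
  }
  expect_true(isSymmetric(V))
})

test_that("non-positive-definite systems are reported, not silently accepted", {
  G <- matrix(c(1, 2, 2, 1), 2)   # indefinite
  expect_error(si_accuracy_single(c(.1, .1), G, sigma2_e = 0),
               "positive definite")
})
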