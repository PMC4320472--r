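test_that("the profiled REML objective matches a dense oracle and beats a grid", {
  set.seed(51)
  n <- 24
  W <- matrix(rnorm(n * 80), n)
  G <- tcrossprod(scale(W)) / 80 + diag(n) * 0.05
  dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
  a <- drop(chol(G) %*% rnorm(n)) * sqrt(0.8)
  y <- 2 + a + rnorm(n, 0, sqrt(0.4))
  ph <- tibble::tibble(id = rownames(G), population = "p", y = y)
  fit <- reml_single(ph, G)
  expect_true(fit$converged)
  X <- matrix(1, n, 1)
  # dense restricted likelihood at the optimum agrees with the fit value
  V_opt <- fit$sigma2_a * G + diag(fit$sigma2_e, n)
  expect_equal(fit$loglik, reml_loglik_oracle(y, X, V_opt),
               tolerance = 1e-6)
  # and dominates a 50 x 50 grid evaluated with the oracle
  grid <- expand.grid(s2a = seq(0.05, 3, length.out = 50),
                      s2e = seq(0.05, 3, length.out = 50))
  ll <- mapply(function(s2a, s2e)
    reml_loglik_oracle(y, X, s2a * G + diag(s2e, n)),
    grid$s2a, grid$s2e)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("an identity relationship matrix is rejected as non-identifiable", {
  n <- 10
  G <- diag(n); dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
  ph <- tibble::tibble(id = rownames(G), population = "p", y = rnorm(n))
  expect_error(reml_single(ph, G), "identifiable")
})

test_that("variance components are recovered on a structured panel", {
  mats <- shared_matrices()
  G <- mats$G_pool
  Gm <- unclass(G); dimnames(Gm) <- dimnames(G)
  ids <- rownames(Gm)
  pops <- attr(G, "population")
  n <- length(ids)
  ch <- chol(Gm + diag(1e-6, n))
  s2a_true <- 1; s2e_true <- 1 / 0.95 - 1
  ests <- t(sapply(1:12, function(r) {
    set.seed(600 + r)
    a <- drop(crossprod(ch, rnorm(n))) * sqrt(s2a_true)
    y <- a + rnorm(n, 0, sqrt(s2e_true))
    ph <- tibble::tibble(id = ids, population = unname(pops), y = y)
    fit <- reml_single(ph, G)
    c(fit$sigma2_a, fit$sigma2_e)
  }))
  for (k in 1:2) {
    truth <- c(s2a_true, s2e_true)[k]
    se <- sd(ests[, k]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, k]) - truth), 2 * se + 0.02 * truth)
  }
})

test_that("GBLUP prediction matches the explicit matrix formula and shrinks", {
  set.seed(61)
  n <- 6
  W <- matrix(rnorm(n * 40), n)
  G <- tcrossprod(scale(W)) / 40 + diag(n) * 0.1
  dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
  ref <- paste0("i", 1:4); cand <- paste0("i", 5:6)
  y <- rnorm(4)
  ph <- tibble::tibble(id = ref, population = "p", y = y)
  fit <- reml_single(ph, G)
  ebv <- blup_predict(fit, G, cand)
  V <- fit$sigma2_a * G[ref, ref] + diag(fit$sigma2_e, 4)
  expect_equal(unname(ebv),
               unname(drop(fit$sigma2_a * G[cand, ref] %*%
                             solve(V, y - fit$beta[1]))),
               tolerance = 1e-8)
  # unrelated candidate: zero EBV
  G2 <- G; G2[cand[1], ref] <- 0; G2[ref, cand[1]] <- 0
  expect_equal(unname(blup_predict(fit, G2, cand[1])), 0)
  # candidates overlapping the reference are refused
  expect_error(blup_predict(fit, G, c("i1")), "overlap")
  # shrinkage: larger residual/genetic ratio never inflates EBV spread
  f1 <- fit; f1$sigma2_a <- 1; f1$sigma2_e <- 0.1
  f2 <- fit; f2$sigma2_a <- 1; f2$sigma2_e <- 5
  p1 <- xpopacc:::.refresh_projection(f1, G, ph, ref)
  p2 <- xpopacc:::.refresh_projection(f2, G, ph, ref)
  expect_lte(var(blup_predict(p2, G, cand)), var(blup_predict(p1, G, cand)))
})

test_that("empirical accuracy is a within-population correlation with guards", {
  ebv <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 3, b2 = 1, b3 = 2)
  pops <- c(rep("a", 3), rep("b", 3))
  acc <- empirical_accuracy(ebv, ebv, pops)
  expect_equal(acc$accuracy, c(1, 1))
  expect_error(empirical_accuracy(ebv * 0, ebv, pops), "constant")
  expect_error(empirical_accuracy(ebv[1:4], ebv[1:4], pops[1:4]),
               "fewer than 3")
  # invariant to a constant shift within a population (fixed-effect logic)
  tbv <- c(a1 = .1, a2 = -.4, a3 = .2, b1 = .5, b2 = 0, b3 = -.1)
  shifted <- ebv + rep(c(10, -3), each = 3)
  expect_equal(empirical_accuracy(shifted, tbv, pops)$accuracy,
               empirical_accuracy(ebv, tbv, pops)$accuracy)
})

test_that("empirical across-population accuracy agrees with the selection-index prediction", {
  sim <- shared_sim(); qc <- shared_qc(); part <- shared_partition()
  spec <- scenario_spec("agree", "pop1", "pop2", r_G = 1, n_qtl = 300,
                        n_replicates = 10, base_seed = 99)
  rep <- run_scenario(spec, qc$panel, sim$pedigree, part)
  s <- summarize_replicates(rep)
  emp <- s[s$method == "empirical", ]
  si <- s[s$method == "selection_index", ]
  comb_se <- sqrt(emp$se^2 + si$se^2)
  expect_lt(abs(emp$mean - si$mean), 2 * comb_se + 0.05)
})

test_that("the bivariate model recovers the simulated genetic correlation", {
  sim <- shared_sim(); qc <- shared_qc(); part <- shared_partition()
  panel <- qc$panel
  pops <- unique(panel$population)
  # pooled-frequency G regressed towards A; the within-block inbreeding
  # rescaling is omitted here because it rescales within- but not
  # cross-population blocks and so distorts the correlation scale when
  # pedigree inbreeding is substantial
  G <- shared_matrices()$G_pool_reg
  h2 <- 0.95
  recover <- function(r_true, n_rep = 8) {
    sapply(seq_len(n_rep), function(r) {
      eff <- sample_qtl_effects(300, r_true, seed = 3000 + r, n_pop = 2)
      rownames(eff) <- pops
      set.seed(4000 + r)
      qtl <- sample(part$candidate_qtl_indices, 300)
      tbv <- compute_tbv(panel, qtl, eff, populations = pops)
      ph <- simulate_phenotypes(tbv, panel$population, h2, seed = 5000 + r)
      fit <- reml_genetic_correlation(
        ph, G, pop_free = "pop1", pop_fixed = "pop2",
        fixed_components = list(
          sigma2_a = var(tbv[panel$population == "pop2"]),
          sigma2_e = attr(ph, "sigma2_e")))
      fit$r_G
    })
  }
  for (r_true in c(0.2, 0.6, 1.0)) {
    est <- recover(r_true)
    expect_true(all(abs(est) <= 1))
    mc_se <- sd(est) / sqrt(length(est))
    if (r_true == 1) {
      # mild downward bias is expected against the boundary
      expect_gte(mean(est) + 2 * mc_se, 0.85)
    } else {
      expect_lt(abs(mean(est) - r_true), 0.1 + 2 * mc_se)
    }
  }
})
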