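test_that("allele frequencies: per population and equal-weight pooled", {
  pan <- toy_panel(rbind(c(0, 2), c(2, 2), c(0, 1), c(2, 1)),
                   c("a", "a", "b", "b"))
  af <- allele_frequencies(pan)
  expect_equal(unname(af$per_population["a", ]), c(0.5, 1))
  expect_equal(unname(af$per_population["b", ]), c(0.5, 0.5))
  expect_equal(unname(af$pooled), c(0.5, 0.75))  # unweighted mean
})

test_that("GRM standardization: closed form, oracle, and centering identity", {
  # one locus at p = 0.5, dosages 0 and 2: x = -sqrt(2), +sqrt(2)
  pan <- toy_panel(cbind(c(0, 2)), c("a", "a"))
  af <- allele_frequencies(pan)
  af$per_population[] <- 0.5
  af$pooled[] <- 0.5
  G <- build_grm(pan, freqs = af, scheme = "own_population")
  expect_equal(unclass(G)[1:2, 1:2], matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)

  # 5 individuals x 10 loci against elementwise brute force
  set.seed(12)
  dos <- matrix(sample(0:2, 50, TRUE), 5)
  pan2 <- toy_panel(dos, c("a", "a", "a", "b", "b"))
  G2 <- build_grm(pan2, scheme = "pooled_equal_weight")
  af2 <- allele_frequencies(pan2)
  p <- af2$pooled
  usable <- p > 0 & p < 1
  X <- sapply(which(usable), function(k)
    (dos[, k] - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k])))
  for (i in 1:5) for (j in 1:5)
    expect_equal(G2[i, j], sum(X[i, ] * X[j, ]) / sum(usable),
                 tolerance = 1e-12)

  # own-population centering: cross-block mean exactly 0
  mats <- shared_matrices()
  pop <- attr(mats$G_own, "population")
  cross <- unclass(mats$G_own)[pop == "pop1", pop == "pop2"]
  expect_lt(abs(mean(cross)), 1e-12)
  # within-population mean diagonal near 1 + F for an outbred panel
  expect_equal(mean(diag(unclass(mats$G_own))[pop == "pop1"]), 1,
               tolerance = 0.1)
})

test_that("monomorphic loci are excluded per population with block-wise locus counts", {
  dos <- rbind(c(0, 0, 1), c(2, 0, 2), c(1, 1, 0), c(1, 2, 2))
  pan <- toy_panel(dos, c("a", "a", "b", "b"))  # locus 2 monomorphic in a
  G <- build_grm(pan, scheme = "own_population")
  nb <- attr(G, "n_loci_block")
  expect_equal(nb["a", "a"], 2L)  # loci 1 and 3
  expect_equal(nb["b", "b"], 3L)
  expect_equal(nb["a", "b"], 2L)
  expect_equal(attr(G, "n_loci"), 2L)
})

test_that("tabular pedigree matrix matches textbook values and the path-counting oracle", {
  ped <- tibble::tibble(
    id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
    population = "a", generation = c(0L, 0L, 1L))
  A <- pedigree_nrm(ped)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["o", "o"], 1.0)

  # offspring of two half sibs: F = 0.125
  ped2 <- tibble::tibble(
    id = c("gs", "d1", "d2", "h1", "h2", "x"),
    sire = c(NA, NA, NA, "gs", "gs", "h1"),
    dam = c(NA, NA, NA, "d1", "d2", "h2"),
    population = "a", generation = c(0L, 0L, 0L, 1L, 1L, 2L))
  A2 <- pedigree_nrm(ped2)
  expect_equal(A2["x", "x"], 1.125)

  # random small pedigrees against the independent recursive-kinship oracle
  set.seed(19)
  for (rep in 1:6) {
    n <- 8
    ped3 <- tibble::tibble(id = paste0("i", 1:n), sire = NA_character_,
                           dam = NA_character_, population = "a",
                           generation = 0L)
    for (i in 4:n) {
      par <- sample(1:(i - 1), 2)
      ped3$sire[i] <- paste0("i", par[1])
      ped3$dam[i] <- paste0("i", par[2])
      ped3$generation[i] <- max(ped3$generation[par]) + 1L
    }
    ped3 <- validate_pedigree(ped3)
    A3 <- pedigree_nrm(ped3)
    expect_equal(unclass(A3)[ped3$id, ped3$id], kinship_oracle(ped3),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pedigree truncation matches rebuilding from a manually cut pedigree", {
  # 9-generation single line with a side branch
  n <- 10
  ped <- tibble::tibble(
    id = paste0("g", 0:n), sire = c(NA, paste0("g", 0:(n - 1))),
    dam = NA_character_, population = "a", generation = 0:n)
  tr <- truncate_pedigree(ped, max_generations = 7)
  expect_setequal(tr$id, paste0("g", (n - 7):n))
  expect_true(is.na(tr$sire[tr$id == paste0("g", n - 7)]))
  manual <- ped[ped$generation >= (n - 7), ]
  manual$sire[manual$generation == (n - 7)] <- NA
  expect_equal(unclass(pedigree_nrm(tr)),
               unclass(pedigree_nrm(validate_pedigree(manual))),
               ignore_attr = TRUE)
})

test_that("inbreeding rescaling acts on within-population blocks only", {
  m <- matrix(c(1, 0, 0.1, 0, 1, 0, 0.1, 0, 1.2), 3,
              dimnames = list(c("a1", "a2", "b1"), c("a1", "a2", "b1")))
  G <- xpopacc:::new_relationship_matrix(m, "genomic", "pooled_equal_weight",
                                         c("a", "a", "b"), n_loci = 100)
  # F = 0 leaves the matrix unchanged
  G0 <- rescale_inbreeding(G, fbar = c(a = 0, b = 0))
  expect_equal(unclass(G0), m, ignore_attr = TRUE)
  # F = 0.5: a within-block 0 becomes 1.0; cross block untouched bitwise
  G5 <- rescale_inbreeding(G, fbar = c(a = 0.5, b = 0))
  expect_equal(G5["a1", "a2"], 1.0)
  expect_identical(G5["a1", "b1"], m["a1", "b1"])
  expect_true("inbreeding_rescaled" %in% attr(G5, "adjustments"))
  expect_error(rescale_inbreeding(G, fbar = c(a = 0.1)), "no pedigree")
})

test_that("regression to the pedigree matrix uses the stated shrinkage per bin", {
  set.seed(23)
  n <- 40
  ids <- paste0("i", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  d <- matrix(rnorm(n * n, 0, sqrt(0.02)), n); d <- (d + t(d)) / 2
  m <- A + d
  G <- xpopacc:::new_relationship_matrix(m, "genomic", "pooled_equal_weight",
                                         rep("a", n), n_loci = 100)
  Gh <- regress_to_nrm(G, A, n_loci = 100)
  bins <- attr(Gh, "regression_bins")
  off <- upper.tri(m)
  v <- var(d[off])
  b_expect <- max(0, min(1, (v - 1 / 100) / v))
  expect_equal(bins$b[1], b_expect, tolerance = 1e-12)
  # entries follow Ghat = A + b (G* - A); diagonal copied from G*
  expect_equal(Gh[1, 2], A[1, 2] + b_expect * (m[1, 2] - A[1, 2]))
  expect_equal(diag(unclass(Gh)), diag(m), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(Gh)))
  # sampling variance dominating: b ~ 1 and Ghat ~ G*
  Gh2 <- regress_to_nrm(G, A, n_loci = 1e6)
  expect_equal(unclass(Gh2)[off], m[off], tolerance = 1e-3)
})

test_that("parent-offspring pairs are exempt from regression when the pedigree is supplied", {
  ped <- tibble::tibble(
    id = c("s", "d", "o1", "o2"), sire = c(NA, NA, "s", "s"),
    dam = c(NA, NA, "d", "d"), population = "a",
    generation = c(0L, 0L, 1L, 1L))
  A <- pedigree_nrm(ped)
  set.seed(2)
  m <- unclass(A) + matrix(rnorm(16, 0, 0.05), 4) |> (\(x) (x + t(x)) / 2)()
  G <- xpopacc:::new_relationship_matrix(m, "genomic", "pooled_equal_weight",
                                         rep("a", 4), n_loci = 50)
  Gh <- regress_to_nrm(G, A, pedigree = ped)
  expect_identical(Gh["s", "o1"], m["s", "o1"])  # copied, not shrunk
})

test_that("effective segments equal the brute-force pairwise variance", {
  eye <- diag(3); dimnames(eye) <- list(c("u", "v", "w"), c("u", "v", "w"))
  expect_error(effective_segments(eye, eye, c("u", "v", "w"),
                                  mode = "within"),
               "zero variance")
  set.seed(3)
  ids <- paste0("i", 1:7)
  G <- matrix(rnorm(49, 0, 0.1), 7); G <- (G + t(G)) / 2; diag(G) <- 1
  dimnames(G) <- list(ids, ids)
  A <- diag(7); dimnames(A) <- list(ids, ids)
  refs <- ids[1:4]; cands <- ids[5:7]
  me_w <- effective_segments(G, A, refs, mode = "within")
  dvals <- (G - A)[refs, refs][upper.tri(diag(4))]
  expect_equal(me_w$me, 1 / var(dvals))
  me_a <- effective_segments(G, A, refs, cands, mode = "across")
  expect_equal(me_a$me, 1 / var(as.vector((G - A)[refs, cands])))
  expect_equal(me_a$n_pairs, 12L)
  expect_error(effective_segments(G, A, refs, ids[4:5], mode = "across"),
               "overlap")
  # reciprocal arithmetic: Var = 0.01 -> Me = 100
  D <- A; D[1, 2] <- D[2, 1] <- 0.1
  set.seed(9)
  G2 <- A + matrix(rnorm(49, 0, 0.1), 7)
  G2 <- (G2 + t(G2)) / 2; dimnames(G2) <- list(ids, ids)
  d2 <- (G2 - A)[ids[1:4], ids[5:7]]
  scale_f <- sqrt(var(as.vector(d2)) / 0.01)
  G3 <- A + (G2 - A) / scale_f
  me3 <- effective_segments(G3, A, ids[1:4], ids[5:7], mode = "across")
  expect_equal(me3$me, 100, tolerance = 1e-9)
})
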