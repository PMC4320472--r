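#' Sample correlated allele substitution effects across populations
#'
#' For each QTL, per-population effects are drawn from a multivariate
#' standard normal with the given cross-population correlation matrix, by
#' multiplying independent standard normals with the Cholesky factor of the
#' correlation matrix. With a correlation of 1 between all pairs the
#' populations receive identical effect vectors.
#'
#' @param n_qtl Number of QTL.
#' @param correlation_matrix Populations x populations genetic correlation
#'   matrix: symmetric, unit diagonal, positive semidefinite. A single
#'   number is expanded to a compound-symmetric matrix for `n_pop`
#'   populations.
#' @param seed RNG seed.
#' @param n_pop Number of populations when `correlation_matrix` is scalar.
#' @return Matrix of effects, populations in rows and QTL in columns.
#' @export
sample_qtl_effects <- function(n_qtl, correlation_matrix, seed = 1L,
                               n_pop = NULL) {
  if (length(correlation_matrix) == 1 && !is.matrix(correlation_matrix)) {
    if (is.null(n_pop)) stop("`n_pop` needed with a scalar correlation",
                             call. = FALSE)
    r <- correlation_matrix
    correlation_matrix <- matrix(r, n_pop, n_pop)
    diag(correlation_matrix) <- 1
  }
  K <- correlation_matrix
  if (!isSymmetric(unname(K), tol = 1e-10) || any(abs(diag(K) - 1) > 1e-10))
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  if (any(abs(K) > 1 + 1e-12))
    stop("correlation matrix entries must be in [-1, 1]", call. = FALSE)
  # triangular factor for the positive-definite case; a symmetric
  # eigen square root when the matrix is singular PSD (e.g. correlation 1,
  # where all populations must receive the identical effect vector)
  ch <- tryCatch(chol(K, pivot = FALSE), error = function(e) NULL)
  if (is.null(ch)) {
    ed <- eigen(K, symmetric = TRUE)
    if (min(ed$values) < -1e-12 * max(ed$values))
      stop(sprintf(
        "correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
        min(ed$values)), call. = FALSE)
    ev <- ed$values
    ev[ev < 1e-12 * max(ev)] <- 0
    ch <- diag(sqrt(ev)) %*% t(ed$vectors)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_qtl * nrow(K)), n_qtl, nrow(K))
  eff <- t(Z %*% ch)    # populations x QTL
  rownames(eff) <- rownames(K)
  eff
}

#' True breeding values from QTL dosages and population-specific effects
#'
#' The raw breeding value of an individual is the dosage-weighted sum of its
#' own population's allele substitution effects over the QTL. Breeding
#' values are then linearly rescaled to mean 0 and variance 1 across all
#' populations; the per-population means are retained (they reflect real
#' allele-frequency divergence), so population means generally differ from
#' zero after rescaling.
#'
#' @param panel A [genotype_panel()].
#' @param qtl_indices Integer indices of the QTL loci in the panel.
#' @param effects Populations x QTL effect matrix
#'   ([sample_qtl_effects()]); row order must follow `populations`.
#' @param populations Population labels matching the rows of `effects`;
#'   defaults to `rownames(effects)` or the panel's population order.
#' @return Named numeric vector of rescaled TBV, one per individual.
#' @export
compute_tbv <- function(panel, qtl_indices, effects, populations = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(populations)) populations <- rownames(effects)
  if (is.null(populations)) populations <- unique(panel$population)
  if (nrow(effects) != length(populations))
    stop("`effects` needs one row per population", call. = FALSE)
  qtl <- panel$dosage[, qtl_indices, drop = FALSE]
  tbv <- numeric(nrow(qtl))
  names(tbv) <- rownames(qtl)
  for (k in seq_along(populations)) {
    rows <- panel$population == populations[k]
    tbv[rows] <- qtl[rows, , drop = FALSE] %*% effects[k, ]
  }
  s <- stats::sd(tbv)
  if (!is.finite(s) || s == 0)
    stop("raw TBV has zero variance and cannot be rescaled", call. = FALSE)
  (tbv - mean(tbv)) / s
}

#' Simulate phenotypes at a target heritability
#'
#' Environmental effects are drawn independently per individual from
#' `Normal(0, (1/h2 - 1) * v)`, where `v` is the variance of TBV after
#' subtracting each individual's own population mean (pooled over all
#' individuals), so that all populations share the same environmental
#' variance and realized within-population heritability. The population
#' means are subtracted only for computing `v`; phenotypes are
#' `y = tbv + e` with the TBV still carrying its population mean.
#'
#' @param tbv Named numeric vector of true breeding values.
#' @param populations Population label per individual (same order as `tbv`).
#' @param h2 Target heritability, in `(0, 1]`.
#' @param seed RNG seed.
#' @return A tibble of class `simulated_phenotypes` with columns `id`,
#'   `population`, `tbv`, `e`, `y`; the environmental variance used is in
#'   `attr(, "sigma2_e")`.
#' @export
simulate_phenotypes <- function(tbv, populations, h2 = 0.95, seed = 1L) {
  if (h2 <= 0 || h2 > 1) stop("`h2` must be in (0, 1]", call. = FALSE)
  stopifnot(length(tbv) == length(populations))
  centred <- tbv - stats::ave(tbv, populations)
  v <- stats::var(centred)
  sigma2_e <- (1 / h2 - 1) * v
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  e <- stats::rnorm(length(tbv), 0, sqrt(sigma2_e))
  out <- tibble::tibble(
    id = if (is.null(names(tbv))) as.character(seq_along(tbv)) else names(tbv),
    population = as.character(populations),
    tbv = unname(tbv), e = e, y = unname(tbv) + e)
  attr(out, "sigma2_e") <- sigma2_e
  attr(out, "h2") <- h2
  class(out) <- c("simulated_phenotypes", class(out))
  out
}
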