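# restricted log-likelihood for y ~ N(X b, V); dense, used by the
# correlation model and as the common backend
.reml_loglik_dense <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Vi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  ldetX <- 2 * sum(log(diag(chX)))
  beta <- backsolve(chX, backsolve(chX, crossprod(X, Vi_y),
                                   transpose = TRUE))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * (ldetV + ldetX + yPy)
}

#' Single-trait GREML with a genomic relationship matrix
#'
#' Fits `y = X beta + a + e` on the phenotyped reference individuals, with
#' `Var(a) = G sigma2_a` and `Var(e) = I sigma2_e`, maximizing the
#' restricted likelihood over the two variance components. Population is
#' the fixed effect (an intercept when only one population is phenotyped).
#' The reference block of G is eigendecomposed once, making each likelihood
#' evaluation linear in the number of individuals; the fit is deterministic
#' given its inputs.
#'
#' @param phenotypes A data frame with columns `id`, `population`, `y`
#'   (e.g. [simulate_phenotypes()] output).
#' @param G Relationship matrix covering at least the phenotyped ids (a
#'   [build_grm()] result, typically pooled-frequency with both
#'   adjustments).
#' @param reference_ids Ids to use as phenotyped reference; defaults to all
#'   rows of `phenotypes`.
#' @param eig Optional precomputed `eigen()` of `G[reference_ids,
#'   reference_ids]` (symmetric), to reuse across replicate fits on the same
#'   panel.
#' @param max_iterations Iteration cap for the optimizer.
#' @return An object of class `greml_fit`: estimated `sigma2_a`, `sigma2_e`,
#'   `loglik`, `converged`, `iterations`, fixed-effect estimates `beta`,
#'   reference EBV `ebv`, and internals used by [blup_predict()].
#' @export
reml_single <- function(phenotypes, G, reference_ids = NULL, eig = NULL,
                        max_iterations = 200) {
  ph <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("id", "population", "y") %in% names(ph)))
  if (is.null(reference_ids)) reference_ids <- ph$id
  ph <- ph[match(reference_ids, ph$id), ]
  if (anyNA(ph$id))
    stop("phenotype missing for a reference individual", call. = FALSE)
  Gm <- rm_values(G)
  if (!all(reference_ids %in% rownames(Gm)))
    stop("G does not cover all reference individuals", call. = FALSE)
  Grr <- Gm[reference_ids, reference_ids]
  n <- length(reference_ids)
  if (max(abs(Grr - diag(n))) < 1e-8)
    stop("G is an identity on the reference: genetic and residual variance are not identifiable",
         call. = FALSE)
  pops <- factor(ph$population)
  X <- if (nlevels(pops) > 1) stats::model.matrix(~pops) else
    matrix(1, n, 1)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)
  y <- ph$y

  if (is.null(eig)) eig <- eigen(Grr, symmetric = TRUE)
  lam <- eig$values
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)

  nll <- function(theta) {
    s2a <- exp(theta[1]); s2e <- exp(theta[2])
    d <- s2a * lam + s2e
    if (any(d <= 0)) return(1e10)
    Dix <- Xt / d
    XtViX <- crossprod(Xt, Dix)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(1e10)
    Xt_vi_y <- crossprod(Dix, yt)
    beta <- backsolve(chX, backsolve(chX, Xt_vi_y, transpose = TRUE))
    yPy <- sum(yt^2 / d) - sum(Xt_vi_y * beta)
    0.5 * (sum(log(d)) + 2 * sum(log(diag(chX))) + yPy)
  }

  vy <- stats::var(y)
  opt <- stats::nlminb(log(c(0.5 * vy, 0.5 * vy)), nll,
                       control = list(iter.max = max_iterations,
                                      rel.tol = 1e-10))
  s2a <- exp(opt$par[1]); s2e <- exp(opt$par[2])
  converged <- opt$convergence == 0
  boundary <- s2a < 1e-6 * vy || s2e < 1e-6 * vy

  d <- s2a * lam + s2e
  Dix <- Xt / d
  XtViX <- crossprod(Xt, Dix)
  beta <- solve(XtViX, crossprod(Dix, yt))
  resid_t <- yt - Xt %*% beta
  vinv_resid <- eig$vectors %*% (resid_t / d)      # V^{-1}(y - X beta)
  ebv <- drop(s2a * Grr %*% vinv_resid)
  names(ebv) <- reference_ids

  structure(list(
    sigma2_a = s2a, sigma2_e = s2e, loglik = -opt$objective,
    converged = converged, boundary = boundary,
    iterations = opt$iterations,
    beta = stats::setNames(drop(beta), colnames(X)),
    ebv = ebv,
    vinv_resid = drop(vinv_resid),
    reference_ids = reference_ids,
    reference_populations = stats::setNames(ph$population, ph$id)),
    class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf(
    "<greml_fit> sigma2_a = %.4f, sigma2_e = %.4f (h2 = %.3f)\n  logL = %.3f, %s in %d iterations, n = %d\n",
    x$sigma2_a, x$sigma2_e, x$sigma2_a / (x$sigma2_a + x$sigma2_e),
    x$loglik, if (x$converged) "converged" else "NOT converged",
    x$iterations, length(x$reference_ids)))
  invisible(x)
}

#' GBLUP prediction of unphenotyped selection candidates
#'
#' `ebv_cand = sigma2_a * G[cand, ref] %*% V^{-1} (y - X beta)` with the
#' variance components and residual projection taken from a converged
#' [reml_single()] fit. A candidate unrelated to every reference individual
#' gets an EBV of 0.
#'
#' @param fit A converged `greml_fit`.
#' @param G Relationship matrix covering reference and candidate ids.
#' @param candidate_ids Ids to predict; must not overlap the phenotyped
#'   reference.
#' @return Named numeric vector of candidate EBV.
#' @export
blup_predict <- function(fit, G, candidate_ids) {
  stopifnot(inherits(fit, "greml_fit"))
  if (!fit$converged)
    stop("cannot predict from an unconverged fit", call. = FALSE)
  if (length(intersect(candidate_ids, fit$reference_ids)))
    stop("candidates overlap the phenotyped reference", call. = FALSE)
  Gm <- rm_values(G)
  missing <- setdiff(candidate_ids, rownames(Gm))
  if (length(missing))
    stop("candidate missing from G: ", missing[1], call. = FALSE)
  Gcr <- Gm[candidate_ids, fit$reference_ids, drop = FALSE]
  drop(fit$sigma2_a * Gcr %*% fit$vinv_resid)
}

#' Empirical accuracy: correlation of EBV with TBV per population
#'
#' @param ebv Named numeric vector of estimated breeding values.
#' @param tbv Named numeric vector of true breeding values (same ids).
#' @param populations Population label per individual, named by id or in the
#'   order of `ebv`.
#' @return Tibble with columns `population`, `n`, `accuracy` (Pearson
#'   correlation within each population).
#' @export
empirical_accuracy <- function(ebv, tbv, populations) {
  ids <- names(ebv)
  if (!is.null(ids)) {
    tbv <- tbv[ids]
    if (!is.null(names(populations))) populations <- populations[ids]
  }
  stopifnot(length(ebv) == length(tbv),
            length(populations) == length(ebv))
  purrr::map_dfr(unique(populations), function(p) {
    sel <- populations == p
    if (sum(sel) < 3)
      stop(sprintf("population '%s' has fewer than 3 individuals", p),
           call. = FALSE)
    if (stats::sd(ebv[sel]) == 0 || stats::sd(tbv[sel]) == 0)
      stop(sprintf("constant EBV or TBV in population '%s': correlation undefined", p),
           call. = FALSE)
    tibble::tibble(population = p, n = sum(sel),
                   accuracy = stats::cor(ebv[sel], tbv[sel]))
  })
}

#' Genetic correlation between two populations by bivariate GREML
#'
#' The same trait measured in two populations is treated as two traits. The
#' covariance structure is
#' `Var = [[s2aA G_AA, r s_aA s_aB G_AB], [., s2aB G_BB]]` plus independent
#' environmental variances per trait with zero environmental
#' cross-covariance (candidates of the two populations share no
#' environment). The focal population's genetic and environmental variances
#' and the correlation are free; the other population's components are held
#' fixed at supplied values (small populations rarely support their
#' estimation). Each trait has its own mean as fixed effect.
#'
#' @param phenotypes Data frame with `id`, `population`, `y` for both
#'   populations.
#' @param G Relationship matrix covering all phenotyped ids (same matrix as
#'   the prediction model).
#' @param pop_free Label of the population whose components are estimated.
#' @param pop_fixed Label of the population whose components are fixed.
#' @param fixed_components List with `sigma2_a` and `sigma2_e` for
#'   `pop_fixed`.
#' @param start Optional starting values `c(sigma2_a, sigma2_e, r_G)` for
#'   the free parameters.
#' @param max_iterations Iteration cap.
#' @return An object of class `greml_rg_fit` with the estimated `r_G`
#'   (constrained to (-0.999, 0.999)), free components, echoed fixed
#'   components, `loglik`, `converged` and `boundary` flags.
#' @export
reml_genetic_correlation <- function(phenotypes, G, pop_free, pop_fixed,
                                     fixed_components, start = NULL,
                                     max_iterations = 200) {
  ph <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("id", "population", "y") %in% names(ph)))
  ph <- ph[ph$population %in% c(pop_free, pop_fixed), ]
  idsA <- ph$id[ph$population == pop_free]
  idsB <- ph$id[ph$population == pop_fixed]
  if (!length(idsA) || !length(idsB))
    stop("both populations must have phenotyped individuals", call. = FALSE)
  s2aB <- fixed_components$sigma2_a
  s2eB <- fixed_components$sigma2_e
  if (is.null(s2aB) || is.null(s2eB) || s2aB <= 0 || s2eB <= 0)
    stop("`fixed_components` must supply positive sigma2_a and sigma2_e",
         call. = FALSE)
  Gm <- rm_values(G)
  ids <- c(idsA, idsB)
  if (!all(ids %in% rownames(Gm)))
    stop("G does not cover all phenotyped individuals", call. = FALSE)
  GAA <- Gm[idsA, idsA]; GBB <- Gm[idsB, idsB]; GAB <- Gm[idsA, idsB]
  nA <- length(idsA); nB <- length(idsB)
  y <- ph$y[match(ids, ph$id)]
  X <- cbind(c(rep(1, nA), rep(0, nB)), c(rep(0, nA), rep(1, nB)))

  nll <- function(theta) {
    s2aA <- exp(theta[1]); s2eA <- exp(theta[2])
    r <- 0.999 * tanh(theta[3])
    Vx <- r * sqrt(s2aA * s2aB) * GAB
    V <- rbind(cbind(s2aA * GAA + diag(s2eA, nA), Vx),
               cbind(t(Vx), s2aB * GBB + diag(s2eB, nB)))
    ll <- .reml_loglik_dense(y, X, V)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  vA <- stats::var(y[seq_len(nA)])
  if (is.null(start)) start <- c(0.5 * vA, 0.5 * vA, 0.5)
  theta0 <- c(log(start[1]), log(start[2]), atanh(start[3] / 0.999))
  opt <- stats::nlminb(theta0, nll,
                       control = list(iter.max = max_iterations,
                                      rel.tol = 1e-8))
  r_hat <- 0.999 * tanh(opt$par[3])
  s2aA <- exp(opt$par[1]); s2eA <- exp(opt$par[2])
  structure(list(
    r_G = r_hat, sigma2_a = s2aA, sigma2_e = s2eA,
    fixed_components = list(sigma2_a = s2aB, sigma2_e = s2eB),
    pop_free = pop_free, pop_fixed = pop_fixed,
    loglik = -opt$objective, converged = opt$convergence == 0,
    boundary = abs(r_hat) > 0.99 || s2aA < 1e-6 * vA,
    iterations = opt$iterations),
    class = "greml_rg_fit")
}

#' @export
print.greml_rg_fit <- function(x, ...) {
  cat(sprintf(
    "<greml_rg_fit> r_G = %.3f (%s ~ %s)\n  free: sigma2_a = %.4f, sigma2_e = %.4f; logL = %.3f, %s\n",
    x$r_G, x$pop_free, x$pop_fixed, x$sigma2_a, x$sigma2_e, x$loglik,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
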