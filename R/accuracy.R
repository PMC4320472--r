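# symmetric PD solve with a single-jitter fallback; never forms an inverse
.pd_chol <- function(M, context = "system matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    n <- nrow(M)
    if (min(ev) > -1e-8 * sum(diag(M)) / n) {
      ch <- tryCatch(chol(M + diag(1e-8, n)), error = function(e) NULL)
    }
    if (is.null(ch))
      stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                   context, min(ev)), call. = FALSE)
  }
  ch
}

# quadratic forms g_j' M^{-1} g_j for all columns of g, via one Cholesky
.quad_forms <- function(M, g, context = "system matrix") {
  ch <- .pd_chol(M, context)
  w <- backsolve(ch, g, transpose = TRUE)
  colSums(w^2)
}

#' Selection-index accuracy with a single reference population
#'
#' Accuracy of the genomic breeding value of candidates predicted from one
#' reference population:
#' `r = r_G * sqrt( g' [G_B + R_B * s2e/s2a]^{-1} g )`,
#' where `g` holds the genomic relationships between the candidate and the
#' reference individuals and `G_B` the relationships within the reference.
#' The genetic correlation `r_G` between the candidate and reference
#' populations enters as a multiplicative factor, so accuracy is exactly
#' proportional to it.
#'
#' @param g_vec Relationships between candidate(s) and reference
#'   individuals: a vector, or a matrix with one column per candidate.
#' @param G_ref Reference-by-reference genomic relationship matrix.
#' @param r_G Genetic correlation between candidate and reference
#'   populations.
#' @param sigma2_a,sigma2_e Genetic and environmental variance in the
#'   reference population; only their ratio matters.
#' @param R Environmental correlation matrix of the reference; identity when
#'   `NULL` (independent environments).
#' @return Numeric vector of accuracies, one per candidate.
#' @export
si_accuracy_single <- function(g_vec, G_ref, r_G = 1, sigma2_a = 1,
                               sigma2_e = 0, R = NULL) {
  G_ref <- rm_values(G_ref)
  g <- as.matrix(g_vec)
  if (nrow(g) != nrow(G_ref))
    stop("`g_vec` length must equal the reference population size",
         call. = FALSE)
  if (is.null(R)) R <- diag(nrow(G_ref))
  M <- G_ref + R * (sigma2_e / sigma2_a)
  q <- .quad_forms(M, g, "reference system matrix")
  r_G * sqrt(pmax(q, 0))
}

#' Selection-index accuracy with two reference populations
#'
#' Extends [si_accuracy_single()] to a combined reference of populations B
#' and C:
#' `r = sqrt( [r_AB g_B', r_AC g_C'] V^{-1} [r_AB g_B; r_AC g_C] )`
#' with the block system
#' `V = [[G_B + R_B s2eB/s2aB, r_BC G_BC], [r_BC G_BC', G_C + R_C s2eC/s2aC]]`.
#' With an empty population C (or `r_G_AC = 0` and `G_BC = 0`) this reduces
#' to the single-reference formula; with one population and candidates drawn
#' from that same population it reduces to the classical within-population
#' relationship-based accuracy.
#'
#' @param g_B,g_C Candidate-to-reference relationship vectors (or matrices,
#'   one column per candidate) for populations B and C.
#' @param G_B,G_C,G_BC Reference relationship blocks.
#' @param r_G_AB,r_G_AC,r_G_BC Genetic correlations between the candidate
#'   population A and B, A and C, and between B and C.
#' @param sigma2_a_B,sigma2_e_B,sigma2_a_C,sigma2_e_C Variance components of
#'   the two reference populations.
#' @param R_B,R_C Environmental correlation matrices; identity when `NULL`.
#' @return Numeric vector of accuracies, one per candidate.
#' @export
si_accuracy_multi <- function(g_B, g_C, G_B, G_C, G_BC,
                              r_G_AB = 1, r_G_AC = 1, r_G_BC = 1,
                              sigma2_a_B = 1, sigma2_e_B = 0,
                              sigma2_a_C = 1, sigma2_e_C = 0,
                              R_B = NULL, R_C = NULL) {
  G_B <- rm_values(G_B)
  nB <- nrow(G_B)
  nC <- if (is.null(G_C) || length(G_C) == 0) 0L else nrow(as.matrix(G_C))
  if (nC == 0L)
    return(si_accuracy_single(g_B, G_B, r_G_AB, sigma2_a_B, sigma2_e_B, R_B))
  G_C <- rm_values(G_C); G_BC <- rm_values(G_BC)
  if (nrow(G_BC) != nB || ncol(G_BC) != nC)
    stop("inconsistent block dimensions", call. = FALSE)
  gB <- as.matrix(g_B); gC <- as.matrix(g_C)
  if (nrow(gB) != nB || nrow(gC) != nC || ncol(gB) != ncol(gC))
    stop("candidate relationship vectors do not match the blocks",
         call. = FALSE)
  if (is.null(R_B)) R_B <- diag(nB)
  if (is.null(R_C)) R_C <- diag(nC)
  V <- rbind(
    cbind(G_B + R_B * (sigma2_e_B / sigma2_a_B), r_G_BC * G_BC),
    cbind(r_G_BC * t(G_BC), G_C + R_C * (sigma2_e_C / sigma2_a_C)))
  g <- rbind(r_G_AB * gB, r_G_AC * gC)
  q <- .quad_forms(V, g, "two-population block system")
  sqrt(pmax(q, 0))
}

#' Leave-one-out selection-index accuracy within one population
#'
#' For every individual, the accuracy of predicting its breeding value from
#' all remaining individuals of the same matrix, computed from a single
#' factorization of the full system `H = G + (s2e/s2a) I` through the
#' partitioned-inverse identity
#' `g_i' M_{-i}^{-1} g_i = H_ii - 1 / (H^{-1})_ii`.
#'
#' @param G Within-population genomic relationship matrix over all
#'   individuals.
#' @param r_G Genetic correlation (1 for same-population candidates).
#' @param sigma2_a,sigma2_e Variance components.
#' @return Numeric vector of accuracies, one per individual of `G`.
#' @export
si_accuracy_loo <- function(G, r_G = 1, sigma2_a = 1, sigma2_e = 0) {
  Gm <- rm_values(G)
  ratio <- sigma2_e / sigma2_a
  H <- Gm + diag(ratio, nrow(Gm))
  ch <- .pd_chol(H, "full leave-one-out system")
  Hinv <- chol2inv(ch)
  q <- diag(H) - 1 / diag(Hinv)
  stats::setNames(r_G * sqrt(pmax(q, 0)), rownames(Gm))
}

#' Population-parameter accuracy of genomic prediction
#'
#' `r_P = r_G * sqrt( N_p h2 / (N_p h2 + Me) )`: the accuracy implied by the
#' size of the reference population, the heritability, and the effective
#' number of independently segregating chromosome segments, scaled by the
#' genetic correlation between reference population and selection
#' candidates. A single value applies to all candidates of a population.
#'
#' @param N_p Reference population size.
#' @param h2 Heritability of the (pseudo-)phenotype.
#' @param Me Effective number of chromosome segments
#'   ([effective_segments()]; across mode for across-population prediction).
#' @param r_G Genetic correlation between reference and candidate
#'   populations.
#' @return Accuracy in `[0, |r_G|]`.
#' @export
pp_accuracy <- function(N_p, h2, Me, r_G = 1) {
  if (any(N_p < 1)) stop("`N_p` must be >= 1", call. = FALSE)
  if (any(h2 <= 0 | h2 > 1)) stop("`h2` must be in (0, 1]", call. = FALSE)
  if (any(Me <= 0)) stop("`Me` must be positive", call. = FALSE)
  r_G * sqrt(N_p * h2 / (N_p * h2 + Me))
}

#' Reliability of a deregressed proof from progeny information
#'
#' Accuracy of a sire's breeding value based on `n` daughter records:
#' `r = sqrt( n h2 / (n h2 + (4 - h2)) )`; the reliability is `r^2` and acts
#' as the heritability of the deregressed proof in genomic analyses. With
#' 285 daughters and `h2 = 0.25` the reliability is exactly 0.95.
#'
#' @param n_daughters Number of daughters with records.
#' @param h2 Heritability of the daughter trait.
#' @return A list with `accuracy` and `reliability`.
#' @export
drp_reliability <- function(n_daughters, h2) {
  if (any(n_daughters < 1)) stop("`n_daughters` must be >= 1", call. = FALSE)
  if (any(h2 <= 0 | h2 > 1)) stop("`h2` must be in (0, 1]", call. = FALSE)
  r <- sqrt(n_daughters * h2 / (n_daughters * h2 + (4 - h2)))
  list(accuracy = r, reliability = r^2)
}

#' Phenotypic covariance matrix of one or two reference populations
#'
#' Assembles `Var(y) = G s2a + R s2e` for a single population, or the
#' two-population block form with cross-population genetic covariance
#' `r_BC * s_aB * s_aC * G_BC` and zero environmental cross-covariance.
#'
#' @param G_blocks A list with element `B` (and optionally `C` and `BC`)
#'   holding the relationship blocks.
#' @param sigma2_a,sigma2_e Numeric vectors of genetic and environmental
#'   variances, one entry per population (named or in B, C order).
#' @param r_G_BC Genetic correlation between the two reference populations.
#' @param R_blocks Optional list of environmental correlation matrices `B`
#'   (and `C`); identity when absent.
#' @return The phenotypic covariance matrix.
#' @export
build_phenotypic_covariance <- function(G_blocks, sigma2_a, sigma2_e,
                                        r_G_BC = 1, R_blocks = NULL) {
  GB <- rm_values(G_blocks$B)
  RB <- if (!is.null(R_blocks$B)) R_blocks$B else diag(nrow(GB))
  VB <- GB * sigma2_a[1] + RB * sigma2_e[1]
  if (is.null(G_blocks$C)) return(VB)
  GC <- rm_values(G_blocks$C)
  GBC <- rm_values(G_blocks$BC)
  if (nrow(GBC) != nrow(GB) || ncol(GBC) != nrow(GC))
    stop("cross block dimensions do not match", call. = FALSE)
  RC <- if (!is.null(R_blocks$C)) R_blocks$C else diag(nrow(GC))
  VC <- GC * sigma2_a[2] + RC * sigma2_e[2]
  Vx <- r_G_BC * sqrt(sigma2_a[1] * sigma2_a[2]) * GBC
  rbind(cbind(VB, Vx), cbind(t(Vx), VC))
}
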