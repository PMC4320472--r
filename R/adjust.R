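#' Rescale the inbreeding level of a genomic relationship matrix
#'
#' When a population's own allele frequencies define the base, the
#' inbreeding level of G differs from that of the pedigree matrix A. The
#' within-population blocks are therefore rescaled as
#' `G* = (1 - Fb) G + 2 Fb J`, where `Fb` is the mean pedigree inbreeding
#' coefficient of population `b` and `J` is a matrix of ones.
#' Cross-population blocks are left untouched.
#'
#' @param G A genomic [build_grm()] matrix.
#' @param pedigree Optional pedigree tibble; the mean inbreeding per
#'   population is computed from the pedigree truncated at `max_generations`.
#' @param fbar Optional named numeric vector of mean inbreeding per
#'   population, used instead of `pedigree`.
#' @param max_generations Pedigree truncation depth used when `pedigree` is
#'   given.
#' @return The adjusted matrix with `"inbreeding_rescaled"` appended to its
#'   `adjustments` attribute.
#' @export
rescale_inbreeding <- function(G, pedigree = NULL, fbar = NULL,
                               max_generations = 7) {
  stopifnot(inherits(G, "relationship_matrix"),
            attr(G, "kind") == "genomic")
  pop <- attr(G, "population")
  if (is.null(fbar)) {
    if (is.null(pedigree))
      stop("supply either `pedigree` or `fbar`", call. = FALSE)
    nrm <- pedigree_nrm(truncate_pedigree(pedigree, max_generations))
    fbar <- mean_inbreeding(nrm, intersect(rownames(G), rownames(nrm)))
  }
  missing <- setdiff(unique(pop), names(fbar))
  if (length(missing))
    stop("population with no pedigree records: ", missing[1], call. = FALSE)
  out <- rm_values(G)
  for (b in unique(pop)) {
    rows <- which(pop == b)
    fb <- fbar[[b]]
    out[rows, rows] <- (1 - fb) * out[rows, rows] + 2 * fb
  }
  new_relationship_matrix(out, kind = "genomic", scheme = attr(G, "scheme"),
                          population = pop, n_loci = attr(G, "n_loci"),
                          n_loci_block = attr(G, "n_loci_block"),
                          excluded_loci = attr(G, "excluded_loci"),
                          adjustments = union(attr(G, "adjustments"),
                                              "inbreeding_rescaled"))
}

# direct parent-offspring pairs among `ids`, as a 2-column index matrix
.parent_offspring_pairs <- function(pedigree, ids) {
  ped <- tibble::as_tibble(pedigree)
  ped <- ped[ped$id %in% ids, ]
  pairs <- rbind(cbind(ped$id, ped$sire), cbind(ped$id, ped$dam))
  pairs <- pairs[!is.na(pairs[, 2]) & pairs[, 2] %in% ids, , drop = FALSE]
  pairs
}

#' Regress a genomic relationship matrix towards the pedigree matrix
#'
#' Sampling error from a finite number of loci makes the observed G an
#' imperfect estimate of the relationship at unobserved loci; the matrix is
#' therefore shrunk towards A as `Ghat = A + b (G* - A)` with
#' `b = (Var(G* - A) - 1/n) / Var(G* - A)` estimated separately per bin of
#' pedigree relationship, within each population and for each population
#' pair (cross-population pairs have A near 0 and fall in the first bin).
#' Self-relationships and direct parent-offspring pairs are hardly affected
#' by sampling error; they are excluded from the regression and copied from
#' G* unchanged.
#'
#' @param Gstar A genomic [build_grm()] matrix (typically after
#'   [rescale_inbreeding()]).
#' @param A A pedigree relationship matrix covering the same individuals.
#' @param n_loci Number of loci G was computed from; defaults to the
#'   matrix's `n_loci` attribute.
#' @param bins Upper edges of the inner relationship bins; pairs are binned
#'   by their A value into `(-Inf, .10], (.10, .25], (.25, .50], (.50, Inf)`
#'   by default.
#' @param pedigree Optional pedigree tibble used to identify direct
#'   parent-offspring pairs; without it only self-relationships are
#'   excluded.
#' @return The regressed matrix with `"regressed_to_A"` appended to its
#'   `adjustments` attribute and the per-bin coefficients in
#'   `attr(, "regression_bins")`.
#' @export
regress_to_nrm <- function(Gstar, A, n_loci = NULL,
                           bins = c(0.10, 0.25, 0.50), pedigree = NULL) {
  stopifnot(inherits(Gstar, "relationship_matrix"))
  ids <- rownames(Gstar)
  if (!all(ids %in% rownames(A)))
    stop("A does not cover all individuals in G", call. = FALSE)
  if (is.null(n_loci)) n_loci <- attr(Gstar, "n_loci")
  if (is.null(n_loci) || n_loci <= 0)
    stop("`n_loci` must be a positive count", call. = FALSE)
  pop <- attr(Gstar, "population")
  Gm <- rm_values(Gstar)
  Am <- rm_values(A)[ids, ids]
  n <- length(ids)

  excl <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(excl) <- TRUE
  if (!is.null(pedigree)) {
    po <- .parent_offspring_pairs(pedigree, ids)
    if (nrow(po)) {
      excl[po] <- TRUE
      excl[po[, c(2, 1), drop = FALSE]] <- TRUE
    }
  }

  edges <- c(-Inf, bins, Inf)
  out <- Gm
  bin_log <- list()
  pops <- unique(pop)
  for (ai in seq_along(pops)) for (bi in ai:length(pops)) {
    pa <- pops[ai]; pb <- pops[bi]
    ra <- which(pop == pa); rb <- which(pop == pb)
    idx <- as.matrix(expand.grid(ra, rb))
    if (pa == pb) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    idx <- idx[!excl[idx], , drop = FALSE]
    if (!nrow(idx)) next
    aval <- Am[idx]
    bin_id <- findInterval(aval, edges, left.open = TRUE)
    for (bn in sort(unique(bin_id))) {
      sel <- idx[bin_id == bn, , drop = FALSE]
      d <- Gm[sel] - Am[sel]
      if (nrow(sel) <= 1 || stats::var(d) == 0) {
        b <- 1   # degenerate bin: leave G* unshrunk
      } else {
        v <- stats::var(d)
        b <- (v - 1 / n_loci) / v
        b <- min(1, max(0, b))
      }
      newv <- Am[sel] + b * (Gm[sel] - Am[sel])
      out[sel] <- newv
      out[sel[, c(2, 1), drop = FALSE]] <- newv
      bin_log[[length(bin_log) + 1L]] <- tibble::tibble(
        pop_a = pa, pop_b = pb, bin = bn, n_pairs = nrow(sel), b = b)
    }
  }
  res <- new_relationship_matrix(
    out, kind = "genomic", scheme = attr(Gstar, "scheme"),
    population = pop, n_loci = n_loci,
    n_loci_block = attr(Gstar, "n_loci_block"),
    excluded_loci = attr(Gstar, "excluded_loci"),
    adjustments = union(attr(Gstar, "adjustments"), "regressed_to_A"))
  attr(res, "regression_bins") <- dplyr::bind_rows(bin_log)
  res
}

#' Effective number of chromosome segments
#'
#' `Me = 1 / Var(G_ij - A_ij)`, the reciprocal of the variance of the
#' deviation of genomic from pedigree relationships. In `"within"` mode the
#' variance is taken over all distinct pairs within the reference set
#' (diagonal excluded); in `"across"` mode over all reference x candidate
#' pairs, which is the quantity entering the population-parameter accuracy
#' of across-population prediction. G should be built with own-population
#' allele frequencies so that unrelated individuals have expected
#' relationship 0.
#'
#' @param G Genomic relationship matrix covering all ids.
#' @param A Pedigree relationship matrix covering all ids.
#' @param reference_ids Ids of the reference population.
#' @param candidate_ids Ids of the selection candidates (`"across"` mode).
#' @param mode `"within"` or `"across"`.
#' @return A list of class `effective_segments` with elements `me`, `mode`
#'   and `n_pairs`.
#' @export
effective_segments <- function(G, A, reference_ids, candidate_ids = NULL,
                               mode = c("within", "across")) {
  mode <- match.arg(mode)
  Gm <- rm_values(G); Am <- rm_values(A)[rownames(Gm), rownames(Gm)]
  if (mode == "within") {
    if (length(reference_ids) < 2)
      stop("need at least 2 reference individuals", call. = FALSE)
    sub <- reference_ids
    D <- Gm[sub, sub] - Am[sub, sub]
    d <- D[upper.tri(D)]
  } else {
    if (is.null(candidate_ids))
      stop("`candidate_ids` required in across mode", call. = FALSE)
    if (length(intersect(reference_ids, candidate_ids)))
      stop("reference and candidate id sets overlap", call. = FALSE)
    d <- as.vector(Gm[reference_ids, candidate_ids, drop = FALSE] -
                     Am[reference_ids, candidate_ids, drop = FALSE])
  }
  if (length(d) < 2) stop("need at least 2 pairs", call. = FALSE)
  v <- stats::var(d)
  if (v == 0) stop("zero variance of relationship deviations: Me is infinite",
                   call. = FALSE)
  structure(list(me = 1 / v, mode = mode, n_pairs = length(d)),
            class = "effective_segments")
}

#' @export
print.effective_segments <- function(x, ...) {
  cat(sprintf("<effective_segments> Me = %.1f (%s mode, %d pairs)\n",
              x$me, x$mode, x$n_pairs))
  invisible(x)
}
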