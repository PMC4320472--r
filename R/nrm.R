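#' Truncate a pedigree a fixed number of generations above its panel
#'
#' Ancestors more than `max_generations` above any panel individual are
#' replaced by unknown parents and dropped from the table, so that a uniform
#' pedigree depth is used for every individual (different pedigree depths
#' would otherwise create artificial differences in inbreeding levels
#' between populations).
#'
#' @param pedigree A pedigree tibble (`id`, `sire`, `dam`, `population`,
#'   `generation`).
#' @param max_generations Number of generations of ancestry to keep.
#' @param ids Individuals the depth is counted from; defaults to the
#'   terminal individuals (those that are nobody's parent).
#' @return The truncated, validated pedigree tibble.
#' @export
truncate_pedigree <- function(pedigree, max_generations = 7, ids = NULL) {
  ped <- validate_pedigree(pedigree)
  if (is.null(ids))
    ids <- setdiff(ped$id, c(ped$sire, ped$dam))
  if (!all(ids %in% ped$id))
    stop("individual missing from pedigree: ",
         setdiff(ids, ped$id)[1], call. = FALSE)
  dist <- stats::setNames(rep(Inf, nrow(ped)), ped$id)
  dist[ids] <- 0
  # upward sweep in reverse topological order: parent distance is one more
  # than its closest counted descendant
  for (i in rev(seq_len(nrow(ped)))) {
    d <- dist[ped$id[i]]
    if (!is.finite(d)) next
    for (par in c(ped$sire[i], ped$dam[i]))
      if (!is.na(par) && dist[par] > d + 1) dist[par] <- d + 1
  }
  keep <- is.finite(dist[ped$id]) & dist[ped$id] <= max_generations
  ped <- ped[keep, ]
  dropped <- !(ped$sire %in% ped$id)
  ped$sire[dropped] <- NA_character_
  ped$dam[!(ped$dam %in% ped$id)] <- NA_character_
  validate_pedigree(ped)
}

#' Pedigree (numerator) relationship matrix by the tabular method
#'
#' Builds A in topological order: `A_ii = 1 + F_i` with
#' `F_i = 0.5 * A(sire_i, dam_i)` and
#' `A_ij = 0.5 * (A(j, sire_i) + A(j, dam_i))` for `j < i`; unknown parents
#' contribute zero.
#'
#' @param pedigree A pedigree tibble; it is validated (acyclic, parents
#'   defined) before use.
#' @return A symmetric matrix of class `relationship_matrix`
#'   (`kind = "pedigree"`) over all pedigree individuals, in pedigree order.
#' @export
pedigree_nrm <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[prev, s] else 0
      ad_ <- if (!is.na(d)) A[prev, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new_relationship_matrix(A, kind = "pedigree", scheme = "not_applicable",
                          population = ped$population)
}

#' Mean pedigree inbreeding coefficient per population
#'
#' @param nrm A [pedigree_nrm()] result (or plain A matrix with a
#'   `population` attribute).
#' @param ids Individuals to average over (e.g. the genotyped panel);
#'   defaults to all.
#' @return Named numeric vector of mean `F = A_ii - 1` per population.
#' @export
mean_inbreeding <- function(nrm, ids = NULL) {
  pop <- attr(nrm, "population")
  if (is.null(pop)) stop("matrix carries no population labels", call. = FALSE)
  if (is.null(ids)) ids <- rownames(nrm)
  missing <- setdiff(ids, rownames(nrm))
  if (length(missing))
    stop("individual missing from pedigree matrix: ", missing[1],
         call. = FALSE)
  f <- diag(rm_values(nrm))[ids] - 1
  c(tapply(f, pop[ids], mean))
}
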