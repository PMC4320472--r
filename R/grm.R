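#' Observed allele frequencies per population and pooled
#'
#' Per-population frequency of the second allele at each locus, plus the
#' pooled frequency defined as the unweighted arithmetic mean over the
#' populations, so the pooled value is not dominated by the largest
#' population.
#'
#' @param panel A [genotype_panel()].
#' @return A list of class `allele_freq_set` with `per_population` (matrix,
#'   populations x loci) and `pooled` (numeric vector per locus).
#' @export
allele_frequencies <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  pops <- unique(panel$population)
  per <- t(vapply(pops, function(p) {
    rows <- panel$population == p
    if (!any(rows)) stop(sprintf("population '%s' is empty", p), call. = FALSE)
    colMeans(panel$dosage[rows, , drop = FALSE]) / 2
  }, numeric(ncol(panel$dosage))))
  if (length(pops) == 1) per <- matrix(per, nrow = 1)
  dimnames(per) <- list(pops, colnames(panel$dosage))
  structure(list(per_population = per, pooled = colMeans(per)),
            class = "allele_freq_set")
}

#' Genomic relationship matrix with selectable frequency centering
#'
#' Computes `G = XX'/n` from standardized dosages
#' `x = (g - 2p) / sqrt(2p(1-p))`. Under the `own_population` scheme each
#' individual is standardized with the allele frequencies of its own
#' population, which makes each population its own base: cross-population
#' blocks then average exactly zero. Under `pooled_equal_weight` the
#' equal-weight mean frequency across populations is used for everyone.
#'
#' Loci whose standardizing frequency is not strictly inside (0, 1) cannot be
#' standardized and are excluded. Under the own-population scheme exclusion
#' is per population: a locus monomorphic in one population is dropped from
#' that population's standardization and from blocks involving it, and every
#' block of the matrix is divided by the number of loci usable for that pair
#' of populations.
#'
#' @param panel A [genotype_panel()].
#' @param freqs An [allele_frequencies()] result; defaults to frequencies
#'   observed in the supplied (possibly subset) panel.
#' @param scheme `"own_population"` or `"pooled_equal_weight"`.
#' @param locus_subset Optional integer/character/logical index over loci
#'   (e.g. the marker side of a [partition_candidates()]).
#' @param individuals Optional individual ids to restrict the matrix to.
#' @return A symmetric matrix of class `relationship_matrix` with attributes
#'   `kind = "genomic"`, `scheme`, `population` (named labels), `n_loci`
#'   (loci usable in every block) and, for the own-population scheme,
#'   `n_loci_block` (per population-pair counts).
#' @export
build_grm <- function(panel, freqs = NULL,
                      scheme = c("own_population", "pooled_equal_weight"),
                      locus_subset = NULL, individuals = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  scheme <- match.arg(scheme)
  if (!is.null(individuals) || !is.null(locus_subset))
    panel <- subset_panel(panel, individuals, locus_subset)
  if (is.null(freqs)) freqs <- allele_frequencies(panel)
  stopifnot(inherits(freqs, "allele_freq_set"))
  dos <- panel$dosage
  pop <- panel$population
  pops <- unique(pop)
  n <- nrow(dos)
  Lall <- ncol(dos)

  if (scheme == "pooled_equal_weight") {
    p <- freqs$pooled[match(colnames(dos),
                            colnames(freqs$per_population))]
    if (anyNA(p)) stop("frequency set does not cover all panel loci",
                       call. = FALSE)
    usable <- p > 0 & p < 1
    if (!any(usable)) stop("no usable loci under the pooled scheme",
                           call. = FALSE)
    pu <- p[usable]
    X <- sweep(dos[, usable, drop = FALSE], 2, 2 * pu)
    X <- sweep(X, 2, sqrt(2 * pu * (1 - pu)), "/")
    G <- tcrossprod(X) / sum(usable)
    n_loci <- sum(usable)
    n_block <- NULL
    excluded <- Lall - n_loci
  } else {
    pf <- freqs$per_population[, match(colnames(dos),
                                       colnames(freqs$per_population)),
                               drop = FALSE]
    if (anyNA(pf)) stop("frequency set does not cover all panel loci",
                        call. = FALSE)
    usable <- pf > 0 & pf < 1               # populations x loci
    X <- matrix(0, n, Lall, dimnames = dimnames(dos))
    for (pp in pops) {
      rows <- pop == pp
      pv <- pf[pp, ]
      ok <- usable[pp, ]
      Xi <- sweep(dos[rows, ok, drop = FALSE], 2, 2 * pv[ok])
      X[rows, ok] <- sweep(Xi, 2, sqrt(2 * pv[ok] * (1 - pv[ok])), "/")
    }
    n_block <- matrix(0L, length(pops), length(pops),
                      dimnames = list(pops, pops))
    for (a in pops) for (b in pops)
      n_block[a, b] <- sum(usable[a, ] & usable[b, ])
    if (any(n_block == 0))
      stop("no usable loci for at least one population pair", call. = FALSE)
    G <- tcrossprod(X)
    denom <- n_block[pop, pop]
    G <- G / denom
    n_loci <- sum(apply(usable, 2, all))
    excluded <- Lall - n_loci
  }
  dimnames(G) <- list(rownames(dos), rownames(dos))
  new_relationship_matrix(G, kind = "genomic", scheme = scheme,
                          population = pop, n_loci = n_loci,
                          n_loci_block = n_block,
                          excluded_loci = excluded)
}

new_relationship_matrix <- function(mat, kind, scheme, population,
                                    n_loci = NULL, n_loci_block = NULL,
                                    excluded_loci = NULL,
                                    adjustments = character()) {
  attr(mat, "kind") <- kind
  attr(mat, "scheme") <- scheme
  attr(mat, "population") <- stats::setNames(population, rownames(mat))
  attr(mat, "n_loci") <- n_loci
  attr(mat, "n_loci_block") <- n_loci_block
  attr(mat, "excluded_loci") <- excluded_loci
  attr(mat, "adjustments") <- adjustments
  class(mat) <- c("relationship_matrix", class(mat))
  mat
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> %s, %d x %d, scheme: %s\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "scheme")))
  if (!is.null(attr(x, "n_loci")))
    cat("  loci used:", attr(x, "n_loci"), "\n")
  adj <- attr(x, "adjustments")
  if (length(adj)) cat("  adjustments:", paste(adj, collapse = ", "), "\n")
  invisible(x)
}

# plain matrix view (drops class and provenance attributes)
rm_values <- function(x) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}
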