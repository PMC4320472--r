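#' Marker quality control
#'
#' Removes, in order: loci with pooled minor allele frequency at or below
#' `maf_threshold`; loci with fewer than three genotype classes observed in
#' the pooled panel; and, scanning each chromosome left to right, any locus
#' whose squared dosage correlation with the nearest retained locus to its
#' left equals 1 (within `1e-12`) — of such a pair the leftmost locus is
#' kept.
#'
#' @param panel A [genotype_panel()].
#' @param maf_threshold Pooled minor-allele-frequency threshold; loci with
#'   MAF less than or equal to this value are removed. Default 0.005.
#' @return A list with elements `panel` (the filtered [genotype_panel()])
#'   and `report`, a tibble with one row per rule
#'   (`maf_low`, `two_genotype_classes`, `adjacent_complete_ld`) giving the
#'   number of loci removed, plus the retained count as attribute columns.
#' @export
marker_qc <- function(panel, maf_threshold = 0.005) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosage
  if (ncol(dos) == 0) stop("panel has no loci", call. = FALSE)
  n_in <- ncol(dos)

  p <- colMeans(dos) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- maf <= maf_threshold
  dos <- dos[, !drop_maf, drop = FALSE]

  n_classes <- apply(dos, 2, function(g) length(unique(g)))
  drop_cls <- n_classes < 3
  dos <- dos[, !drop_cls, drop = FALSE]

  keep_map <- panel$map[match(colnames(dos), panel$map$locus), ]
  drop_ld <- logical(ncol(dos))
  for (ch in unique(keep_map$chr)) {
    idx <- which(keep_map$chr == ch)
    if (length(idx) < 2) next
    last_kept <- idx[1]
    for (k in idx[-1]) {
      r <- stats::cor(dos[, last_kept], dos[, k])
      if (is.finite(r) && abs(r^2 - 1) < 1e-12) {
        drop_ld[k] <- TRUE
      } else {
        last_kept <- k
      }
    }
  }
  dos <- dos[, !drop_ld, drop = FALSE]

  if (ncol(dos) == 0) stop("all loci removed by quality control", call. = FALSE)
  out <- genotype_panel(dos, panel$population,
                        panel$map[match(colnames(dos), panel$map$locus), ])
  report <- tibble::tibble(
    rule = c("maf_low", "two_genotype_classes", "adjacent_complete_ld"),
    removed = c(sum(drop_maf), sum(drop_cls), sum(drop_ld)))
  stopifnot(sum(report$removed) + ncol(dos) == n_in)
  attr(report, "retained") <- ncol(dos)
  attr(report, "input_loci") <- n_in
  list(panel = out, report = report)
}

#' Partition retained loci into candidate QTL and markers
#'
#' Draws a uniform random sample of loci (without replacement) to act as the
#' candidate QTL pool; all remaining loci are the markers used for
#' relationship matrices. The partition is drawn once and held fixed across
#' replicates; only the realized QTL are resampled from the candidate pool.
#'
#' @param panel A [genotype_panel()], or a single integer giving the total
#'   number of retained loci.
#' @param n_candidates Number of candidate-QTL loci.
#' @param seed RNG seed making the partition reproducible.
#' @return A list of class `locus_partition` with sorted integer index
#'   vectors `candidate_qtl_indices` and `marker_indices`, and the `seed`.
#' @export
partition_candidates <- function(panel, n_candidates, seed = 1L) {
  n_loci <- if (inherits(panel, "genotype_panel")) ncol(panel$dosage)
            else as.integer(panel)
  if (n_candidates >= n_loci)
    stop("`n_candidates` must be smaller than the number of retained loci",
         call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  cand <- sort(sample.int(n_loci, n_candidates))
  structure(list(candidate_qtl_indices = cand,
                 marker_indices = setdiff(seq_len(n_loci), cand),
                 seed = as.integer(seed)),
            class = "locus_partition")
}

#' @export
print.locus_partition <- function(x, ...) {
  cat(sprintf("<locus_partition> %d candidate QTL + %d markers (seed %d)\n",
              length(x$candidate_qtl_indices), length(x$marker_indices),
              x$seed))
  invisible(x)
}
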