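#' Construct a genotype panel
#'
#' A genotype panel holds a dosage matrix (individuals in rows, loci in
#' columns, values 0/1/2 counting copies of the second allele), a population
#' label per individual, and a genetic map per locus.
#'
#' @param dosage Integer matrix of allele dosages in `{0, 1, 2}` with row
#'   names giving individual identifiers and column names giving locus
#'   identifiers. Missing values are not supported.
#' @param population Character vector, one population label per row of
#'   `dosage`.
#' @param map Data frame with columns `locus`, `chr` (chromosome index) and
#'   `pos_cm` (genetic position in centimorgan), one row per column of
#'   `dosage`, in the same order. Positions must be strictly increasing
#'   within a chromosome.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `population` (named by individual) and `map` (a tibble).
#' @export
#' @examples
#' dos <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("i1", "i2"), c("m1", "m2", "m3")))
#' map <- data.frame(locus = c("m1", "m2", "m3"), chr = 1, pos_cm = c(5, 10, 15))
#' genotype_panel(dos, c("A", "A"), map)
genotype_panel <- function(dosage, population, map) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix", call. = FALSE)
  if (anyNA(dosage)) {
    bad <- which(is.na(dosage), arr.ind = TRUE)[1, ]
    stop(sprintf("missing dosage for individual '%s' at locus '%s'",
                 rownames(dosage)[bad[1]], colnames(dosage)[bad[2]]),
         call. = FALSE)
  }
  if (!all(dosage %in% c(0L, 1L, 2L))) {
    bad <- which(!(dosage %in% c(0L, 1L, 2L)), arr.ind = FALSE)[1]
    ij <- arrayInd(bad, dim(dosage))
    stop(sprintf("dosage '%s' for individual '%s' at locus '%s' is not 0/1/2",
                 dosage[bad], rownames(dosage)[ij[1]], colnames(dosage)[ij[2]]),
         call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("locus", seq_len(ncol(dosage)))
  population <- as.character(population)
  if (length(population) != nrow(dosage))
    stop("`population` must have one label per individual", call. = FALSE)
  names(population) <- rownames(dosage)
  map <- tibble::as_tibble(map)
  stopifnot(all(c("locus", "chr", "pos_cm") %in% names(map)))
  if (nrow(map) != ncol(dosage))
    stop("`map` must have one row per locus", call. = FALSE)
  if (!identical(as.character(map$locus), colnames(dosage)))
    stop("`map$locus` must match the dosage column names in order", call. = FALSE)
  for (ch in unique(map$chr)) {
    p <- map$pos_cm[map$chr == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", ch),
           call. = FALSE)
  }
  structure(list(dosage = dosage, population = population, map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(x$population)
  cat(sprintf("<genotype_panel> %d individuals x %d loci (%d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chr)),
              if (length(unique(x$map$chr)) == 1) "" else "s"))
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param individuals Individual identifiers or logical/integer index over
#'   rows; `NULL` keeps all.
#' @param loci Locus identifiers or logical/integer index over columns;
#'   `NULL` keeps all.
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, individuals = NULL, loci = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ri <- if (is.null(individuals)) seq_len(nrow(panel$dosage)) else individuals
  ci <- if (is.null(loci)) seq_len(ncol(panel$dosage)) else loci
  dos <- panel$dosage[ri, ci, drop = FALSE]
  keep <- match(colnames(dos), panel$map$locus)
  genotype_panel(dos, panel$population[rownames(dos)], panel$map[keep, ])
}

#' Individual identifiers of a panel, optionally per population
#'
#' @param panel A [genotype_panel()].
#' @param population Optional population label(s); when given, only ids from
#'   those populations are returned.
#' @return Character vector of individual identifiers.
#' @export
panel_ids <- function(panel, population = NULL) {
  ids <- rownames(panel$dosage)
  if (is.null(population)) return(ids)
  ids[panel$population %in% population]
}

unknown_parent <- NA_character_

#' Validate a pedigree table
#'
#' Checks that a pedigree (tibble with columns `id`, `sire`, `dam`,
#' `population`, `generation`) is acyclic and that every named parent occurs
#' as an individual in an earlier generation. Unknown parents are `NA`.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`, `population`,
#'   `generation`.
#' @return The pedigree as a tibble, invisibly ordered by generation
#'   (topological order: parents precede offspring).
#' @export
validate_pedigree <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  need <- c("id", "sire", "dam", "population", "generation")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ped$id))
    stop("duplicated individual id in pedigree: ",
         ped$id[duplicated(ped$id)][1], call. = FALSE)
  ped <- dplyr::arrange(ped, .data$generation)
  gen <- stats::setNames(ped$generation, ped$id)
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    missing <- setdiff(par[known], ped$id)
    if (length(missing) > 0)
      stop(sprintf("parent '%s' is not an individual in the pedigree",
                   missing[1]), call. = FALSE)
    bad <- known & gen[par] >= ped$generation
    if (any(bad, na.rm = TRUE))
      stop(sprintf(
        "cycle or ordering violation: parent '%s' of '%s' is not in an earlier generation",
        par[which(bad)[1]], ped$id[which(bad)[1]]), call. = FALSE)
  }
  ped
}
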