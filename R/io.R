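#' Read and write genotype panels
#'
#' Two plain-text formats are supported. `"csv"` is a single file whose first
#' two columns are `id` and `population`, followed by one column per locus
#' named `<locus>:<chr>:<pos_cm>` (the genetic map is encoded in the header).
#' `"plink_raw"` is a PLINK `.raw`-style whitespace table
#' (`FID IID PAT MAT SEX PHENOTYPE` then one dosage column per locus, FID
#' carrying the population label) with the map written to a companion
#' `<path>.map` file (`chr locus pos_cm`).
#'
#' @param path File path.
#' @param format `"csv"` or `"plink_raw"`.
#' @param panel A [genotype_panel()].
#' @return `read_panel()` returns a [genotype_panel()]; `write_panel()`
#'   returns `path` invisibly. A write-then-read round trip reproduces the
#'   panel exactly.
#' @export
read_panel <- function(path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character")
    if (!identical(names(tab)[1:2], c("id", "population")))
      stop("malformed header: first columns must be id,population",
           call. = FALSE)
    spec <- strsplit(names(tab)[-(1:2)], ":", fixed = TRUE)
    if (any(lengths(spec) != 3))
      stop("malformed locus column header (expect <locus>:<chr>:<pos_cm>)",
           call. = FALSE)
    map <- tibble::tibble(
      locus = vapply(spec, `[`, "", 1),
      chr = as.integer(vapply(spec, `[`, "", 2)),
      pos_cm = as.numeric(vapply(spec, `[`, "", 3)))
    dos <- as.matrix(tab[, -(1:2), drop = FALSE])
    suppressWarnings(storage.mode(dos) <- "integer")
    dimnames(dos) <- list(tab$id, map$locus)
    genotype_panel(dos, tab$population, map)
  } else {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(tab)[1:6], fixed))
      stop("malformed header: expected PLINK raw columns ",
           paste(fixed, collapse = " "), call. = FALSE)
    map_path <- paste0(path, ".map")
    if (!file.exists(map_path))
      stop("companion map file not found: ", map_path, call. = FALSE)
    map <- utils::read.table(map_path, header = TRUE,
                             col.names = c("chr", "locus", "pos_cm"))
    map <- tibble::tibble(locus = as.character(map$locus),
                          chr = as.integer(map$chr),
                          pos_cm = as.numeric(map$pos_cm))
    dos <- as.matrix(tab[, -(1:6), drop = FALSE])
    suppressWarnings(storage.mode(dos) <- "integer")
    if (!identical(colnames(dos), map$locus))
      stop("dosage columns do not match the map file", call. = FALSE)
    dimnames(dos) <- list(tab$IID, map$locus)
    genotype_panel(dos, tab$FID, map)
  }
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path, format = c("csv", "plink_raw")) {
  stopifnot(inherits(panel, "genotype_panel"))
  format <- match.arg(format)
  if (format == "csv") {
    hdr <- sprintf("%s:%d:%s", panel$map$locus, panel$map$chr,
                   format(panel$map$pos_cm, digits = 15, trim = TRUE,
                          scientific = FALSE))
    out <- data.frame(id = rownames(panel$dosage),
                      population = unname(panel$population),
                      panel$dosage, check.names = FALSE)
    names(out)[-(1:2)] <- hdr
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(FID = unname(panel$population),
                      IID = rownames(panel$dosage),
                      PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                      panel$dosage, check.names = FALSE)
    utils::write.table(out, path, row.names = FALSE, quote = FALSE)
    map <- data.frame(chr = panel$map$chr, locus = panel$map$locus,
                      pos_cm = format(panel$map$pos_cm, digits = 15,
                                      trim = TRUE, scientific = FALSE))
    utils::write.table(map, paste0(path, ".map"), row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read and write pedigree tables
#'
#' Pedigrees are CSV files with header `id,sire,dam,population,generation`;
#' unknown parents are written as `0`. Reading validates the pedigree
#' (acyclic, parents present in earlier generations).
#'
#' @param path File path.
#' @param pedigree A pedigree tibble as produced by
#'   [simulate_multibreed_panel()] or [validate_pedigree()].
#' @return `read_pedigree()` returns a validated pedigree tibble;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(
    id = "character", sire = "character", dam = "character",
    population = "character", generation = "integer"))
  tab$sire[tab$sire == "0"] <- NA_character_
  tab$dam[tab$dam == "0"] <- NA_character_
  validate_pedigree(tab)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- validate_pedigree(pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write relationship matrices in GCTA-style text format
#'
#' The matrix is stored as two files: `<prefix>.grm.id` (one id per line,
#' two tab-separated columns: population and id) and `<prefix>.grm` with one
#' line per lower-triangle element: `i j n_loci value`.
#'
#' @param mat A numeric symmetric matrix with individual ids as dimnames, or
#'   a [build_grm()]/[pedigree_nrm()] result.
#' @param prefix Path prefix for the two files.
#' @param n_loci Number of loci the matrix was computed from (stored in the
#'   triplet lines); taken from the matrix attribute when available.
#' @return `read_grm()` returns the symmetric matrix with ids as dimnames and
#'   the population labels in `attr(, "population")`; `write_grm()` returns
#'   `prefix` invisibly. Round trips preserve values to better than 1e-9.
#' @export
write_grm <- function(mat, prefix, n_loci = NULL) {
  population <- attr(mat, "population")
  if (is.null(n_loci)) n_loci <- attr(mat, "n_loci")
  if (is.null(n_loci)) n_loci <- 0L
  m <- unclass(mat)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  ids <- rownames(m)
  if (is.null(population)) population <- rep("NA", length(ids))
  writeLines(paste(population, ids, sep = "\t"),
             paste0(prefix, ".grm.id"))
  n <- nrow(m)
  i <- rep(seq_len(n), times = seq_len(n))
  j <- sequence(seq_len(n))
  writeLines(sprintf("%d\t%d\t%d\t%.12g", i, j, as.integer(n_loci[1]),
                     m[cbind(i, j)]),
             paste0(prefix, ".grm"))
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  idtab <- utils::read.table(paste0(prefix, ".grm.id"),
                             col.names = c("population", "id"),
                             colClasses = "character")
  tri <- utils::read.table(paste0(prefix, ".grm"),
                           col.names = c("i", "j", "n_loci", "value"))
  n <- nrow(idtab)
  m <- matrix(0, n, n, dimnames = list(idtab$id, idtab$id))
  m[cbind(tri$i, tri$j)] <- tri$value
  m[cbind(tri$j, tri$i)] <- tri$value
  attr(m, "population") <- stats::setNames(idtab$population, idtab$id)
  attr(m, "n_loci") <- tri$n_loci[1]
  m
}
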