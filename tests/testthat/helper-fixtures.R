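# shared fixtures, built lazily once per test run

.fixtures <- new.env(parent = emptyenv())

# two-population panel with family structure: the workhorse for the
# relationship, GREML and scenario tests
shared_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- synth_config(n_populations = 2, founders_per_population = 40,
                        ancestral_pool_size = 60, burnin_generations = 30,
                        divergence_generations = 15,
                        loci_per_chromosome = 2400,
                        chromosome_lengths = c(0.8, 0.8, 0.8),
                        final_panel_sizes = c(200, 80), seed = 42)
    .fixtures$sim <- simulate_multibreed_panel(cfg)
  }
  .fixtures$sim
}

shared_qc <- function() {
  if (is.null(.fixtures$qc)) .fixtures$qc <- marker_qc(shared_sim()$panel)
  .fixtures$qc
}

shared_partition <- function() {
  if (is.null(.fixtures$part))
    .fixtures$part <- partition_candidates(shared_qc()$panel, 1000, seed = 7)
  .fixtures$part
}

# own-frequency marker GRM + truncated-pedigree NRM on the shared panel
shared_matrices <- function() {
  if (is.null(.fixtures$mats)) {
    sim <- shared_sim(); qc <- shared_qc(); part <- shared_partition()
    tped <- truncate_pedigree(sim$pedigree)
    nrm <- pedigree_nrm(tped)
    G_pool <- build_grm(qc$panel, scheme = "pooled_equal_weight",
                        locus_subset = part$marker_indices)
    .fixtures$mats <- list(
      G_own = build_grm(qc$panel, scheme = "own_population",
                        locus_subset = part$marker_indices),
      G_pool = G_pool,
      G_pool_reg = regress_to_nrm(G_pool, nrm, pedigree = tped),
      nrm = nrm, tped = tped)
  }
  .fixtures$mats
}

# small hand-specified panel builder
toy_panel <- function(dosage, population, chr = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("m", seq_len(ncol(dosage)))
  if (is.null(chr)) chr <- rep(1L, ncol(dosage))
  if (is.null(pos)) pos <- seq_len(ncol(dosage))
  genotype_panel(dosage, population,
                 data.frame(locus = colnames(dosage), chr = chr,
                            pos_cm = pos))
}

# independent path-counting pedigree relationship oracle (recursive kinship)
kinship_oracle <- function(ped) {
  ids <- ped$id
  sire <- stats::setNames(ped$sire, ids)
  dam <- stats::setNames(ped$dam, ids)
  ord <- stats::setNames(seq_along(ids), ids)
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (a == b) {
      s <- sire[[a]]; d <- dam[[a]]
      return(0.5 * (1 + f(s, d)))
    }
    # recurse on the younger individual
    if (ord[[a]] < ord[[b]]) { tmp <- a; a <- b; b <- tmp }
    0.5 * (f(sire[[a]], b) + f(dam[[a]], b))
  }
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) A[i, j] <- 2 * f(i, j) * ifelse(i == j, 1, 1)
  for (i in ids) A[i, i] <- 2 * f(i, i)
  A
}

# dense restricted log-likelihood, written independently of the package
reml_loglik_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(y) %*% P %*% y) |> as.numeric()
}
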