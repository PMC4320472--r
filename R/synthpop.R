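#' Configuration for the multi-breed gene-dropping simulator
#'
#' Defines the demographic design used by [simulate_multibreed_panel()]:
#' an ancestral random-mating pool that establishes short-range linkage
#' disequilibrium, independent drift of each population after the split, and
#' a final within-breed breeding phase with few sires per generation that
#' creates dairy-cattle-like paternal half-sib families.
#'
#' @param n_populations Number of populations to split off the ancestral pool.
#' @param founders_per_population Diploid founders per population at the
#'   split; this is also the census (and approximate effective) size during
#'   the divergence phase.
#' @param sires_per_generation Number of sires used in each within-breed
#'   breeding generation.
#' @param dams_per_generation Maximum number of dams used in each
#'   within-breed generation (capped at the number of available females).
#' @param offspring_generations_within Number of within-breed breeding
#'   generations after divergence.
#' @param divergence_generations Generations of independent random mating per
#'   population after the split.
#' @param ancestral_pool_size Diploid size of the ancestral pool.
#' @param burnin_generations Random-mating generations inside the ancestral
#'   pool before the split, used to build up linkage disequilibrium.
#' @param chromosome_lengths Numeric vector of chromosome lengths in Morgan.
#' @param loci_per_chromosome Number of evenly spaced loci per chromosome.
#' @param final_panel_sizes Integer vector, one entry per population: size of
#'   every within-breed generation and of the returned panel.
#' @param seed RNG seed; the simulation is deterministic given the seed.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_populations = 3,
                         founders_per_population = 50,
                         sires_per_generation = 10,
                         dams_per_generation = 200,
                         offspring_generations_within = 3,
                         divergence_generations = 20,
                         ancestral_pool_size = 100,
                         burnin_generations = 50,
                         chromosome_lengths = c(1, 1, 1),
                         loci_per_chromosome = 4000,
                         final_panel_sizes = c(400, 100, 100),
                         seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              founders_per_population = as.integer(founders_per_population),
              sires_per_generation = as.integer(sires_per_generation),
              dams_per_generation = as.integer(dams_per_generation),
              offspring_generations_within = as.integer(offspring_generations_within),
              divergence_generations = as.integer(divergence_generations),
              ancestral_pool_size = as.integer(ancestral_pool_size),
              burnin_generations = as.integer(burnin_generations),
              chromosome_lengths = as.numeric(chromosome_lengths),
              loci_per_chromosome = as.integer(loci_per_chromosome),
              final_panel_sizes = as.integer(final_panel_sizes),
              seed = as.integer(seed))
  counts <- c("n_populations", "founders_per_population", "sires_per_generation",
              "dams_per_generation", "ancestral_pool_size", "loci_per_chromosome")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(sprintf("`%s` must be >= 1", nm), call. = FALSE)
  for (nm in c("offspring_generations_within", "divergence_generations",
               "burnin_generations"))
    if (cfg[[nm]] < 0L) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  if (any(cfg$chromosome_lengths <= 0))
    stop("chromosome lengths must be positive (Morgan)", call. = FALSE)
  if (length(cfg$final_panel_sizes) != cfg$n_populations)
    stop("`final_panel_sizes` needs one entry per population", call. = FALSE)
  if (any(cfg$final_panel_sizes < 1L))
    stop("final panel sizes must be >= 1", call. = FALSE)
  # sex alternates at birth, so a cohort of n holds ceiling(n/2) males
  if (cfg$sires_per_generation > ceiling(cfg$founders_per_population / 2))
    stop("infeasible mating design: fewer male founders than sires required",
         call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

# one gamete: recombinant mosaic of the two parental haplotypes under
# Haldane's model (Poisson crossovers, uniform breakpoints, no interference)
.gamete <- function(h1, h2, geno) {
  out <- h1
  for (c in seq_along(geno$len_m)) {
    idx <- geno$idx[[c]]
    nx <- stats::rpois(1L, geno$len_m[c])
    start <- sample.int(2L, 1L) - 1L
    if (nx == 0L) {
      if (start == 1L) out[idx] <- h2[idx]
    } else {
      bp <- sort(stats::runif(nx, 0, geno$len_m[c]))
      src <- (start + findInterval(geno$pos_m[[c]], bp)) %% 2L
      sel <- idx[src == 1L]
      out[sel] <- h2[sel]
    }
  }
  out
}

# random-mating generation at constant size n; H is (2n x L), rows 2i-1, 2i
# belong to individual i; sex of individual i is i %% 2 (1 = male)
.random_mating_generation <- function(H, n_off, sires, dams, geno,
                                      balanced = FALSE) {
  Hn <- matrix(0L, nrow = 2L * n_off, ncol = ncol(H))
  if (balanced) {
    # equalized parental shares: half-sib family design of the breeding phase
    sire_of <- sample(rep_len(sires, n_off))
    dam_of <- sample(rep_len(dams, n_off))
  } else {
    # multinomial family sizes: keeps effective size near census size
    sire_of <- sample(sires, n_off, replace = TRUE)
    dam_of <- sample(dams, n_off, replace = TRUE)
  }
  for (i in seq_len(n_off)) {
    s <- sire_of[i]; d <- dam_of[i]
    Hn[2L * i - 1L, ] <- .gamete(H[2L * s - 1L, ], H[2L * s, ], geno)
    Hn[2L * i, ] <- .gamete(H[2L * d - 1L, ], H[2L * d, ], geno)
  }
  list(H = Hn, sire = sire_of, dam = dam_of)
}

#' Simulate a multi-population genotype panel with matching pedigree
#'
#' Gene-dropping simulation: ancestral haplotypes are drawn locus-wise with
#' allele frequencies Uniform(0.1, 0.9), the ancestral pool random-mates for
#' a burn-in period to build short-range linkage disequilibrium, populations
#' then split and drift independently, and finally each breeds with a
#' few-sires/many-dams design that produces paternal half-sib families.
#' Gametes are formed under Haldane's recombination model. Loci are placed
#' evenly along each chromosome.
#'
#' @param config A [synth_config()].
#' @return A list with elements `panel` (a [genotype_panel()] of the last
#'   within-breed generation of every population; the phased haplotypes are
#'   kept in `attr(panel, "haplotypes")`) and `pedigree` (a tibble covering
#'   the divergence and breeding phases; population founders at the split
#'   have unknown parents).
#' @export
#' @examples
#' cfg <- synth_config(n_populations = 2, founders_per_population = 10,
#'                     divergence_generations = 2, ancestral_pool_size = 20,
#'                     burnin_generations = 5, loci_per_chromosome = 50,
#'                     chromosome_lengths = 1, final_panel_sizes = c(20, 20),
#'                     offspring_generations_within = 1, sires_per_generation = 3,
#'                     seed = 42)
#' sim <- simulate_multibreed_panel(cfg)
#' sim$panel
simulate_multibreed_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  n_chr <- length(config$chromosome_lengths)
  m <- config$loci_per_chromosome
  L <- n_chr * m
  geno <- list(
    len_m = config$chromosome_lengths,
    idx = lapply(seq_len(n_chr), function(c) ((c - 1L) * m + 1L):(c * m)),
    pos_m = lapply(seq_len(n_chr), function(c)
      (seq_len(m) - 0.5) / m * config$chromosome_lengths[c]))
  map <- tibble::tibble(
    locus = paste0("c", rep(seq_len(n_chr), each = m), "_l",
                   rep(seq_len(m), n_chr)),
    chr = rep(seq_len(n_chr), each = m),
    pos_cm = unlist(geno$pos_m) * 100)

  # ancestral pool + burn-in
  p0 <- stats::runif(L, 0.1, 0.9)
  n_anc <- config$ancestral_pool_size
  H <- matrix(stats::rbinom(2L * n_anc * L, 1L, rep(p0, each = 2L * n_anc)),
              nrow = 2L * n_anc, ncol = L)
  anc_males <- which(seq_len(n_anc) %% 2L == 1L)
  anc_females <- which(seq_len(n_anc) %% 2L == 0L)
  for (g in seq_len(config$burnin_generations))
    H <- .random_mating_generation(H, n_anc, anc_males, anc_females, geno)$H

  ped_list <- list()
  panels <- list()
  haps <- list()
  nf <- config$founders_per_population

  for (pop in seq_len(config$n_populations)) {
    pop_lab <- paste0("pop", pop)
    # founders: one more random-mating draw out of the (unpedigreed) pool
    Hp <- .random_mating_generation(H, nf, anc_males, anc_females, geno)$H
    ids <- paste0(pop_lab, "_g0_", seq_len(nf))
    ped_list[[length(ped_list) + 1L]] <- tibble::tibble(
      id = ids, sire = NA_character_, dam = NA_character_,
      population = pop_lab, generation = 0L)
    prev_ids <- ids
    gen <- 0L
    # divergence phase: random mating at constant census size
    for (g in seq_len(config$divergence_generations)) {
      gen <- gen + 1L
      males <- which(seq_len(nf) %% 2L == 1L)
      females <- which(seq_len(nf) %% 2L == 0L)
      res <- .random_mating_generation(Hp, nf, males, females, geno)
      Hp <- res$H
      ids <- paste0(pop_lab, "_g", gen, "_", seq_len(nf))
      ped_list[[length(ped_list) + 1L]] <- tibble::tibble(
        id = ids, sire = prev_ids[res$sire], dam = prev_ids[res$dam],
        population = pop_lab, generation = gen)
      prev_ids <- ids
    }
    # within-breed breeding phase: few sires, many dams, half-sib families
    n_prev <- nf
    n_target <- config$final_panel_sizes[pop]
    for (g in seq_len(config$offspring_generations_within)) {
      gen <- gen + 1L
      males <- which(seq_len(n_prev) %% 2L == 1L)
      females <- which(seq_len(n_prev) %% 2L == 0L)
      if (length(males) < config$sires_per_generation)
        stop("infeasible mating design: fewer males than sires required",
             call. = FALSE)
      sires <- sample(males, config$sires_per_generation)
      dams <- if (length(females) > config$dams_per_generation)
        sample(females, config$dams_per_generation) else females
      res <- .random_mating_generation(Hp, n_target, sires, dams, geno,
                                       balanced = TRUE)
      Hp <- res$H
      ids <- paste0(pop_lab, "_g", gen, "_", seq_len(n_target))
      ped_list[[length(ped_list) + 1L]] <- tibble::tibble(
        id = ids, sire = prev_ids[res$sire], dam = prev_ids[res$dam],
        population = pop_lab, generation = gen)
      prev_ids <- ids
      n_prev <- n_target
    }
    rownames(Hp) <- paste0(rep(prev_ids, each = 2L), c("_h1", "_h2"))
    haps[[pop]] <- Hp
    dos <- Hp[seq(1L, nrow(Hp), by = 2L), , drop = FALSE] +
      Hp[seq(2L, nrow(Hp), by = 2L), , drop = FALSE]
    rownames(dos) <- prev_ids
    panels[[pop]] <- dos
  }

  dosage <- do.call(rbind, panels)
  colnames(dosage) <- map$locus
  population <- rep(paste0("pop", seq_len(config$n_populations)),
                    times = config$final_panel_sizes)
  panel <- genotype_panel(dosage, population, map)
  hap_all <- do.call(rbind, haps)
  colnames(hap_all) <- map$locus
  attr(panel, "haplotypes") <- hap_all
  pedigree <- validate_pedigree(dplyr::bind_rows(ped_list))
  list(panel = panel, pedigree = pedigree)
}

#' Hudson's FST between two populations of a panel
#'
#' Ratio-of-averages Hudson estimator over polymorphic loci:
#' per-locus numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#' p_2(1-p_2)/(n_2-1)} and denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, with
#' \eqn{n_i} the number of sampled alleles, averaged before taking the ratio.
#'
#' @param panel A [genotype_panel()].
#' @param pop_a,pop_b Population labels present in the panel.
#' @return A single FST estimate (may be slightly negative by sampling).
#' @export
estimate_fst <- function(panel, pop_a, pop_b) {
  stopifnot(inherits(panel, "genotype_panel"))
  for (p in c(pop_a, pop_b))
    if (sum(panel$population == p) < 2)
      stop(sprintf("population '%s' absent or has fewer than 2 individuals", p),
           call. = FALSE)
  da <- panel$dosage[panel$population == pop_a, , drop = FALSE]
  db <- panel$dosage[panel$population == pop_b, , drop = FALSE]
  n1 <- 2 * nrow(da); n2 <- 2 * nrow(db)
  p1 <- colMeans(da) / 2
  p2 <- colMeans(db) / 2
  poly <- !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(poly)) stop("no polymorphic loci between the two populations",
                       call. = FALSE)
  p1 <- p1[poly]; p2 <- p2[poly]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
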