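#' Cross-validation folds
#'
#' Randomly divides ids into `k` disjoint, exhaustive groups whose sizes
#' differ by at most one; each group serves once as selection candidates
#' with the remainder as reference.
#'
#' @param ids Character vector of individual ids.
#' @param k Number of folds.
#' @param seed RNG seed; folds are deterministic given the seed.
#' @return A list of `k` character vectors.
#' @export
make_cv_folds <- function(ids, k = 20, seed = 1L) {
  if (k > length(ids)) stop("`k` exceeds the number of ids", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  unname(split(sample(ids), rep_len(seq_len(k), length(ids))))
}

#' Specification of a prediction scenario
#'
#' A scenario names the reference population(s), the candidate population,
#' the assumed genetic correlation between allele substitution effects
#' across populations, the trait settings, and the replication design. In
#' the base (within-population) scenario the candidate population equals
#' the single reference population: the deterministic accuracy is then
#' leave-one-out and the empirical accuracy uses k-fold cross-validation.
#'
#' @param name Scenario name.
#' @param reference_populations One or two population labels.
#' @param candidate_population A single population label.
#' @param r_G Genetic correlation between allele substitution effects of
#'   every pair of populations.
#' @param h2 Simulated heritability.
#' @param n_qtl Number of QTL drawn per replicate from the candidate pool.
#' @param n_replicates Number of phenotype replicates.
#' @param cv_folds Number of cross-validation folds (base scenario only).
#' @param base_seed Base RNG seed; replicate seeds are derived from it by
#'   fixed offsets.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, reference_populations, candidate_population,
                          r_G = 1, h2 = 0.95, n_qtl = 300,
                          n_replicates = 20, cv_folds = 20, base_seed = 1L) {
  is_base <- identical(sort(reference_populations),
                       sort(candidate_population))
  if (!is_base && candidate_population %in% reference_populations)
    stop("candidate population must not be among the reference populations in an across scenario",
         call. = FALSE)
  if (length(reference_populations) > 2)
    stop("at most two reference populations are supported", call. = FALSE)
  structure(list(name = name,
                 reference_populations = reference_populations,
                 candidate_population = candidate_population,
                 r_G = r_G, h2 = h2, n_qtl = n_qtl,
                 n_replicates = n_replicates, cv_folds = cv_folds,
                 base_seed = as.integer(base_seed), is_base = is_base),
            class = "scenario_spec")
}

# deterministic seeds per replicate, recorded in the report
.replicate_seeds <- function(base_seed, r) {
  list(qtl = base_seed + r,
       effect = base_seed + 100000L + r,
       noise = base_seed + 200000L + r,
       fold = base_seed + 300000L + r)
}

#' Run a prediction scenario end to end
#'
#' For the scenario's populations this computes, on the marker side of the
#' locus partition: (1) the deterministic selection-index accuracy per
#' candidate (leave-one-out within the population for the base scenario,
#' one- or two-reference-population formula otherwise) using the
#' own-population-frequency G and the simulation-truth variance ratio;
#' (2) the population-parameter accuracy using the effective number of
#' chromosome segments from the deviation of G from A (across-pairs mode for
#' across-population scenarios); and (3) the empirical accuracy per
#' replicate: phenotypes are simulated from QTL resampled out of the
#' candidate pool with cross-population effect correlation `r_G`, a GREML
#' model with population fixed effects is fitted on the reference
#' phenotypes using the pooled-frequency adjusted G, candidates are
#' predicted by GBLUP, and EBV are correlated with TBV within the candidate
#' population.
#'
#' @param spec A [scenario_spec()].
#' @param panel A post-QC [genotype_panel()].
#' @param pedigree The matching pedigree tibble.
#' @param partition A [partition_candidates()] result on this panel.
#' @param fast_cv Base scenario only: estimate variance components on the
#'   first fold and reuse them for the remaining folds of the same
#'   replicate (the default refits per fold).
#' @param adjust_grm Apply inbreeding rescaling and regression to A to the
#'   pooled-frequency G used by GREML (default `TRUE`).
#' @return An object of class `accuracy_report`; see
#'   [summarize_replicates()].
#' @export
run_scenario <- function(spec, panel, pedigree, partition,
                         fast_cv = FALSE, adjust_grm = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(panel, "genotype_panel"),
            inherits(partition, "locus_partition"))
  pops_used <- unique(c(spec$reference_populations,
                        spec$candidate_population))
  ids <- panel_ids(panel, pops_used)
  sub <- subset_panel(panel, ids)
  markers <- partition$marker_indices
  ref_ids <- panel_ids(panel, spec$reference_populations)
  cand_ids <- panel_ids(panel, spec$candidate_population)

  tped <- truncate_pedigree(pedigree)
  nrm <- pedigree_nrm(tped)
  missing_ped <- setdiff(ids, rownames(nrm))
  if (length(missing_ped))
    stop("panel individual missing from truncated pedigree: ",
         missing_ped[1], call. = FALSE)

  G_own <- build_grm(sub, scheme = "own_population", locus_subset = markers)
  G_pool <- build_grm(sub, scheme = "pooled_equal_weight",
                      locus_subset = markers)
  if (adjust_grm) {
    G_pool <- rescale_inbreeding(G_pool, fbar = mean_inbreeding(nrm, ids))
    G_pool <- regress_to_nrm(G_pool, nrm, pedigree = tped)
  }
  ratio_var <- (1 / spec$h2 - 1)   # sigma2_e / sigma2_a on the TBV scale

  # deterministic accuracies: no phenotypes involved, computed once
  if (spec$is_base) {
    Gp <- G_own[cand_ids, cand_ids]
    si <- si_accuracy_loo(Gp, r_G = 1, sigma2_a = 1, sigma2_e = ratio_var)
    si_tbl <- tibble::tibble(candidate_id = cand_ids, accuracy = unname(si))
    me <- effective_segments(G_own, nrm, ref_ids[-1], mode = "within")
    # reference size for one left-out candidate
    n_ref_det <- length(ref_ids) - 1L
    pp <- pp_accuracy(n_ref_det, spec$h2, me$me, r_G = 1)
  } else {
    refA <- panel_ids(panel, spec$reference_populations[1])
    g_A <- rm_values(G_own)[refA, cand_ids, drop = FALSE]
    G_A <- rm_values(G_own)[refA, refA]
    if (length(spec$reference_populations) == 1) {
      si <- si_accuracy_single(g_A, G_A, r_G = spec$r_G,
                               sigma2_a = 1, sigma2_e = ratio_var)
    } else {
      refB <- panel_ids(panel, spec$reference_populations[2])
      g_B <- rm_values(G_own)[refB, cand_ids, drop = FALSE]
      si <- si_accuracy_multi(
        g_A, g_B, G_A, rm_values(G_own)[refB, refB],
        rm_values(G_own)[refA, refB],
        r_G_AB = spec$r_G, r_G_AC = spec$r_G, r_G_BC = spec$r_G,
        sigma2_a_B = 1, sigma2_e_B = ratio_var,
        sigma2_a_C = 1, sigma2_e_C = ratio_var)
    }
    si_tbl <- tibble::tibble(candidate_id = cand_ids, accuracy = unname(si))
    me <- effective_segments(G_own, nrm, ref_ids, cand_ids, mode = "across")
    pp <- pp_accuracy(length(ref_ids), spec$h2, me$me, r_G = spec$r_G)
  }

  # empirical accuracy per replicate
  corr <- matrix(spec$r_G, length(pops_used), length(pops_used),
                 dimnames = list(pops_used, pops_used))
  diag(corr) <- 1
  eig_ref <- if (!spec$is_base)
    eigen(rm_values(G_pool)[ref_ids, ref_ids], symmetric = TRUE) else NULL

  emp_list <- list()
  seed_list <- list()
  for (r in seq_len(spec$n_replicates)) {
    sd_r <- .replicate_seeds(spec$base_seed, r)
    qtl_pool <- partition$candidate_qtl_indices
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(sd_r$qtl)
    qtl <- sample(qtl_pool, spec$n_qtl)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    eff <- sample_qtl_effects(spec$n_qtl, corr, seed = sd_r$effect)
    tbv <- compute_tbv(sub, qtl, eff, populations = pops_used)
    ph <- simulate_phenotypes(tbv, sub$population, spec$h2,
                              seed = sd_r$noise)
    if (spec$is_base) {
      folds <- make_cv_folds(cand_ids, spec$cv_folds, seed = sd_r$fold)
      ebv <- numeric(0)
      fit0 <- NULL
      for (f in folds) {
        train <- setdiff(ref_ids, f)
        if (fast_cv && !is.null(fit0)) {
          # reuse the first fold's variance components; refresh beta and
          # the residual projection on this fold's reference
          fit <- .refresh_projection(fit0, G_pool, ph, train)
        } else {
          fit <- reml_single(ph, G_pool, train)
          if (is.null(fit0)) fit0 <- fit
        }
        ebv <- c(ebv, blup_predict(fit, G_pool, f))
      }
      acc <- empirical_accuracy(ebv, tbv[names(ebv)],
                                sub$population[names(ebv)])
    } else {
      fit <- reml_single(ph, G_pool, ref_ids, eig = eig_ref)
      ebv <- blup_predict(fit, G_pool, cand_ids)
      acc <- empirical_accuracy(ebv, tbv[cand_ids],
                                sub$population[cand_ids])
    }
    acc$replicate <- r
    emp_list[[r]] <- acc
    seed_list[[r]] <- tibble::tibble(replicate = r, qtl_seed = sd_r$qtl,
                                     effect_seed = sd_r$effect,
                                     noise_seed = sd_r$noise)
  }

  structure(list(
    spec = spec,
    si = si_tbl,
    pp = tibble::tibble(candidate_population = spec$candidate_population,
                        me = me$me, n_ref = length(ref_ids),
                        accuracy = pp),
    empirical = dplyr::bind_rows(emp_list),
    seeds = dplyr::bind_rows(seed_list)),
    class = "accuracy_report")
}

# recompute beta/ebv/projection at fixed variance components
.refresh_projection <- function(fit, G, phenotypes, reference_ids) {
  ph <- tibble::as_tibble(phenotypes)
  ph <- ph[match(reference_ids, ph$id), ]
  Gm <- rm_values(G)
  Grr <- Gm[reference_ids, reference_ids]
  n <- length(reference_ids)
  V <- fit$sigma2_a * Grr + diag(fit$sigma2_e, n)
  pops <- factor(ph$population)
  X <- if (nlevels(pops) > 1) stats::model.matrix(~pops) else matrix(1, n, 1)
  ch <- chol(V)
  Vi_y <- backsolve(ch, backsolve(ch, ph$y, transpose = TRUE))
  Vi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  resid <- ph$y - X %*% beta
  vinv_resid <- backsolve(ch, backsolve(ch, resid, transpose = TRUE))
  fit$beta <- drop(beta)
  fit$vinv_resid <- drop(vinv_resid)
  fit$reference_ids <- reference_ids
  fit$ebv <- drop(fit$sigma2_a * Grr %*% fit$vinv_resid)
  fit$converged <- TRUE
  fit
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> scenario '%s': %s -> %s, r_G = %g\n",
              x$spec$name,
              paste(x$spec$reference_populations, collapse = "+"),
              x$spec$candidate_population, x$spec$r_G))
  print(summarize_replicates(x))
  invisible(x)
}

#' Summarize an accuracy report across replicates and candidates
#'
#' @param reports An `accuracy_report` or a list of them.
#' @return A tibble with one row per scenario x method x candidate
#'   population: `mean`, `sd`, `se` and the axis the spread is taken over
#'   (replicates for the empirical method, candidates for the
#'   selection-index method; the population-parameter accuracy is a single
#'   number). With a single replicate the empirical `se` is `NA`.
#' @export
summarize_replicates <- function(reports) {
  if (inherits(reports, "accuracy_report")) reports <- list(reports)
  purrr::map_dfr(reports, function(rep) {
    emp <- rep$empirical |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(
        mean = mean(.data$accuracy),
        sd = if (dplyr::n() > 1) stats::sd(.data$accuracy) else NA_real_,
        n = dplyr::n(), .groups = "drop") |>
      dplyr::transmute(
        scenario = rep$spec$name, method = "empirical",
        population = .data$population, mean = .data$mean, sd = .data$sd,
        se = .data$sd / sqrt(.data$n), n = .data$n, axis = "replicates")
    si <- tibble::tibble(
      scenario = rep$spec$name, method = "selection_index",
      population = rep$spec$candidate_population,
      mean = mean(rep$si$accuracy),
      sd = stats::sd(rep$si$accuracy),
      se = stats::sd(rep$si$accuracy) / sqrt(nrow(rep$si)),
      n = nrow(rep$si), axis = "candidates")
    pp <- tibble::tibble(
      scenario = rep$spec$name, method = "population_parameters",
      population = rep$spec$candidate_population,
      mean = rep$pp$accuracy, sd = NA_real_, se = NA_real_, n = 1L,
      axis = "single")
    dplyr::bind_rows(emp, si, pp)
  })
}
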