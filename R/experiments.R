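#' Derive per-replicate child seeds from a master seed
#'
#' Replicates are independent given their child seeds, so any single
#' replicate can be reproduced in isolation from the logged seed.
#'
#' @param master master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of `n` seeds.
#' @export
child_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2147483647L, n)
}

# Dispatch a model fit by name.
fit_model <- function(model, Z, y, alpha = 0.2, bayes = list()) {
  switch(model,
         rrblup = fit_rrblup(Z, y),
         ols = fit_ols_stepwise(Z, y, alpha),
         bayescpi = do.call(fit_bayescpi, c(list(Z = Z, y = y), bayes)),
         stop("unknown model: ", model, call. = FALSE))
}

subset_population <- function(pop, idx) {
  new_population(pop$hap1[, idx, drop = FALSE], pop$hap2[, idx, drop = FALSE],
                 pop$generation)
}

# One cross-validation replicate: fresh architecture, one DH population from
# one F1, first n_train lines are candidates for phenotyping, the last
# n_validation lines are never phenotyped and never enter training.
# Returns one accuracy per model (all models see identical data).
cv_replicate <- function(genome, n_train, n_ph, r, h2plot, models,
                         n_validation, alpha, n_qtl, n_markers, bayes) {
  arch <- assign_architecture(genome, n_qtl, n_markers)
  pop <- make_dh_population(founder_f1(genome), n_train + n_validation, genome)
  gv <- genetic_values(pop, arch)
  s2e <- error_variance(realized_sigma_a2(gv$values), h2plot)
  ph <- if (n_ph < n_train) sort(sample.int(n_train, n_ph)) else seq_len(n_train)
  valid <- n_train + seq_len(n_validation)
  Z <- marker_matrix(pop, arch)
  y <- simulate_entry_means(gv$values[ph], r, s2e)
  Zt <- Z[ph, , drop = FALSE]
  Zv <- Z[valid, , drop = FALSE]
  vapply(models, function(mdl) {
    fit <- fit_model(mdl, Zt, y, alpha, bayes)
    prediction_accuracy(predict(fit, Zv), gv$values[valid])
  }, numeric(1))
}

#' Cross-validation accuracy experiment
#'
#' For every cell of the `n` x `r` x `h2plot` grid, runs `n_replicates`
#' independent replicates. Each replicate simulates a fresh trait
#' architecture and a fresh DH population of `n + n_validation` lines from
#' one F1; the first `n` lines (or a random `n_ph` of them) are phenotyped
#' with entry means of `r` plots and used to train each requested model, and
#' accuracy is the correlation between GEBVs and true genetic values of the
#' `n_validation` held-out lines. The plot error variance is calibrated to
#' the realized genetic variance of each replicate's DH population.
#'
#' @param n vector of training-population sizes.
#' @param r vector of replication numbers.
#' @param h2plot vector of plot heritabilities.
#' @param models character vector among `"rrblup"`, `"bayescpi"`, `"ols"`;
#'   all models in a replicate are fitted to identical data.
#' @param n_replicates replicates per cell (default 200).
#' @param n_validation validation-set size (default 500).
#' @param seed master seed; child seeds are derived per replicate.
#' @param alpha stepwise-OLS entry/removal threshold.
#' @param genome a `gs_genome` (default: the maize-like 10 x 179.6 cM map).
#' @param n_qtl,n_markers trait architecture dimensions.
#' @param n_ph number of phenotyped lines (default: all `n`); scalar or one
#'   value per element of `n`.
#' @param bayes list of extra arguments for [fit_bayescpi()].
#' @param keep_replicates if `TRUE`, per-replicate accuracies are returned.
#' @return list of class `gs_result`: `summary` (data frame with one row per
#'   cell x model: `model, n, n_ph, r, h2plot, mean, se, n_reps`),
#'   `replicates` (when kept: list of replicate-by-model matrices), and
#'   `seeds` (the matrix of child seeds, cells x replicates).
#' @export
run_cross_validation <- function(n, r, h2plot, models = "rrblup",
                                 n_replicates = 200, n_validation = 500,
                                 seed = 1, alpha = 0.2,
                                 genome = build_genome(), n_qtl = 100,
                                 n_markers = 200, n_ph = NULL, bayes = list(),
                                 keep_replicates = FALSE) {
  stopifnot(n_replicates >= 2, all(n >= 3))
  grid <- expand.grid(n = n, r = r, h2plot = h2plot,
                      KEEP.OUT.ATTRS = FALSE)
  if (is.null(n_ph)) {
    grid$n_ph <- grid$n
  } else {
    stopifnot(length(n_ph) %in% c(1L, length(n)))
    grid$n_ph <- rep(n_ph, length.out = length(n))[match(grid$n, n)]
  }
  seeds <- matrix(child_seeds(seed, nrow(grid) * n_replicates),
                  nrow(grid), n_replicates)
  reps <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    acc <- matrix(NA_real_, n_replicates, length(models),
                  dimnames = list(NULL, models))
    for (k in seq_len(n_replicates)) {
      set.seed(seeds[i, k])
      acc[k, ] <- cv_replicate(genome, grid$n[i], grid$n_ph[i], grid$r[i],
                               grid$h2plot[i], models, n_validation, alpha,
                               n_qtl, n_markers, bayes)
    }
    reps[[i]] <- acc
    s <- summarize_replicates(acc)
    rows[[i]] <- data.frame(model = models, n = grid$n[i], n_ph = grid$n_ph[i],
                            r = grid$r[i], h2plot = grid$h2plot[i],
                            mean = s$mean, se = s$se, n_reps = n_replicates,
                            row.names = NULL)
  }
  structure(list(summary = do.call(rbind, rows),
                 replicates = if (keep_replicates) reps else NULL,
                 seeds = seeds),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat("<gs_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Budget tradeoff grid
#'
#' Evaluates every `(B, C, r)` cell at fixed phenotyped fraction `F`: the
#' budget identity of [allocate()] sets the population size and the number of
#' phenotyped lines, and the cell is scored by cross-validation as in
#' [run_cross_validation()]. Cells whose population size falls below `min_n`
#' are skipped with a warning.
#'
#' @inheritParams run_cross_validation
#' @inheritParams allocate
#' @param B,C,r vectors defining the grid.
#' @param F phenotyped fraction, fixed for the run.
#' @param min_n smallest admissible population size (default 10).
#' @return a `gs_result`; the summary gains columns `B`, `C`, `F`.
#' @export
run_budget_grid <- function(B, C, F = 1, r = 1:4, h2plot, models = "rrblup",
                            n_replicates = 200, n_validation = 500, seed = 1,
                            alpha = 0.2, genome = build_genome(), n_qtl = 100,
                            n_markers = 200, min_n = 10, bayes = list(),
                            keep_replicates = FALSE) {
  cells <- expand.grid(r = r, C = C, B = B, h2plot = h2plot,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  reps <- list()
  for (i in seq_len(nrow(cells))) {
    al <- allocate(cells$B[i], cells$C[i], F, cells$r[i])
    if (al$n < min_n || al$n_ph < 3) {
      warning(sprintf("skipping cell B=%g C=%g r=%d: n=%d below minimum",
                      cells$B[i], cells$C[i], cells$r[i], al$n))
      next
    }
    res <- run_cross_validation(al$n, cells$r[i], cells$h2plot[i], models,
                                n_replicates, n_validation,
                                seed = seed + i, alpha = alpha,
                                genome = genome, n_qtl = n_qtl,
                                n_markers = n_markers, n_ph = al$n_ph,
                                bayes = bayes,
                                keep_replicates = keep_replicates)
    s <- res$summary
    s$B <- cells$B[i]; s$C <- cells$C[i]; s$F <- F
    out[[i]] <- s
    if (keep_replicates) reps[[length(reps) + 1L]] <- res$replicates[[1]]
  }
  structure(list(summary = do.call(rbind, out),
                 replicates = if (keep_replicates) reps else NULL),
            class = "gs_result")
}

#' Theory versus simulation comparison
#'
#' Runs the RR-BLUP cross-validation grid and sets the deterministic expected
#' accuracy (adjusted form, `me` effective loci, entry-mean heritability)
#' alongside each simulated mean, reporting the per-`r` average excess of
#' theory over observation.
#'
#' @inheritParams run_cross_validation
#' @param me effective number of loci used in the theoretical formula
#'   (default 27.96; the theory column is deterministic and seed-free).
#' @return list of class `gs_result` with `summary` (per-cell observed mean,
#'   `theory_unadjusted`, `theory_adjusted`, `excess = theory_adjusted -
#'   mean`) and `by_r` (average excess per replication number).
#' @export
compare_theory <- function(n, r, h2plot, me = 27.96, n_replicates = 200,
                           n_validation = 500, seed = 1,
                           genome = build_genome(), n_qtl = 100,
                           n_markers = 200, keep_replicates = FALSE) {
  res <- run_cross_validation(n, r, h2plot, "rrblup", n_replicates,
                              n_validation, seed, genome = genome,
                              n_qtl = n_qtl, n_markers = n_markers,
                              keep_replicates = keep_replicates)
  s <- res$summary
  acc <- expected_accuracy(s$n, entry_mean_h2(s$h2plot, s$r), me)
  s$theory_unadjusted <- acc$unadjusted
  s$theory_adjusted <- acc$adjusted
  s$excess <- s$theory_adjusted - s$mean
  by_r <- stats::aggregate(excess ~ r, data = s, FUN = mean)
  structure(list(summary = s, by_r = by_r, replicates = res$replicates),
            class = "gs_result")
}

#' Prediction-accuracy decay under random mating
#'
#' Trains a model on a cycle-0 DH population, then follows the population
#' through generations of random mating without selection (so allele
#' frequencies and genetic variance stay stable in expectation): the C0 DH
#' lines are mated to `n_f1` F1s, the F1s to `cycle_size` C1 S0 plants, and
#' each later cycle is random-mated from the previous one. The C0-trained
#' model is scored within every cycle.
#'
#' @inheritParams run_cross_validation
#' @param n C0 DH population size (training size; all lines phenotyped
#'   unless `n_ph` is given).
#' @param r replications for the C0 phenotypes.
#' @param n_f1 number of F1s bridging C0 and C1 (default 1000).
#' @param cycle_size size of each random-mating cycle (default 1000).
#' @param n_cycles number of random-mating cycles after C0 (default 3).
#' @return a `gs_result` whose summary has one row per model x cycle
#'   (cycle 0 = within the training DH lines).
#' @export
run_random_mating_decay <- function(n, r, h2plot, models = "rrblup",
                                    n_f1 = 1000, cycle_size = 1000,
                                    n_cycles = 3, n_replicates = 200,
                                    seed = 1, alpha = 0.2,
                                    genome = build_genome(), n_qtl = 100,
                                    n_markers = 200, n_ph = n,
                                    bayes = list(),
                                    keep_replicates = FALSE) {
  stopifnot(n_replicates >= 2, n >= 3, n_cycles >= 1)
  seeds <- child_seeds(seed, n_replicates)
  n_models <- length(models)
  acc <- array(NA_real_, c(n_replicates, n_cycles + 1, n_models),
               dimnames = list(NULL, paste0("cycle", 0:n_cycles), models))
  for (k in seq_len(n_replicates)) {
    set.seed(seeds[k])
    arch <- assign_architecture(genome, n_qtl, n_markers)
    pop0 <- make_dh_population(founder_f1(genome), n, genome)
    gv0 <- genetic_values(pop0, arch)
    s2e <- error_variance(realized_sigma_a2(gv0$values), h2plot)
    ph <- if (n_ph < n) sort(sample.int(n, n_ph)) else seq_len(n)
    Z0 <- marker_matrix(pop0, arch)
    y <- simulate_entry_means(gv0$values[ph], r, s2e)
    fits <- lapply(models, function(mdl)
      fit_model(mdl, Z0[ph, , drop = FALSE], y, alpha, bayes))
    for (j in seq_len(n_models))
      acc[k, 1, j] <- prediction_accuracy(predict(fits[[j]], Z0), gv0$values)
    f1s <- random_mate(pop0, n_f1, genome, "F1")
    pop <- random_mate(f1s, cycle_size, genome, "C1")
    for (cyc in seq_len(n_cycles)) {
      gv <- genetic_values(pop, arch)
      Zc <- marker_matrix(pop, arch)
      for (j in seq_len(n_models))
        acc[k, cyc + 1, j] <- prediction_accuracy(predict(fits[[j]], Zc),
                                                  gv$values)
      if (cyc < n_cycles)
        pop <- random_mate(pop, cycle_size, genome, paste0("C", cyc + 1))
    }
  }
  rows <- list()
  for (j in seq_len(n_models)) for (cyc in 0:n_cycles) {
    s <- summarize_replicates(acc[, cyc + 1, j])
    rows[[length(rows) + 1L]] <-
      data.frame(model = models[j], n = n, n_ph = n_ph, r = r,
                 h2plot = h2plot, cycle = cyc, mean = s$mean, se = s$se,
                 n_reps = n_replicates)
  }
  structure(list(summary = do.call(rbind, rows),
                 replicates = if (keep_replicates) acc else NULL,
                 seeds = seeds),
            class = "gs_result")
}

#' Recurrent genomic selection with genetic gain
#'
#' Simulates the marker-score recurrent selection scheme: a C0 DH population
#' of `n` lines is genotyped, `n_ph` of them are phenotyped with `r` plots,
#' and a model is trained once on C0. The top `n_sel0` of all `n` lines by
#' GEBV are selected and paired at random into `n_crosses` disjoint crosses;
#' the resulting F1s are randomly mated to `cycle_size` C1 S0 plants. In each
#' later cycle the C0-trained model picks the top `n_sel` plants, which are
#' randomly mated to form the next cycle. Per-cycle mean genetic values are
#' standardized by the C0 genetic standard deviation, so C0 sits at 0 by
#' construction. Selection in C0 uses marker scores only, never phenotypes.
#'
#' With `selection = "oracle"` the true genetic values replace GEBVs for
#' selection (an accuracy-1 upper bound); the model is still fitted and its
#' C0 accuracies are reported.
#'
#' @inheritParams run_random_mating_decay
#' @param model a single model name (default `"rrblup"`).
#' @param n_sel0 C0 selected count (default 10).
#' @param n_crosses number of C0 crosses (default `n_sel0 / 2`).
#' @param cycle_size progeny per cycle (default 200).
#' @param n_sel selected count in cycles 1+ (default 20).
#' @param selection `"gebv"` (default) or `"oracle"`.
#' @return a `gs_result`; metrics are `i` (C0 selection intensity,
#'   deterministic), `acc_phenotyped`, `acc_nonphenotyped` (`NA` when all
#'   lines are phenotyped), and `cycle<k>_mean` standardized gains.
#' @export
run_recurrent_selection <- function(n, n_ph = n, r, h2plot, model = "rrblup",
                                    n_sel0 = 10, n_crosses = n_sel0 %/% 2,
                                    cycle_size = 200, n_sel = 20,
                                    n_cycles = 3, n_replicates = 500,
                                    seed = 1, alpha = 0.2,
                                    genome = build_genome(), n_qtl = 100,
                                    n_markers = 200, bayes = list(),
                                    selection = c("gebv", "oracle"),
                                    keep_replicates = FALSE) {
  selection <- match.arg(selection)
  stopifnot(length(model) == 1, n_ph >= 3, n_sel0 >= 2 * n_crosses,
            n_replicates >= 2)
  seeds <- child_seeds(seed, n_replicates)
  metrics <- c("acc_phenotyped", "acc_nonphenotyped",
               paste0("cycle", seq_len(n_cycles), "_mean"))
  out <- matrix(NA_real_, n_replicates, length(metrics),
                dimnames = list(NULL, metrics))
  for (k in seq_len(n_replicates)) {
    set.seed(seeds[k])
    arch <- assign_architecture(genome, n_qtl, n_markers)
    pop0 <- make_dh_population(founder_f1(genome), n, genome)
    gv0 <- genetic_values(pop0, arch)
    s2e <- error_variance(realized_sigma_a2(gv0$values), h2plot)
    ph <- if (n_ph < n) sort(sample.int(n, n_ph)) else seq_len(n)
    Z0 <- marker_matrix(pop0, arch)
    y <- simulate_entry_means(gv0$values[ph], r, s2e)
    fit <- fit_model(model, Z0[ph, , drop = FALSE], y, alpha, bayes)
    gebv0 <- predict(fit, Z0)
    out[k, "acc_phenotyped"] <-
      prediction_accuracy(gebv0[ph], gv0$values[ph])
    if (n_ph < n) {
      nonph <- setdiff(seq_len(n), ph)
      out[k, "acc_nonphenotyped"] <-
        if (length(nonph) >= 3)
          prediction_accuracy(gebv0[nonph], gv0$values[nonph]) else NA_real_
    }
    score0 <- if (selection == "gebv") gebv0 else gv0$values
    sel <- order(score0, decreasing = TRUE)[seq_len(n_sel0)]
    perm <- sample(sel)  # random perfect matching into disjoint crosses
    f1s <- cross_pairs(pop0, perm[seq_len(n_crosses)],
                       perm[n_crosses + seq_len(n_crosses)], genome)
    sd0 <- sd(gv0$values)
    pop <- random_mate(f1s, cycle_size, genome, "C1")
    for (cyc in seq_len(n_cycles)) {
      gv <- genetic_values(pop, arch)
      out[k, paste0("cycle", cyc, "_mean")] <-
        (mean(gv$values) - mean(gv0$values)) / sd0
      if (cyc < n_cycles) {
        score <- if (selection == "gebv") predict(fit, marker_matrix(pop, arch))
                 else gv$values
        keep <- order(score, decreasing = TRUE)[seq_len(n_sel)]
        pop <- random_mate(subset_population(pop, keep), cycle_size, genome,
                           paste0("C", cyc + 1))
      }
    }
  }
  s <- summarize_replicates(out)
  summary <- data.frame(model = model, n = n, n_ph = n_ph, r = r,
                        h2plot = h2plot, i = selection_intensity(n_sel0 / n),
                        metric = metrics, mean = s$mean, se = s$se,
                        n_reps = n_replicates, row.names = NULL)
  structure(list(summary = summary,
                 replicates = if (keep_replicates) out else NULL,
                 seeds = seeds),
            class = "gs_result")
}

#' Genetic-gain grid over phenotyping strategies
#'
#' Runs [run_recurrent_selection()] for every `(F, r)` combination under a
#' budget, reproducing the layout of the published gain tables: the budget
#' identity sets `n` and `n_ph` per cell, and cells with fewer than `min_nph`
#' phenotyped lines are skipped with a warning.
#'
#' @inheritParams run_recurrent_selection
#' @inheritParams allocate
#' @param F vector of phenotyped fractions (default `c(0.5, 0.75, 1)`).
#' @param r vector of replication numbers (default `1:4`).
#' @param min_nph smallest admissible phenotyped count (default 10).
#' @return a `gs_result`; the summary gains columns `B`, `C`, `F`.
#' @export
run_gain_grid <- function(B, C, F = c(0.5, 0.75, 1), r = 1:4, h2plot,
                          model = "rrblup", n_replicates = 500, seed = 1,
                          genome = build_genome(), min_nph = 10, ...) {
  cells <- expand.grid(r = r, F = F, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    al <- allocate(B, C, cells$F[i], cells$r[i])
    if (al$n_ph < min_nph) {
      warning(sprintf("skipping cell F=%g r=%d: n_ph=%d below minimum",
                      cells$F[i], cells$r[i], al$n_ph))
      next
    }
    res <- run_recurrent_selection(al$n, al$n_ph, cells$r[i], h2plot, model,
                                   n_replicates = n_replicates,
                                   seed = seed + i, genome = genome, ...)
    s <- res$summary
    s$B <- B; s$C <- C; s$F <- cells$F[i]
    out[[i]] <- s
  }
  structure(list(summary = do.call(rbind, out)), class = "gs_result")
}

#' Mean and standard error over replicates
#'
#' @param x numeric vector, or a matrix / data frame with one row per
#'   replicate and one column per metric.
#' @return data frame with columns `metric`, `mean`, `se`
#'   (`sd / sqrt(n_reps)`), computed over non-missing replicates.
#' @export
summarize_replicates <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "value"))
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 replicates", call. = FALSE)
  mn <- apply(x, 2, mean, na.rm = TRUE)
  nn <- apply(!is.na(x), 2, sum)
  se <- apply(x, 2, sd, na.rm = TRUE) / sqrt(nn)
  se[nn < 2] <- NA_real_
  mn[nn == 0] <- NA_real_
  data.frame(metric = colnames(x), mean = unname(mn), se = unname(se),
             row.names = NULL)
}
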