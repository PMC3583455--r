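test_that("summarize_replicates gives means and standard errors", {
  s <- summarize_replicates(rep(0.7, 10))
  expect_equal(s$mean, 0.7)
  expect_equal(s$se, 0)
  s2 <- summarize_replicates(c(0, 1))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$se, 0.5)  # sample sd (n - 1) over sqrt(n)
  set.seed(60)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  s3 <- summarize_replicates(x)
  for (j in 1:2) {
    expect_equal(s3$mean[j], sum(x[, j]) / 20)
    expect_equal(s3$se[j], sqrt(sum((x[, j] - mean(x[, j]))^2) / 19) / sqrt(20))
  }
  expect_error(summarize_replicates(1), "2 replicates")
})

test_that("experiments are bit-reproducible under the master seed", {
  g <- small_genome()
  a <- run_cross_validation(n = 30, r = 1, h2plot = 0.5, n_replicates = 4,
                            n_validation = 50, seed = 99, genome = g,
                            n_qtl = 10, n_markers = 8)
  b <- run_cross_validation(n = 30, r = 1, h2plot = 0.5, n_replicates = 4,
                            n_validation = 50, seed = 99, genome = g,
                            n_qtl = 10, n_markers = 8)
  expect_identical(a$summary, b$summary)
  expect_identical(a$seeds, b$seeds)
  c <- run_cross_validation(n = 30, r = 1, h2plot = 0.5, n_replicates = 4,
                            n_validation = 50, seed = 100, genome = g,
                            n_qtl = 10, n_markers = 8)
  expect_false(identical(a$summary$mean, c$summary$mean))
})

test_that("cross-validation accuracy rises with training size at high heritability", {
  g <- small_genome(4, 60, 30)
  res <- run_cross_validation(n = c(20, 150), r = 1, h2plot = 1,
                              n_replicates = 8, n_validation = 80, seed = 61,
                              genome = g, n_qtl = 20, n_markers = 24)
  s <- res$summary
  expect_gt(s$mean[s$n == 150], s$mean[s$n == 20])
  expect_true(all(s$mean > 0 & s$mean < 1))
})

test_that("budget grid applies the allocation identity and skips tiny cells", {
  g <- small_genome()
  res <- run_budget_grid(B = 40, C = 0, F = 1, r = 1, h2plot = 0.8,
                         n_replicates = 3, n_validation = 30, seed = 62,
                         genome = g, n_qtl = 10, n_markers = 8)
  expect_equal(res$summary$n, 40)  # C = 0, F = 1, r = 1 gives n = B
  expect_warning(
    run_budget_grid(B = 40, C = 0, F = 1, r = c(1, 8), h2plot = 0.8,
                    n_replicates = 3, n_validation = 30, seed = 63,
                    genome = g, n_qtl = 10, n_markers = 8),
    "below minimum")
})

test_that("theory comparison attaches a deterministic theory column", {
  g <- small_genome()
  r1 <- compare_theory(n = c(30, 60), r = 1, h2plot = 0.5, me = 10,
                       n_replicates = 3, n_validation = 40, seed = 64,
                       genome = g, n_qtl = 10, n_markers = 8)
  r2 <- compare_theory(n = c(30, 60), r = 1, h2plot = 0.5, me = 10,
                       n_replicates = 3, n_validation = 40, seed = 999,
                       genome = g, n_qtl = 10, n_markers = 8)
  expect_identical(r1$summary$theory_adjusted, r2$summary$theory_adjusted)
  expect_equal(r1$summary$theory_adjusted,
               expected_accuracy(c(30, 60), 0.5, 10)$adjusted)
  expect_equal(r1$summary$excess,
               r1$summary$theory_adjusted - r1$summary$mean)
})

test_that("complete linkage keeps accuracy perfect across random-mating cycles", {
  g <- linked_genome(30)
  arch <- list(qtl_idx = c(2L, 9L, 20L), qtl_eff = c(1, 0.5, 0.25),
               marker_idx = c(5L, 15L, 25L))
  class(arch) <- "trait_arch"
  set.seed(65)
  pop0 <- make_dh_population(founder_f1(g), 30, g)
  gv0 <- genetic_values(pop0, arch)
  fit <- fit_rrblup(marker_matrix(pop0, arch),
                    simulate_entry_means(gv0$values, 1, 0.01))
  pop <- random_mate(pop0, 100, g)
  for (cyc in 1:3) {
    gv <- genetic_values(pop, arch)
    acc <- prediction_accuracy(predict(fit, marker_matrix(pop, arch)),
                               gv$values)
    expect_gt(acc, 0.999)
    pop <- random_mate(pop, 100, g)
  }
})

test_that("accuracy decays with generations of random mating", {
  g <- small_genome(4, 100, 40)
  res <- run_random_mating_decay(n = 80, r = 1, h2plot = 0.6,
                                 n_f1 = 150, cycle_size = 150,
                                 n_replicates = 25, seed = 66, genome = g,
                                 n_qtl = 30, n_markers = 24)
  s <- res$summary
  a1 <- s$mean[s$cycle == 1]; a3 <- s$mean[s$cycle == 3]
  se13 <- sqrt(s$se[s$cycle == 1]^2 + s$se[s$cycle == 3]^2)
  expect_gt(a1, a3 - 3 * se13)
  expect_gt(a1, 0.2)
})

test_that("recurrent selection produces positive standardized gain", {
  g <- small_genome(4, 100, 40)
  res <- run_recurrent_selection(n = 60, r = 1, h2plot = 0.6,
                                 n_sel0 = 10, cycle_size = 80, n_sel = 16,
                                 n_replicates = 15, seed = 67, genome = g,
                                 n_qtl = 30, n_markers = 24)
  s <- res$summary
  gains <- s$mean[grep("cycle", s$metric)]
  expect_true(all(gains > 0))
  expect_gt(gains[3], gains[1])  # gain accumulates over cycles
  expect_equal(unique(s$i), selection_intensity(10 / 60))
  # all lines phenotyped: no non-phenotyped accuracy is defined
  expect_true(is.na(s$mean[s$metric == "acc_nonphenotyped"]))
  expect_gt(s$mean[s$metric == "acc_phenotyped"], 0.3)
})

test_that("an oracle selector is at least as good as model-based selection", {
  g <- small_genome(4, 100, 40)
  args <- list(n = 60, r = 1, h2plot = 0.3, n_sel0 = 10, cycle_size = 80,
               n_sel = 16, n_replicates = 20, seed = 68, genome = g,
               n_qtl = 30, n_markers = 24, keep_replicates = TRUE)
  gebv <- do.call(run_recurrent_selection, c(args, selection = "gebv"))
  orac <- do.call(run_recurrent_selection, c(args, selection = "oracle"))
  d <- orac$replicates[, "cycle3_mean"] - gebv$replicates[, "cycle3_mean"]
  expect_gt(mean(d), -3 * sd(d) / sqrt(length(d)))
})

test_that("phenotyped lines are predicted better than non-phenotyped lines", {
  g <- small_genome(4, 100, 40)
  res <- run_recurrent_selection(n = 80, n_ph = 40, r = 1, h2plot = 0.6,
                                 n_sel0 = 10, cycle_size = 60, n_sel = 12,
                                 n_replicates = 25, seed = 69, genome = g,
                                 n_qtl = 30, n_markers = 24)
  s <- res$summary
  expect_gt(s$mean[s$metric == "acc_phenotyped"],
            s$mean[s$metric == "acc_nonphenotyped"])
})
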