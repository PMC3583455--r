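test_that("build_genome lays out evenly spaced loci and validates input", {
  g <- build_genome()
  expect_equal(g$n_chrom, 10)
  expect_equal(g$total_cM, 1796)
  expect_equal(g$n_loci, 5000)
  expect_true(all(g$lengths_cM > 0))

  g1 <- build_genome(1, 100, 2)
  expect_equal(g1$n_loci, 2)
  expect_equal(g1$loci$pos_cM, c(50, 100))

  g2 <- build_genome(2, c(50, 50), 10)
  expect_equal(g2$n_loci, 20)
  for (c in 1:2) {
    p <- g2$loci$pos_cM[g2$loci$chrom == c]
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p <= 50))
  }

  expect_error(build_genome(2, c(50, -1), 10), "positive")
  expect_error(build_genome(1, 100, 1), "loci_per_chrom")
  expect_error(build_genome(0, numeric(0), 5), "n_chrom")
})

test_that("geometric_effects follows a^k with a = (l-1)/(l+1)", {
  expect_equal(geometric_effects(3), c(0.5, 0.25, 0.125))
  expect_equal(geometric_effects(2), c(1 / 3, 1 / 9))
  e100 <- geometric_effects(100)
  a <- 99 / 101
  expect_equal(e100[1], a, tolerance = 1e-12)
  expect_equal(e100[100], a^100, tolerance = 1e-12)
  expect_true(all(diff(e100) < 0))
  expect_true(all(e100 > 0 & e100 < 1))
  expect_error(geometric_effects(1), ">= 2")
})

test_that("assign_architecture gives disjoint marker/QTL sets with random phase", {
  g <- build_genome()
  set.seed(1)
  a <- assign_architecture(g, 100, 200)
  expect_length(a$qtl_idx, 100)
  expect_length(a$marker_idx, 200)
  expect_length(intersect(a$qtl_idx, a$marker_idx), 0)
  expect_false(anyDuplicated(a$qtl_idx) > 0)
  expect_false(anyDuplicated(a$marker_idx) > 0)
  expect_equal(as.vector(table(g$loci$chrom[a$marker_idx])), rep(20, 10))

  set.seed(2)
  b <- assign_architecture(g, 100, 200)
  expect_false(identical(a$qtl_idx, b$qtl_idx))

  # favorable allele goes to either parent with probability 1/2
  set.seed(3)
  n_pos <- replicate(400, sum(assign_architecture(small_genome(), 10, 8)$qtl_eff > 0))
  bt <- binom.test(sum(n_pos), 400 * 10, p = 0.5)
  expect_gt(bt$p.value, 1e-4)

  # uneven marker split distributes the remainder deterministically
  g3 <- build_genome(3, rep(50, 3), 20)
  m3 <- assign_architecture(g3, 5, 8)$marker_idx
  expect_equal(as.vector(table(g3$loci$chrom[m3])), c(3, 3, 2))

  expect_error(assign_architecture(small_genome(), 100, 200), "exceeds")
})

test_that("meiosis respects linkage: intact transmission without recombination", {
  g <- linked_genome()
  f1 <- founder_f1(g)
  set.seed(4)
  gam <- replicate(20, meiosis(f1, 1, g))
  expect_true(all(apply(gam, 2, function(x) all(x == 0) || all(x == 1))))

  # fully homozygous parent transmits its haplotype exactly
  g2 <- small_genome()
  set.seed(5)
  dh <- make_dh_population(founder_f1(g2), 3, g2)
  expect_equal(meiosis(dh, 2, g2), dh$hap1[, 2])
})

test_that("crossover counts are Poisson with mean = map length in Morgans", {
  g <- build_genome(1, 100, 200)
  f1 <- founder_f1(g)
  set.seed(6)
  pop <- make_dh_population(f1, 10000, g)
  # strand switches along the chromosome count crossovers between the first
  # and last locus (span 99.5 cM)
  switches <- colSums(abs(diff(pop$hap1)))
  lam <- (100 - 100 / 200) / 100
  expect_lt(abs(mean(switches) - lam), 4 * sqrt(lam / 10000))
  tb <- table(factor(pmin(switches, 4), levels = 0:4))
  pr <- dpois(0:3, lam); pr <- c(pr, 1 - sum(pr))
  gof <- suppressWarnings(chisq.test(as.vector(tb), p = pr))
  expect_gt(gof$p.value, 1e-3)
})

test_that("whole-genome crossover rate matches the 1796 cM map", {
  g <- build_genome()
  set.seed(7)
  pop <- make_dh_population(founder_f1(g), 4000, g)
  per_chrom <- sapply(seq_len(g$n_chrom), function(c) {
    rows <- (g$chrom_first[c] + 1):(g$chrom_last[c] + 1)
    colSums(abs(diff(pop$hap1[rows, ])))
  })
  total <- rowSums(per_chrom)
  # switches miss the 0.36 cM before each chromosome's first locus
  lam <- (1796 - sum(179.6 / 500)) / 100
  expect_lt(abs(mean(total) - 17.96), 4 * sqrt(lam / 4000) + (17.96 - lam))
})

test_that("recombination fractions follow Haldane's mapping function", {
  g <- build_genome(1, 100, 11)  # loci every 10 cM
  set.seed(8)
  pop <- make_dh_population(founder_f1(g), 6000, g)
  for (d_loci in c(1, 3)) {
    d_M <- d_loci * 10 / 100
    r_exp <- 0.5 * (1 - exp(-2 * d_M))
    rec <- mean(pop$hap1[1, ] != pop$hap1[1 + d_loci, ])
    expect_lt(abs(rec - r_exp), 4 * sqrt(r_exp * (1 - r_exp) / 6000))
  }
})

test_that("DH lines are homozygous with allele frequency 1/2 per locus", {
  g <- small_genome()
  set.seed(9)
  dh <- make_dh_population(founder_f1(g), 5000, g)
  expect_identical(dh$hap1, dh$hap2)
  freq <- rowMeans(dh$hap1)
  expect_lt(abs(mean(freq) - 0.5), 0.01)
  expect_true(all(freq > 0.4 & freq < 0.6))
  expect_error(make_dh_population(dh, 5, g), "heterozygous")
})

test_that("random mating crosses two distinct parents and preserves the mean", {
  g <- small_genome()
  # two fully inbred, fully polymorphic parents give all-heterozygous progeny
  parents <- structure(list(hap1 = cbind(rep(0L, g$n_loci), rep(1L, g$n_loci)),
                            hap2 = cbind(rep(0L, g$n_loci), rep(1L, g$n_loci)),
                            generation = "P"), class = "gs_population")
  set.seed(10)
  f1s <- random_mate(parents, 50, g)
  expect_true(all(f1s$hap1 + f1s$hap2 == 1L))
  expect_equal(n_ind(f1s), 50)

  # no selection: progeny mean genetic value is centered on the parent mean
  set.seed(11)
  arch <- assign_architecture(g, 10, 8)
  dh <- make_dh_population(founder_f1(g), 40, g)
  mu_p <- genetic_values(dh, arch)$mean
  diffs <- replicate(60, {
    prog <- random_mate(dh, 100, g)
    genetic_values(prog, arch)$mean - mu_p
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(60))

  one <- make_dh_population(founder_f1(g), 1, g)
  expect_error(random_mate(one, 10, g), "at least 2")
})

test_that("genetic values sum coded QTL dosages times effects", {
  g <- small_genome()
  set.seed(12)
  arch <- assign_architecture(g, 12, 10)
  f1 <- founder_f1(g)
  expect_equal(genetic_values(f1, arch)$values, 0)

  # a DH carrying the favorable allele everywhere scores the magnitude sum
  hap <- matrix(0L, g$n_loci, 1)
  hap[arch$qtl_idx[arch$qtl_eff > 0]] <- 1L
  best <- structure(list(hap1 = hap, hap2 = hap, generation = "DH"),
                    class = "gs_population")
  expect_equal(genetic_values(best, arch)$values, sum(abs(arch$qtl_eff)))

  # brute-force locus-by-locus oracle on a random DH
  set.seed(13)
  dh <- make_dh_population(f1, 5, g)
  a_oracle <- 0
  for (k in seq_along(arch$qtl_idx)) {
    j <- arch$qtl_idx[k]
    a_oracle <- a_oracle + (dh$hap1[j, 3] + dh$hap2[j, 3] - 1) * arch$qtl_eff[k]
  }
  expect_equal(genetic_values(dh, arch)$values[3], a_oracle)

  # linearity: scaling all effects scales every value exactly
  arch2 <- arch; arch2$qtl_eff <- 2.5 * arch$qtl_eff
  expect_equal(genetic_values(dh, arch2)$values,
               2.5 * genetic_values(dh, arch)$values)
})

test_that("marker matrix codes -1/0/+1 with DH column variance near 1", {
  g <- small_genome()
  set.seed(14)
  arch <- assign_architecture(g, 10, 8)
  expect_equal(as.vector(marker_matrix(founder_f1(g), arch)), rep(0L, 8))
  dh <- make_dh_population(founder_f1(g), 2000, g)
  Z <- marker_matrix(dh, arch)
  expect_true(all(Z %in% c(-1L, 1L)))
  expect_equal(dim(Z), c(2000, 8))
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 0.05)
  expect_lt(max(abs(colMeans(Z))), 0.1)
})

test_that("population export round-trips through tab-separated text", {
  g <- small_genome()
  set.seed(15)
  dh <- make_dh_population(founder_f1(g), 4, g)
  geno <- tempfile(fileext = ".tsv"); map <- tempfile(fileext = ".tsv")
  write_population(dh, g, geno, map)
  gt <- read.table(geno, header = TRUE)
  expect_equal(nrow(gt), g$n_loci)
  expect_equal(unname(as.matrix(gt[, -1])), unname(dh$hap1 + dh$hap2 - 1L))
  mp <- read.table(map, header = TRUE)
  expect_equal(mp$pos_cM, g$loci$pos_cM)
})
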