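# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# A small, fast genome for tests that do not depend on the maize-like map.
small_genome <- function(n_chrom = 2, len = 80, loci = 40) {
  build_genome(n_chrom, rep(len, n_chrom), loci)
}

# A genome with complete linkage: zero-length chromosomes mean meiosis passes
# a parental haplotype through intact. Constructed by editing the map
# directly because build_genome() rejects non-positive lengths by contract.
linked_genome <- function(n_loci = 30) {
  g <- build_genome(1, 100, n_loci)
  g$lengths_cM <- 0
  g$total_cM <- 0
  g$total_M <- 0
  g
}

# Random DH marker data with a known signal for model tests.
sim_marker_data <- function(n, m, effects = numeric(m), sd_e = 1, mu = 0) {
  Z <- matrix(sample(c(-1L, 1L), n * m, replace = TRUE), n, m)
  y <- mu + drop(Z %*% effects) + rnorm(n, 0, sd_e)
  list(Z = Z, y = y)
}

# Dense mixed-model-equation solve for ridge regression with an unpenalized
# intercept: independent oracle for fit_rrblup() at fixed lambda.
mme_ridge <- function(Z, y, lambda) {
  n <- nrow(Z); m <- ncol(Z)
  X <- cbind(rep(1, n))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, m)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  list(mu = sol[1], effects = sol[-1])
}

# Step-by-step re-implementation of the forward-backward stepwise rules using
# lm()/summary() p-values: the brute-force oracle for fit_ols_stepwise().
oracle_stepwise <- function(Z, y, alpha = 0.2) {
  n <- nrow(Z); m <- ncol(Z)
  inc <- integer(0)
  seen <- character(0)
  repeat {
    changed <- FALSE
    if (length(inc) < n - 2 && n - length(inc) - 2 >= 1) {
      cand <- setdiff(seq_len(m), inc)
      p <- vapply(cand, function(j) {
        d <- as.data.frame(Z[, c(inc, j), drop = FALSE])
        cf <- summary(lm(y ~ ., data = cbind(y = y, d)))$coefficients
        if (nrow(cf) < length(inc) + 2) return(Inf)  # collinear: dropped by lm
        cf[nrow(cf), 4]
      }, numeric(1))
      b <- which.min(p)
      if (is.finite(p[b]) && p[b] <= alpha) {
        inc <- c(inc, cand[b]); changed <- TRUE
      }
    }
    repeat {
      if (length(inc) == 0) break
      d <- as.data.frame(Z[, inc, drop = FALSE])
      pv <- summary(lm(y ~ ., data = cbind(y = y, d)))$coefficients[-1, 4]
      w <- which.max(pv)
      if (pv[w] <= alpha) break
      inc <- inc[-w]; changed <- TRUE
    }
    if (!changed) break
    st <- paste(sort(inc), collapse = ",")
    if (st %in% seen) break
    seen <- c(seen, st)
  }
  sort(inc)
}

# The 48 printed (n, n_ph) allocation cells: budgets 250 and 500, genotyping
# costs 0.5 and 1, phenotyped fractions 0.5/0.75/1, replications 1-4.
printed_allocations <- function() {
  txt <- "
B C F r n n_ph
250 0.5 0.50 1 250 125
250 0.5 0.50 2 167 84
250 0.5 0.50 3 125 62
250 0.5 0.50 4 100 50
250 0.5 0.75 1 200 150
250 0.5 0.75 2 125 94
250 0.5 0.75 3 91 68
250 0.5 0.75 4 71 53
250 0.5 1.00 1 167 167
250 0.5 1.00 2 100 100
250 0.5 1.00 3 71 71
250 0.5 1.00 4 56 56
250 1.0 0.50 1 167 84
250 1.0 0.50 2 125 62
250 1.0 0.50 3 100 50
250 1.0 0.50 4 83 42
250 1.0 0.75 1 143 107
250 1.0 0.75 2 100 75
250 1.0 0.75 3 77 58
250 1.0 0.75 4 62 46
250 1.0 1.00 1 125 125
250 1.0 1.00 2 83 83
250 1.0 1.00 3 62 62
250 1.0 1.00 4 50 50
500 0.5 0.50 1 500 250
500 0.5 0.50 2 333 166
500 0.5 0.50 3 250 125
500 0.5 0.50 4 200 100
500 0.5 0.75 1 400 300
500 0.5 0.75 2 250 188
500 0.5 0.75 3 182 136
500 0.5 0.75 4 143 107
500 0.5 1.00 1 333 333
500 0.5 1.00 2 200 200
500 0.5 1.00 3 143 143
500 0.5 1.00 4 111 111
500 1.0 0.50 1 333 166
500 1.0 0.50 2 250 125
500 1.0 0.50 3 200 100
500 1.0 0.50 4 167 84
500 1.0 0.75 1 286 214
500 1.0 0.75 2 200 150
500 1.0 0.75 3 154 116
500 1.0 0.75 4 125 94
500 1.0 1.00 1 250 250
500 1.0 1.00 2 167 167
500 1.0 1.00 3 125 125
500 1.0 1.00 4 100 100"
  read.table(text = txt, header = TRUE)
}

# The published optimal-strategy table: theoretical column of the
# budget/cost/heritability comparison.
printed_theory_optima <- function() {
  txt <- "
B C h2plot strategy
250 0.0 0.2 250:1
250 0.5 0.2 100:2
250 1.0 0.2 83:2
250 0.0 0.6 250:1
250 0.5 0.6 167:1
250 1.0 0.6 125:1
500 0.0 0.2 500:1
500 0.5 0.2 200:2
500 1.0 0.2 167:2
500 0.0 0.6 500:1
500 0.5 0.6 333:1
500 1.0 0.6 250:1"
  read.table(text = txt, header = TRUE, colClasses = c(rep(NA, 3), "character"))
}
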