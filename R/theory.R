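#' Effective number of chromosome segments for a biparental DH family
#'
#' For DH lines derived from a single F1, the number of independently
#' segregating chromosome segments equals the haploid chromosome number plus
#' the expected number of crossovers, which is the genome length in Morgans.
#' The real-valued quantity is what enters the accuracy formulas; an integer
#' value rounded for reporting is returned alongside.
#'
#' @param genome a `gs_genome`.
#' @return list with `me` (real-valued) and `rounded`.
#' @examples
#' effective_loci(build_genome())  # 27.96, reported as 28
#' @export
effective_loci <- function(genome) {
  stopifnot(inherits(genome, "gs_genome"))
  me <- genome$n_chrom + genome$total_M
  list(me = me, rounded = as.integer(round(me)))
}

#' Entry-mean heritability after averaging r plots
#'
#' Averaging `r` plots divides the plot error variance by `r`, so the
#' heritability on an entry-mean basis is
#' `h2 = r h2plot / (r h2plot + 1 - h2plot)`.
#'
#' @param h2plot plot-basis heritability in (0, 1].
#' @param r number of replications (>= 1).
#' @return entry-mean heritability.
#' @export
entry_mean_h2 <- function(h2plot, r) {
  stopifnot(all(h2plot > 0 & h2plot <= 1), all(r >= 1))
  r * h2plot / (r * h2plot + 1 - h2plot)
}

#' Expected genomic prediction accuracy
#'
#' Deterministic expected accuracy of GEBVs for a training population of `n`
#' phenotyped individuals with entry-mean heritability `h2` and `me`
#' effective loci. The unadjusted form is `sqrt(lambda / (lambda + 1))` with
#' `lambda = n h2 / me`. The adjusted form subtracts the approximate
#' correction `0.5 raa^4 / lambda` from the squared accuracy before taking
#' the square root, accounting for all loci being fitted simultaneously
#' rather than one at a time; it simplifies to
#' `adjusted^2 = lambda (lambda + 0.5) / (1 + lambda)^2`, which is always
#' nonnegative and below the unadjusted value.
#'
#' @param n training-population size (>= 0; returns 0 at `n = 0`).
#' @param h2 entry-mean heritability in `[0, 1]`.
#' @param me effective number of loci (> 0).
#' @return list with `unadjusted` and `adjusted` accuracies.
#' @export
expected_accuracy <- function(n, h2, me) {
  stopifnot(all(n >= 0), all(h2 >= 0 & h2 <= 1), all(me > 0))
  lambda <- n * h2 / me
  r2 <- lambda / (lambda + 1)
  adj2 <- lambda * (lambda + 0.5) / (1 + lambda)^2
  list(unadjusted = sqrt(r2), adjusted = sqrt(adj2))
}

#' Standardized selection intensity under truncation selection
#'
#' Mean superiority, in phenotypic standard deviations, of the selected
#' fraction `p` of an infinite normal population:
#' `i = dnorm(qnorm(1 - p)) / p`, with `i = 0` when everything is selected.
#' The infinite-population formula is used without finite-sample
#' (order-statistic) correction, matching the intensities printed in the
#' allocation tables (e.g. `p = 10/250` gives 2.15 where the corrected value
#' would be about 2.13).
#'
#' @param p selected proportion in (0, 1].
#' @return selection intensity (>= 0).
#' @examples
#' selection_intensity(10 / 250)  # 2.15
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]", call. = FALSE)
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Expected response to selection
#'
#' The breeder's equation `R = i * rA * sigma_A`: selection intensity times
#' prediction accuracy times additive genetic standard deviation.
#'
#' @param i selection intensity.
#' @param rA prediction accuracy.
#' @param sigma_A additive genetic standard deviation (>= 0).
#' @return expected response, in trait units.
#' @export
expected_response <- function(i, rA, sigma_A) {
  stopifnot(all(sigma_A >= 0))
  i * rA * sigma_A
}

#' Theoretically optimal allocation of a plot budget
#'
#' For each candidate replication number, computes the population size
#' affordable under the budget identity `n = B / (C + r F)`, the entry-mean
#' heritability, and the expected accuracy, and returns the strategy with the
#' greatest expected accuracy. The ranking evaluates the continuous budget
#' tradeoff (unrounded `n`); integer `n` from [allocate()] is reported for
#' display. Strategies whose expected accuracies tie to within `1e-9` are
#' resolved toward greater replication (several budget scenarios produce
#' exact mathematical ties between `r = 1` and `r = 2`, and the more
#' replicated design is preferred for its higher per-entry precision). Both
#' the unadjusted and adjusted accuracy columns are reported; the ranking
#' criterion is selectable.
#'
#' @inheritParams allocate
#' @param h2plot plot-basis heritability.
#' @param r_candidates integer vector of replication numbers to compare.
#' @param me effective number of loci (default: the 10-chromosome, 1796-cM
#'   genome's 27.96).
#' @param criterion rank by `"unadjusted"` (default) or `"adjusted"` expected
#'   accuracy.
#' @return list with `best_r`, `best_n` (rounded), `strategy` (a string
#'   `"n:r"`), and `table`, a data frame with one row per candidate
#'   (`B, C, F, h2plot, r, n, n_ph, h2_entry, raa_eq2, raa_eq3, is_optimal`).
#' @export
optimal_allocation <- function(B, C, F = 1, h2plot, r_candidates = 1:4,
                               me = 27.96,
                               criterion = c("unadjusted", "adjusted")) {
  criterion <- match.arg(criterion)
  if (length(r_candidates) < 1) stop("empty candidate set", call. = FALSE)
  r_candidates <- sort(as.integer(r_candidates))
  rows <- lapply(r_candidates, function(r) {
    al <- allocate(B, C, F, r)
    n_raw <- B / (C + r * F)
    h2 <- entry_mean_h2(h2plot, r)
    acc <- expected_accuracy(n_raw, h2, me)
    data.frame(B = B, C = C, F = F, h2plot = h2plot, r = r,
               n = al$n, n_ph = al$n_ph, h2_entry = h2,
               raa_eq2 = acc$unadjusted, raa_eq3 = acc$adjusted)
  })
  tab <- do.call(rbind, rows)
  score <- if (criterion == "unadjusted") tab$raa_eq2 else tab$raa_eq3
  tied <- abs(score - max(score)) <= 1e-9
  best <- max(which(tied))  # ties toward larger r
  tab$is_optimal <- seq_len(nrow(tab)) == best
  list(best_r = tab$r[best], best_n = tab$n[best],
       strategy = paste0(tab$n[best], ":", tab$r[best]), table = tab)
}

#' Theoretical optimal-allocation grid
#'
#' Convenience wrapper evaluating [optimal_allocation()] over a grid of
#' budgets, genotyping costs, and plot heritabilities, returning one tidy
#' row per candidate strategy.
#'
#' @param B,C,h2plot vectors defining the grid.
#' @inheritParams optimal_allocation
#' @return data frame with the same columns as `optimal_allocation()$table`.
#' @export
theory_allocation_grid <- function(B = c(250, 500), C = c(0, 0.5, 1),
                                   h2plot = c(0.2, 0.6), F = 1,
                                   r_candidates = 1:4, me = 27.96,
                                   criterion = "unadjusted") {
  grid <- expand.grid(h2plot = h2plot, C = C, B = B)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    optimal_allocation(grid$B[i], grid$C[i], F, grid$h2plot[i],
                       r_candidates, me, criterion)$table
  })
  do.call(rbind, out)
}
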