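#' Plot error variance for a target plot heritability
#'
#' Solves `h2plot = sigma_a2 / (sigma_a2 + sigma_e2)` for the environmental
#' variance of a single plot: `sigma_e2 = sigma_a2 / h2plot - sigma_a2`.
#'
#' @param sigma_a2 additive genetic variance (> 0).
#' @param h2plot heritability of single-plot measurements, in (0, 1].
#' @return the plot error variance.
#' @examples
#' error_variance(1, 0.5)  # 1
#' error_variance(24, 0.6) # 16
#' @export
error_variance <- function(sigma_a2, h2plot) {
  if (any(sigma_a2 <= 0)) stop("sigma_a2 must be > 0", call. = FALSE)
  if (any(h2plot <= 0 | h2plot > 1))
    stop("h2plot must be in (0, 1]", call. = FALSE)
  sigma_a2 * (1 / h2plot - 1)
}

#' Simulate replicated plot phenotypes and entry means
#'
#' Each individual is observed in `r` plots; a plot value is the true genetic
#' value plus an independent normal deviation with variance `sigma_e2`, and
#' the entry mean is the average of the `r` plots. Entry-mean error variance
#' is therefore `sigma_e2 / r`.
#'
#' @param values numeric vector of true genetic values.
#' @param r number of replications (plots per entry, >= 1).
#' @param sigma_e2 plot error variance (>= 0).
#' @return numeric vector of entry means, same length as `values`.
#' @export
simulate_entry_means <- function(values, r, sigma_e2) {
  stopifnot(r >= 1, sigma_e2 >= 0)
  r <- as.integer(r)
  n <- length(values)
  if (sigma_e2 == 0) return(as.numeric(values))
  plots <- matrix(rnorm(n * r, sd = sqrt(sigma_e2)), n, r)
  as.numeric(values) + rowMeans(plots)
}

#' Budget-constrained resource allocation
#'
#' Under a budget of `B` field-plot equivalents, genotyping cost `C` per line
#' (plot equivalents), phenotyped fraction `F`, and `r` replications, the
#' number of lines genotyped is `n = B / (C + r F)` and the number phenotyped
#' is `n_ph = F n`, both rounded half-to-even (the convention that reproduces
#' the published allocation tables, e.g. `0.5 * 167 -> 84` but
#' `0.5 * 333 -> 166`). After rounding, `n (C + r F)` may exceed `B` by less
#' than one plot equivalent.
#'
#' @param B budget in field-plot equivalents (> 0).
#' @param C genotyping cost per line in plot equivalents (>= 0).
#' @param F fraction of genotyped lines that are phenotyped, in (0, 1].
#' @param r number of replications (>= 1).
#' @return An object of class `gs_allocation`: list with `B`, `C`, `F`, `r`,
#'   `n` (lines genotyped), and `n_ph` (lines phenotyped).
#' @examples
#' allocate(250, 0.5, 0.75, 3)  # n = 91, n_ph = 68
#' @export
allocate <- function(B, C, F, r) {
  if (B <= 0) stop("B must be > 0", call. = FALSE)
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  if (F <= 0 || F > 1) stop("F must be in (0, 1]", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  if (C + r * F <= 0) stop("C + r * F must be > 0", call. = FALSE)
  n <- as.integer(round(B / (C + r * F)))
  n_ph <- as.integer(round(F * n))
  structure(list(B = B, C = C, F = F, r = r, n = n, n_ph = n_ph),
            class = "gs_allocation")
}

#' @export
print.gs_allocation <- function(x, ...) {
  cat(sprintf("<gs_allocation> B=%g C=%g F=%g r=%d -> n=%d, n_ph=%d\n",
              x$B, x$C, x$F, as.integer(x$r), x$n, x$n_ph))
  invisible(x)
}

#' Realized additive genetic variance of a population
#'
#' Sample variance (denominator n - 1) of the true genetic values. Used to
#' calibrate the plot error variance so that the target plot heritability
#' holds for the simulated base population actually drawn, rather than for a
#' nominal variance that linkage between QTL would distort.
#'
#' @param values numeric vector of true genetic values (length >= 2).
#' @return the sample variance.
#' @export
realized_sigma_a2 <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 individuals to estimate a variance", call. = FALSE)
  var(values)
}
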