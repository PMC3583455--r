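#' Ridge-regression BLUP of marker effects
#'
#' Fits the entry-mean model `y = mu + Z u + e` with `u ~ N(0, sigma_u2 I)`
#' and `e ~ N(0, sigma_e2 I)`. The variance ratio `lambda = sigma_e2 /
#' sigma_u2` is estimated by restricted maximum likelihood (default) or
#' maximum likelihood using a one-time spectral decomposition: after
#' projecting out the intercept, a single SVD of the centered marker matrix
#' reduces each likelihood evaluation to O(n), so the 1-D optimization over
#' `lambda` is cheap. Effects are then the usual ridge/BLUP solutions
#' `u = (Z'Z + lambda I)^-1 Z'y` on centered data.
#'
#' With constant phenotypes the fit degenerates gracefully: all effects are 0
#' and the intercept equals the common value.
#'
#' @param Z marker matrix (individuals x markers, codes -1/0/+1).
#' @param y entry means, one per row of `Z`.
#' @param lambda optional fixed variance ratio; when supplied no likelihood
#'   optimization is performed (useful for oracle checks).
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `gs_fit` with elements `method` (`"rrblup"`),
#'   `mu`, `effects`, `lambda`, `sigma_u2`, `sigma_e2`.
#' @export
fit_rrblup <- function(Z, y, lambda = NULL, method = c("REML", "ML")) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)", call. = FALSE)
  if (n < 3) stop("need at least 3 training individuals", call. = FALSE)
  if (any(!is.finite(y))) stop("phenotypes must be finite", call. = FALSE)
  m <- ncol(Z)

  ybar <- mean(y)
  yc <- y - ybar
  if (sum(yc^2) == 0) {
    return(new_gs_fit("rrblup", mu = ybar, effects = numeric(m),
                      lambda = Inf, sigma_u2 = 0, sigma_e2 = 0))
  }
  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2, zbar)

  sv <- svd(Zc)
  keep <- sv$d > max(sv$d) * 1e-10
  d2 <- sv$d[keep]^2
  uty <- drop(crossprod(sv$u[, keep, drop = FALSE], yc))
  r2 <- max(0, sum(yc^2) - sum(uty^2))  # part of yc orthogonal to col(Zc)
  n_contrast <- n - 1                    # intercept projected out
  n_null <- n_contrast - length(d2)

  if (is.null(lambda)) {
    # profiled -2 log (restricted) likelihood as a function of log10(lambda)
    ss <- function(l) sum(uty^2 / (d2 + l)) + if (n_null > 0) r2 / l else 0
    dfree <- if (method == "REML") n_contrast else n
    crit <- function(log10l) {
      l <- 10^log10l
      v <- dfree * log(ss(l)) + sum(log(d2 + l)) + n_null * log(l)
      if (method == "ML") v <- v + log(l)  # eigen-direction of the intercept
      v
    }
    grid <- seq(-8, 8, by = 0.5)
    vals <- vapply(grid, crit, 0)
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    lambda <- 10^optimize(crit, c(lo, hi))$minimum
  }

  coef_d <- sv$d[keep] / (d2 + lambda)
  effects <- drop(sv$v[, keep, drop = FALSE] %*% (coef_d * uty))
  sigma_u2 <- (sum(uty^2 / (d2 + lambda)) +
                 if (n_null > 0) r2 / lambda else 0) / n_contrast
  new_gs_fit("rrblup", mu = ybar - sum(zbar * effects), effects = effects,
             lambda = lambda, sigma_u2 = sigma_u2,
             sigma_e2 = lambda * sigma_u2)
}

#' Forward-backward stepwise OLS marker selection
#'
#' Multiple-regression marker model selected by forward inclusion and
#' backward elimination on partial t-tests. In each forward round every
#' excluded marker is tested conditional on the current model; the smallest-p
#' candidate enters if its p-value is at most `alpha` (ties broken toward the
#' lowest marker index). After every entry, included markers whose refit
#' p-value exceeds `alpha` are removed, worst first. The algorithm iterates
#' to convergence; model size is capped at `n - 2` markers so at least one
#' residual degree of freedom remains. Final coefficients are ordinary least
#' squares on the selected markers; excluded markers get effect 0. An empty
#' final model is a valid fit.
#'
#' @inheritParams fit_rrblup
#' @param alpha p-value threshold for both entry and removal (default 0.20).
#' @return a `gs_fit` with `method = "ols"`, `mu`, `effects`, `included`
#'   (marker indices), and `p_values` for the included markers.
#' @export
fit_ols_stepwise <- function(Z, y, alpha = 0.20) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)", call. = FALSE)
  m <- ncol(Z)
  inc <- integer(0)
  max_size <- n - 2
  seen <- character(0)  # visited model states; a revisit means convergence

  repeat {
    changed <- FALSE

    # forward step: partial t-test of each candidate given the current model
    if (length(inc) < max_size && n - length(inc) - 2 >= 1) {
      X <- cbind(1, Z[, inc, drop = FALSE])
      Q <- qr.Q(qr(X))
      ry <- y - Q %*% crossprod(Q, y)
      cand <- setdiff(seq_len(m), inc)
      E <- Z[, cand, drop = FALSE]
      E <- E - Q %*% crossprod(Q, E)
      den <- colSums(E^2)
      num <- drop(crossprod(E, ry))
      df <- n - length(inc) - 2
      rss0 <- sum(ry^2)
      ok <- den > rss0 * 1e-12 + 1e-300
      p <- rep(Inf, length(cand))
      rss1 <- rss0 - num[ok]^2 / den[ok]
      tstat <- (num[ok] / den[ok]) / sqrt(pmax(rss1 / df, 0) / den[ok])
      p[ok] <- 2 * pt(-abs(tstat), df)
      best <- which.min(p)  # first minimum = lowest marker index on ties
      if (is.finite(p[best]) && p[best] <= alpha) {
        inc <- c(inc, cand[best])
        changed <- TRUE
      }
    }

    # backward step: drop included markers whose refit p exceeds alpha
    repeat {
      if (length(inc) == 0) break
      pv <- ols_pvalues(Z[, inc, drop = FALSE], y)
      worst <- which.max(pv)
      if (is.na(pv[worst]) || pv[worst] <= alpha) break
      inc <- inc[-worst]
      changed <- TRUE
    }

    if (!changed) break
    state <- paste(sort(inc), collapse = ",")
    if (state %in% seen) break  # add/drop cycle: model no longer evolves
    seen <- c(seen, state)
  }

  effects <- numeric(m)
  inc <- sort(inc)
  if (length(inc) > 0) {
    fit <- stats::lm.fit(cbind(1, Z[, inc, drop = FALSE]), y)
    effects[inc] <- fit$coefficients[-1]
    mu <- fit$coefficients[1]
    pv <- ols_pvalues(Z[, inc, drop = FALSE], y)
  } else {
    mu <- mean(y)
    pv <- numeric(0)
  }
  new_gs_fit("ols", mu = mu, effects = effects, included = inc, p_values = pv)
}

# t-test p-values of each marker coefficient in the OLS model y ~ 1 + Zsub
ols_pvalues <- function(Zsub, y) {
  n <- nrow(Zsub)
  X <- cbind(1, Zsub)
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  df <- n - ncol(X)
  if (df < 1) return(rep(NA_real_, ncol(Zsub)))
  s2 <- sum(res^2) / df
  XtXi <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtXi), 0) * s2)
  tt <- cf / se
  2 * pt(-abs(tt[-1]), df)
}

new_gs_fit <- function(method, mu, effects, ...) {
  structure(list(method = method, mu = mu, effects = as.numeric(effects), ...),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit> ", x$method, ", ", length(x$effects), " markers, ",
      sum(x$effects != 0), " nonzero effects\n", sep = "")
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' GEBVs are the sums of estimated marker effects over an individual's marker
#' genotype codes. The intercept is deliberately excluded: all downstream
#' accuracy measures are correlations, which an additive constant cannot
#' change.
#'
#' @param object a `gs_fit`.
#' @param Z marker matrix with one column per fitted effect.
#' @param ... unused.
#' @return numeric vector of GEBVs.
#' @export
predict.gs_fit <- function(object, Z, ...) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(object$effects))
    stop("marker matrix has ", ncol(Z), " columns but the fit has ",
         length(object$effects), " effects", call. = FALSE)
  drop(Z %*% object$effects)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and true genetic values. If either
#' vector has zero variance the accuracy is undefined and `NA` is returned
#' with a warning, so the caller can distinguish this from a numeric result.
#'
#' @param gebv,values numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
prediction_accuracy <- function(gebv, values) {
  if (length(gebv) != length(values) || length(gebv) < 3)
    stop("gebv and values must have equal length >= 3", call. = FALSE)
  if (sd(gebv) == 0 || sd(values) == 0) {
    warning("undefined accuracy: zero variance in gebv or values")
    return(NA_real_)
  }
  cor(gebv, values)
}
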