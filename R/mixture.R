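#' Probability-density histogram of FRET-efficiency values
#'
#' Histograms are normalized so that the sum of (density x bin width)
#' equals 1, matching the probability-density convention of ensemble FE
#' plots. Values outside `range` (artifacts far outside the physical FE
#' interval) are excluded.
#'
#' @param fe numeric vector of FE values.
#' @param bin_width histogram bin width.
#' @param range numeric `c(lo, hi)`; values outside are dropped (default
#'   `c(-0.2, 1.2)`).
#' @return data.frame of class `fe_histogram` with columns `mid`, `density`,
#'   `count`; attribute `bin_width`.
#' @export
fe_histogram <- function(fe, bin_width = 0.02, range = c(-0.2, 1.2)) {
  fe <- fe[!is.na(fe) & fe >= range[1] & fe <= range[2]]
  if (length(fe) == 0) stop("at least one FE value is required")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (max(breaks) < range[2]) breaks <- c(breaks, max(breaks) + bin_width)
  h <- graphics::hist(fe, breaks = breaks, plot = FALSE)
  out <- data.frame(mid = h$mids, density = h$density, count = h$counts)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("fe_histogram", "data.frame")
  out
}

#' Fit a Gaussian mixture to FRET-efficiency values
#'
#' EM for a K-component normal mixture ("assuming a two-state model" /
#' "three-state model" ensemble fits). Initialization is deterministic
#' (quantile-spaced means), so the fit is reproducible for a given seed and
#' input; components are reported sorted by ascending mean. The compound
#' curve is the weight-summed component density.
#'
#' @param fe numeric FE values (needs `length(fe) >= 10 * K`).
#' @param K number of components.
#' @param seed integer seed (deterministic path; kept for API symmetry).
#' @param tol,max_iter EM stopping rule (log-likelihood improvement).
#' @param var_floor minimum component variance (collapse guard, warns).
#' @param range values outside are excluded before fitting.
#' @return object of class `fe_mixture`: `weights`, `means`, `sds`,
#'   `log_likelihood`, `ll_trace`, `n`.
#' @export
fit_mixture <- function(fe, K, seed = 1, tol = 1e-8, max_iter = 1000,
                        var_floor = 1e-4, range = c(-0.2, 1.2)) {
  fe <- fe[!is.na(fe) & fe >= range[1] & fe <= range[2]]
  n <- length(fe)
  if (n < 10 * K)
    stop(sprintf("need at least %d values for K = %d (got %d)", 10 * K, K, n))
  if (K == 1) {
    sd1 <- stats::sd(fe) * sqrt((n - 1) / n)  # ML estimate
    ll <- sum(stats::dnorm(fe, mean(fe), sd1, log = TRUE))
    return(structure(list(weights = 1, means = mean(fe), sds = sd1,
                          log_likelihood = ll, ll_trace = ll, n = n),
                     class = "fe_mixture"))
  }
  probs <- seq(0.5 / K, 1 - 0.5 / K, length.out = K)
  means <- as.numeric(stats::quantile(fe, probs))
  if (anyDuplicated(means)) {
    set.seed(seed)
    means <- means + stats::rnorm(K, 0, 1e-3)
  }
  sds <- rep(max(stats::sd(fe) / K, sqrt(var_floor)), K)
  weights <- rep(1 / K, K)
  floored <- FALSE
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      weights[k] * stats::dnorm(fe, means[k], sds[k]), numeric(n))
    tot <- rowSums(dens)
    tot <- pmax(tot, 1e-300)
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    weights <- nk / n
    means <- colSums(resp * fe) / nk
    vars <- colSums(resp * (outer(fe, means, "-")^2)) / nk
    if (any(vars < var_floor)) floored <- TRUE
    sds <- sqrt(pmax(vars, var_floor))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  if (floored)
    warning(sprintf("component variance floored at %g", var_floor))
  ord <- order(means)
  structure(list(weights = weights[ord], means = means[ord], sds = sds[ord],
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, n = n),
            class = "fe_mixture")
}

#' @export
print.fe_mixture <- function(x, ...) {
  cat(sprintf("<fe_mixture> %d components, n = %d, logL = %.2f\n",
              length(x$means), x$n, x$log_likelihood))
  for (k in seq_along(x$means))
    cat(sprintf("  w = %.3f, FE %.3f +- %.3f\n",
                x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

#' Mixture density curve
#' @param object an `fe_mixture`.
#' @param x FE values at which to evaluate.
#' @param component `NULL` for the compound (weighted sum) curve, or a
#'   component index.
#' @return numeric densities.
#' @export
mixture_density <- function(object, x, component = NULL) {
  ks <- component %||% seq_along(object$means)
  rowSums(vapply(ks, function(k)
    object$weights[k] * stats::dnorm(x, object$means[k], object$sds[k]),
    numeric(length(x))))
}
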