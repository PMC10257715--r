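#' Fit an ensemble hidden Markov model to FRET-efficiency trajectories
#'
#' Maximum-likelihood Baum-Welch EM with Gaussian emissions. Emission and
#' transition parameters are shared across all trajectories; each trajectory
#' is treated as an independent sequence (no bridging across molecules).
#' Training stops when the per-frame log-likelihood improvement falls below
#' `tol` or after `max_iter` iterations; the log-likelihood is non-decreasing
#' at every iteration. States are reported sorted by ascending mean, with
#' the transition matrix and initial distribution permuted consistently.
#'
#' Initialization is deterministic: means at the (25, 75) percentiles of the
#' pooled data for `K = 2` or (15, 50, 85) for `K = 3`, SDs at half the
#' pooled sample SD, stay probability 0.95.
#'
#' @param fe list of numeric FE vectors (one per accepted trajectory), or a
#'   single numeric vector. `NA` frames are dropped.
#' @param K number of states (2 or 3 in practice; any K >= 1 works).
#' @param tol per-frame log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed (the fit itself is deterministic; kept for API
#'   symmetry with the stochastic stages).
#' @param var_floor minimum emission variance; components that collapse are
#'   floored here with a warning.
#' @param merge_frac states whose means are separated by less than
#'   `merge_frac` times the larger of their emission SDs do not represent
#'   distinguishable conformations; they are merged onto the
#'   higher-occupancy state (with a warning), so single-state data fed to a
#'   K = 2 model ends up occupying one state. Set to 0 to disable.
#' @return object of class `fret_hmm`: `K`, `means`, `sds`, `trans` (K x K
#'   per-frame transition probabilities, rows sum to 1), `init`,
#'   `log_likelihood`, `ll_trace`, `n_iter`.
#' @export
fit_hmm <- function(fe, K, tol = 1e-6, max_iter = 500, seed = 1,
                    var_floor = 1e-4, merge_frac = 1) {
  if (is.numeric(fe)) fe <- list(fe)
  fe <- lapply(fe, function(x) x[!is.na(x)])
  fe <- fe[vapply(fe, length, integer(1)) > 0]
  if (length(fe) == 0) stop("at least one non-empty trajectory is required")
  all_fe <- unlist(fe)
  n_total <- length(all_fe)
  probs <- switch(as.character(K), "1" = 0.5, "2" = c(0.25, 0.75),
                  "3" = c(0.15, 0.5, 0.85),
                  seq(0.1, 0.9, length.out = K))
  means <- as.numeric(stats::quantile(all_fe, probs))
  if (anyDuplicated(means)) {
    set.seed(seed)
    means <- means + stats::rnorm(K, 0, 1e-3)
  }
  sds <- rep(max(stats::sd(all_fe) / 2, sqrt(var_floor)), K)
  trans <- matrix(if (K > 1) 0.05 / (K - 1) else 0, K, K)
  diag(trans) <- if (K > 1) 0.95 else 1
  init <- rep(1 / K, K)
  floored <- FALSE

  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step: scaled forward-backward per sequence, pooled sufficient stats
    ll <- 0
    g_sum <- numeric(K)            # sum of gamma
    g_obs <- numeric(K)            # sum gamma * x
    g_obs2 <- numeric(K)           # sum gamma * x^2
    xi_sum <- matrix(0, K, K)
    init_sum <- numeric(K)
    for (x in fe) {
      T_len <- length(x)
      B <- matrix(0, T_len, K)
      for (k in seq_len(K))
        B[, k] <- stats::dnorm(x, means[k], sds[k])
      B <- pmax(B, 1e-300)
      alpha_m <- matrix(0, T_len, K)
      cvec <- numeric(T_len)
      a <- init * B[1, ]
      cvec[1] <- sum(a); alpha_m[1, ] <- a / cvec[1]
      if (T_len > 1) for (t in 2:T_len) {
        a <- (alpha_m[t - 1, ] %*% trans) * B[t, ]
        cvec[t] <- sum(a); alpha_m[t, ] <- a / cvec[t]
      }
      beta_m <- matrix(0, T_len, K)
      beta_m[T_len, ] <- 1
      if (T_len > 1) for (t in (T_len - 1):1) {
        b <- trans %*% (B[t + 1, ] * beta_m[t + 1, ])
        beta_m[t, ] <- as.numeric(b) / cvec[t + 1]
      }
      gam <- alpha_m * beta_m
      gam <- gam / rowSums(gam)
      ll <- ll + sum(log(cvec))
      g_sum <- g_sum + colSums(gam)
      g_obs <- g_obs + colSums(gam * x)
      g_obs2 <- g_obs2 + colSums(gam * x^2)
      init_sum <- init_sum + gam[1, ]
      if (T_len > 1) {
        # sum_t xi_t = trans * (alpha[t]' (B*beta/c)[t+1]) as one crossprod
        V <- (B * beta_m / cvec)[2:T_len, , drop = FALSE]
        U <- alpha_m[1:(T_len - 1), , drop = FALSE]
        xi_sum <- xi_sum + trans * crossprod(U, V)
      }
    }
    ll_trace <- c(ll_trace, ll)
    # M-step
    means <- g_obs / g_sum
    vars <- g_obs2 / g_sum - means^2
    if (any(vars < var_floor)) floored <- TRUE
    sds <- sqrt(pmax(vars, var_floor))
    if (K > 1 && sum(xi_sum) > 0) {
      trans <- xi_sum / rowSums(xi_sum)
      trans[!is.finite(trans)] <- 1 / K
    }
    init <- init_sum / sum(init_sum)
    if (is.finite(ll_old) && (ll - ll_old) / n_total < tol) break
    ll_old <- ll
  }
  if (floored)
    warning(sprintf("emission variance floored at %g (degenerate component)",
                    var_floor))
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]
  trans <- trans[ord, ord, drop = FALSE]; init <- init[ord]
  occupancy <- (g_sum / sum(g_sum))[ord]
  # states closer than their emission width are not distinguishable
  # conformations: collapse onto the higher-occupancy member
  if (K > 1 && merge_frac > 0) {
    merged <- FALSE
    for (k in seq_len(K - 1)) {
      if (means[k + 1] - means[k] <= merge_frac * max(sds[k], sds[k + 1])) {
        pair <- c(k, k + 1)
        w <- occupancy[pair] / sum(occupancy[pair])
        mu <- sum(w * means[pair])
        v <- sum(w * (sds[pair]^2 + means[pair]^2)) - mu^2
        means[pair] <- mu
        sds[pair] <- sqrt(max(v, var_floor))
        dom <- pair[which.max(occupancy[pair])]
        minor <- setdiff(pair, dom)
        init[dom] <- init[dom] + init[minor]; init[minor] <- 0
        trans[, dom] <- trans[, dom] + trans[, minor]; trans[, minor] <- 0
        trans[minor, ] <- 0; trans[minor, dom] <- 1
        occupancy[dom] <- sum(occupancy[pair]); occupancy[minor] <- 0
        merged <- TRUE
      }
    }
    if (merged)
      warning("indistinguishable states merged (mean separation below emission width)")
  }
  structure(list(K = K, means = means, sds = sds,
                 trans = trans, init = init, occupancy = occupancy,
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, n_iter = length(ll_trace)),
            class = "fret_hmm")
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat(sprintf("<fret_hmm> K = %d, logL = %.2f (%d EM iterations)\n",
              x$K, x$log_likelihood, x$n_iter))
  for (k in seq_len(x$K))
    cat(sprintf("  state %d: FE %.3f +- %.3f, stay prob %.4f\n",
                k, x$means[k], x$sds[k], x$trans[k, k]))
  invisible(x)
}

#' Most probable state path (Viterbi algorithm)
#'
#' Exact maximization of the joint state-sequence probability under a fitted
#' HMM, in log space.
#'
#' @param model a `fret_hmm` from [fit_hmm()].
#' @param fe numeric FE vector (`NA` frames dropped).
#' @return integer vector of state indices (1..K, states sorted by mean, so
#'   1 is the lowest-FE state); length 0 for an empty series.
#' @export
viterbi <- function(model, fe) {
  fe <- fe[!is.na(fe)]
  T_len <- length(fe)
  if (T_len == 0) return(integer(0))
  K <- model$K
  logB <- matrix(0, T_len, K)
  for (k in seq_len(K))
    logB[, k] <- stats::dnorm(fe, model$means[k], model$sds[k], log = TRUE)
  logA <- log(pmax(model$trans, 1e-300))
  delta <- matrix(-Inf, T_len, K)
  psi <- matrix(0L, T_len, K)
  delta[1, ] <- log(pmax(model$init, 1e-300)) + logB[1, ]
  if (T_len > 1) for (t in 2:T_len) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(T_len)
  path[T_len] <- which.max(delta[T_len, ])
  if (T_len > 1) for (t in (T_len - 1):1)
    path[t] <- psi[t + 1, path[t + 1]]
  path
}
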