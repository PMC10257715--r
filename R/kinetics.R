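#' Extract dwell times from state paths with censoring bookkeeping
#'
#' Maximal constant-state runs of each path become dwells with duration
#' (run length x FE-frame period). A dwell is uncensored only when both its
#' start and its end coincide with observed transitions: trajectory start,
#' movie end and photobleach truncation all censor. A trajectory with no
#' transitions therefore contributes only censored dwells and nothing to the
#' dwell fits.
#'
#' @param state_paths list of integer state vectors (one per trajectory,
#'   aligned to the truncated FE frames).
#' @param frame_period_s time between consecutive FE frames, s.
#' @param fe optional list of FE vectors (same shape) used to attach each
#'   dwell's mean FE (for transition-density coordinates).
#' @param molecule_ids optional identifiers.
#' @return data.frame of `dwell_record`s: `molecule_id`, `state`,
#'   `n_frames`, `duration_s`, `left_bounded_by_transition`,
#'   `right_bounded_by_transition`, `censored`, `mean_fe`.
#' @export
extract_dwells <- function(state_paths, frame_period_s, fe = NULL,
                           molecule_ids = seq_along(state_paths)) {
  if (!is.list(state_paths)) state_paths <- list(state_paths)
  rows <- vector("list", length(state_paths))
  for (i in seq_along(state_paths)) {
    s <- state_paths[[i]]
    if (length(s) == 0) next
    r <- rle(s)
    n_runs <- length(r$lengths)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    mean_fe <- rep(NA_real_, n_runs)
    if (!is.null(fe)) {
      x <- fe[[i]]
      mean_fe <- vapply(seq_len(n_runs), function(j)
        mean(x[starts[j]:ends[j]], na.rm = TRUE), numeric(1))
    }
    left <- seq_len(n_runs) > 1
    right <- seq_len(n_runs) < n_runs
    rows[[i]] <- data.frame(
      molecule_id = unname(molecule_ids[i]), state = r$values,
      n_frames = r$lengths, duration_s = r$lengths * frame_period_s,
      left_bounded_by_transition = left,
      right_bounded_by_transition = right,
      censored = !(left & right), mean_fe = mean_fe)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(molecule_id = integer(0), state = integer(0),
                      n_frames = integer(0), duration_s = numeric(0),
                      left_bounded_by_transition = logical(0),
                      right_bounded_by_transition = logical(0),
                      censored = logical(0), mean_fe = numeric(0))
  out
}

#' Exponential fit of uncensored dwell times for one state
#'
#' `tau_hat` is the sample mean of the uncensored dwells (the exponential
#' MLE); the 95% confidence interval is the exact chi-square interval
#' `[2 n tau / chisq(0.975, 2n), 2 n tau / chisq(0.025, 2n)]`.
#'
#' @param durations dwell durations, s. Pass only uncensored dwells (or a
#'   dwell table via [dwell_fits()], which selects them).
#' @param state optional state label carried into the result.
#' @param min_dwells fits with fewer uncensored dwells are refused.
#' @return list of class `dwell_fit`: `state`, `n_dwells`, `tau_hat`, `ci95`.
#' @export
fit_exponential <- function(durations, state = NA, min_dwells = 5) {
  durations <- durations[is.finite(durations) & durations > 0]
  n <- length(durations)
  if (n < min_dwells)
    stop(sprintf("need at least %d uncensored dwells, got %d", min_dwells, n))
  tau <- mean(durations)
  ci <- c(2 * n * tau / stats::qchisq(0.975, 2 * n),
          2 * n * tau / stats::qchisq(0.025, 2 * n))
  structure(list(state = state, n_dwells = n, tau_hat = tau,
                 ci95 = ci), class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> state %s: tau = %.3f s (95%% CI %.3f-%.3f, n = %d)\n",
              as.character(x$state), x$tau_hat, x$ci95[1], x$ci95[2],
              x$n_dwells))
  invisible(x)
}

#' Per-state exponential dwell fits from a dwell table
#' @param dwells a dwell table from [extract_dwells()].
#' @param min_dwells minimum uncensored dwells per state; states with fewer
#'   are skipped.
#' @return named list of `dwell_fit`s, one per state with enough dwells.
#' @export
dwell_fits <- function(dwells, min_dwells = 5) {
  unc <- dwells[!dwells$censored, , drop = FALSE]
  fits <- list()
  for (s in sort(unique(unc$state))) {
    d <- unc$duration_s[unc$state == s]
    if (length(d) >= min_dwells)
      fits[[as.character(s)]] <- fit_exponential(d, state = s,
                                                 min_dwells = min_dwells)
  }
  fits
}

#' Transition-density map normalized to total observation time
#'
#' For each state change whose new state persists for at least
#' `min_persist_frames` FE frames, the (mean FE of the preceding dwell,
#' mean FE of the following dwell) coordinate is recorded; events are binned
#' into a 2D histogram and the counts divided by the total pre-truncation
#' observation time of the dataset.
#'
#' @param state_paths list of integer state paths (truncated).
#' @param fe list of FE vectors aligned to the paths.
#' @param frame_period_s FE-frame period, s.
#' @param min_persist_frames minimum frames the new state must last
#'   (default 2 = "lasting more than a frame").
#' @param bin_width FE bin width.
#' @param range FE axis range.
#' @return list of class `transition_density`: `counts` (matrix, rows = FE
#'   before), `density` (counts / total observation time, s^-1), `breaks`,
#'   `n_events`, `total_time_s`, `events` (data.frame of coordinates).
#' @export
transition_density <- function(state_paths, fe, frame_period_s,
                               min_persist_frames = 2, bin_width = 0.05,
                               range = c(0, 1)) {
  if (!is.list(state_paths)) state_paths <- list(state_paths)
  if (!is.list(fe)) fe <- list(fe)
  before <- after <- numeric(0)
  total_time <- 0
  for (i in seq_along(state_paths)) {
    s <- state_paths[[i]]
    total_time <- total_time + length(s) * frame_period_s
    if (length(s) < 2) next
    r <- rle(s)
    n_runs <- length(r$lengths)
    if (n_runs < 2) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    x <- fe[[i]]
    run_fe <- vapply(seq_len(n_runs), function(j)
      mean(x[starts[j]:ends[j]], na.rm = TRUE), numeric(1))
    for (j in 2:n_runs) {
      if (r$lengths[j] >= min_persist_frames) {
        before <- c(before, run_fe[j - 1])
        after <- c(after, run_fe[j])
      }
    }
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  nb <- length(breaks) - 1
  counts <- matrix(0, nb, nb,
                   dimnames = list(before = utils::head(breaks, -1),
                                   after = utils::head(breaks, -1)))
  keep <- before >= range[1] & before <= range[2] &
    after >= range[1] & after <= range[2]
  bi <- pmin(pmax(findInterval(before[keep], breaks,
                               rightmost.closed = TRUE), 1), nb)
  ai <- pmin(pmax(findInterval(after[keep], breaks,
                               rightmost.closed = TRUE), 1), nb)
  for (e in seq_along(bi))
    counts[bi[e], ai[e]] <- counts[bi[e], ai[e]] + 1
  structure(list(counts = counts,
                 density = if (total_time > 0) counts / total_time else counts,
                 breaks = breaks, n_events = length(before),
                 total_time_s = total_time,
                 events = data.frame(fe_before = before, fe_after = after)),
            class = "transition_density")
}

#' Ensemble population summary
#'
#' Per-state time occupancy, the fraction of trajectories that visit each
#' state, and the dataset transition frequency (state changes per second of
#' observation).
#'
#' @param state_paths list of integer state paths.
#' @param frame_period_s FE-frame period, s.
#' @param K number of states (defaults to the maximum label present).
#' @return list: `occupancy` (length-K), `visit_fraction` (length-K),
#'   `transitions_per_s`, `n_transitions`, `total_time_s`, `n_trajectories`.
#' @export
population_summary <- function(state_paths, frame_period_s,
                               K = max(unlist(state_paths))) {
  if (!is.list(state_paths)) state_paths <- list(state_paths)
  n_frames <- sum(lengths(state_paths))
  occupancy <- vapply(seq_len(K), function(k)
    sum(unlist(state_paths) == k) / n_frames, numeric(1))
  visit <- vapply(seq_len(K), function(k)
    mean(vapply(state_paths, function(s) any(s == k), logical(1))),
    numeric(1))
  n_trans <- sum(vapply(state_paths, function(s)
    if (length(s) > 1) sum(diff(s) != 0) else 0L, numeric(1)))
  total_time <- n_frames * frame_period_s
  list(occupancy = occupancy, visit_fraction = visit,
       transitions_per_s = n_trans / total_time,
       n_transitions = n_trans, total_time_s = total_time,
       n_trajectories = length(state_paths))
}
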