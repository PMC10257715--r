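#' Define a continuous-time kinetic model of conformational exchange
#'
#' A `kinetic_model` describes a molecule switching between `K` conformational
#' states (e.g. closed/open) as a continuous-time Markov chain, together with
#' the Gaussian FRET-efficiency emission parameters of each state and the mean
#' photon budget per frame.
#'
#' @param rate_matrix K x K matrix of transition rates in s^-1. Off-diagonal
#'   entry `[i, j]` is the rate from state `i` to state `j`; the diagonal is
#'   ignored. All off-diagonal entries must be >= 0.
#' @param fe_means FRET efficiency of each state, in `[0, 1]`. Must be
#'   distinct, separated by more than `max(fe_sds)`.
#' @param fe_sds emission standard deviation of each state (dimensionless).
#' @param total_intensity mean photons per frame at full exposure emitted by
#'   one donor/acceptor pair (before camera noise).
#' @param state_names optional character labels; defaults to
#'   `"closed"`/`"open"` for two states (high-FE state is "closed").
#'
#' @return an object of class `kinetic_model`.
#' @examples
#' closed_open_model(k_open = 0.01, k_close = 0.5)
#' @export
kinetic_model <- function(rate_matrix, fe_means, fe_sds,
                          total_intensity = 500, state_names = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  K <- nrow(rate_matrix)
  if (ncol(rate_matrix) != K)
    stop("rate_matrix must be square")
  off <- rate_matrix[row(rate_matrix) != col(rate_matrix)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("invalid kinetic model: off-diagonal rates must be finite and >= 0")
  if (length(fe_means) != K || length(fe_sds) != K)
    stop("fe_means and fe_sds must have one entry per state")
  if (any(fe_means < 0 | fe_means > 1))
    stop("fe_means must lie in [0, 1]")
  if (any(fe_sds <= 0))
    stop("fe_sds must be > 0")
  if (min(diff(sort(fe_means))) <= max(fe_sds))
    stop("fe_means must be distinct and separated by more than max(fe_sds)")
  if (total_intensity <= 0)
    stop("total_intensity must be > 0")
  if (is.null(state_names)) {
    state_names <- if (K == 2) {
      ifelse(fe_means == max(fe_means), "closed", "open")
    } else {
      paste0("state", seq_len(K))
    }
  }
  diag(rate_matrix) <- 0
  structure(
    list(n_states = K, rate_matrix = rate_matrix,
         fe_means = as.numeric(fe_means), fe_sds = as.numeric(fe_sds),
         total_intensity = total_intensity, state_names = state_names),
    class = "kinetic_model")
}

#' Two-state closed/open kinetic model
#'
#' Convenience constructor for the canonical two-state exchange between a
#' high-FRET closed state and a low-FRET open state.
#'
#' @param k_open closing-to-opening rate (closed -> open), s^-1.
#' @param k_close open -> closed rate, s^-1.
#' @param fe_closed,fe_open state FRET efficiencies.
#' @param fe_sd emission SD shared by both states.
#' @param total_intensity mean photons per frame.
#' @return a [kinetic_model()] with states ordered (closed, open).
#' @export
closed_open_model <- function(k_open = 0.01, k_close = 0.5,
                              fe_closed = 0.8, fe_open = 0.35,
                              fe_sd = 0.08, total_intensity = 500) {
  Q <- matrix(c(0, k_open,
                k_close, 0), nrow = 2, byrow = TRUE)
  kinetic_model(Q, fe_means = c(fe_closed, fe_open),
                fe_sds = rep(fe_sd, 2), total_intensity = total_intensity,
                state_names = c("closed", "open"))
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d states: %s\n", x$n_states,
              paste(x$state_names, collapse = ", ")))
  cat("  FE means:", paste(format(x$fe_means), collapse = ", "), "\n")
  cat("  exit rates (s^-1):",
      paste(format(rowSums(x$rate_matrix)), collapse = ", "), "\n")
  invisible(x)
}

#' Stationary distribution of a kinetic model
#'
#' Solves pi Q = 0 with sum(pi) = 1 for the embedded continuous-time chain.
#' For absorbing models (a state with exit rate 0) mass concentrates on the
#' absorbing classes.
#'
#' @param model a [kinetic_model()].
#' @return numeric vector of stationary state occupancies.
#' @export
stationary_distribution <- function(model) {
  Q <- model$rate_matrix
  diag(Q) <- -rowSums(Q)
  K <- nrow(Q)
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi_hat <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}

#' Simulate a continuous-time state path (Gillespie algorithm)
#'
#' Samples a trajectory of the conformational chain over `[0, duration]`:
#' the dwell in state `i` is exponential with the total exit rate of `i`, and
#' the successor state is drawn proportionally to the outgoing rates.
#'
#' @param model a [kinetic_model()].
#' @param duration total simulated time, s.
#' @param seed integer RNG seed (optional; when `NULL` the current RNG
#'   stream is used, so paths can be drawn inside a larger seeded simulation).
#' @param start_state initial state index, or `"stationary"` (default) to
#'   draw it from [stationary_distribution()].
#' @return a `state_path`: data.frame with columns `state`, `t_start`,
#'   `t_end`; segments are contiguous and cover `[0, duration]`.
#' @export
simulate_state_path <- function(model, duration, seed = NULL,
                                start_state = "stationary") {
  stopifnot(inherits(model, "kinetic_model"))
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  Q <- model$rate_matrix
  exit <- rowSums(Q)
  state <- if (identical(start_state, "stationary")) {
    sample.int(model$n_states, 1, prob = stationary_distribution(model))
  } else {
    as.integer(start_state)
  }
  t_cur <- 0
  cap <- 256L; n <- 0L
  states <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  while (t_cur < duration) {
    dwell <- if (exit[state] > 0) stats::rexp(1, exit[state]) else Inf
    t_next <- min(t_cur + dwell, duration)
    n <- n + 1L
    if (n > cap) {  # grow geometrically
      cap <- cap * 2L
      length(states) <- cap; length(t0) <- cap; length(t1) <- cap
    }
    states[n] <- state; t0[n] <- t_cur; t1[n] <- t_next
    if (t_next >= duration) break
    state <- sample.int(model$n_states, 1, prob = Q[state, ])
    t_cur <- t_next
  }
  structure(data.frame(state = states[seq_len(n)], t_start = t0[seq_len(n)],
                       t_end = t1[seq_len(n)]),
            class = c("state_path", "data.frame"))
}

#' Fractional state occupancy of a path inside a time window
#'
#' @param path a `state_path` from [simulate_state_path()].
#' @param t0,t1 window bounds, s (`t1 > t0`).
#' @param n_states number of states.
#' @return numeric vector of per-state occupancies summing to 1.
#' @export
occupancy_in_window <- function(path, t0, t1, n_states) {
  overlap <- pmax(0, pmin(path$t_end, t1) - pmax(path$t_start, t0))
  occ <- numeric(n_states)
  for (k in seq_len(n_states))
    occ[k] <- sum(overlap[path$state == k])
  occ / (t1 - t0)
}

#' Discretize a continuous state path onto camera frames
#'
#' The camera integrates over the exposure window of each frame, so the ideal
#' (noise-free) FRET efficiency of a 532 nm frame is the exposure-time-weighted
#' mean of the per-state FE values. 641 nm (direct acceptor excitation) frames
#' carry occupancy but no FE.
#'
#' @param path a `state_path` covering the movie duration.
#' @param model the [kinetic_model()] providing `fe_means`.
#' @param acquisition an [acquisition_config()].
#' @return data.frame with one row per frame: `frame` (0-based), `time`
#'   (frame start, s), `excitation` (nm), per-state occupancy columns
#'   `occ_1..occ_K`, and `fe_ideal` (`NA` on 641 frames).
#' @export
discretize_path <- function(path, model, acquisition) {
  stopifnot(inherits(acquisition, "acquisition_config"))
  if (max(path$t_end) < acquisition$movie_duration - 1e-9)
    stop("state path does not cover the movie duration")
  n_frames <- frame_count(acquisition)
  labels <- frame_excitation(acquisition, n_frames)
  starts <- (seq_len(n_frames) - 1) / acquisition$frame_rate
  K <- model$n_states
  occ <- matrix(0, n_frames, K)
  for (i in seq_len(n_frames))
    occ[i, ] <- occupancy_in_window(path, starts[i],
                                    starts[i] + acquisition$exposure, K)
  fe <- as.numeric(occ %*% model$fe_means)
  fe[labels != 532] <- NA_real_
  out <- data.frame(frame = seq_len(n_frames) - 1L, time = starts,
                    excitation = labels)
  colnames(occ) <- paste0("occ_", seq_len(K))
  cbind(out, occ, fe_ideal = fe)
}

#' Photobleaching model and simulation
#'
#' Each fluorophore photobleaches irreversibly in a single step after an
#' exponentially distributed survival time. A rate of 0 means the fluorophore
#' never bleaches (infinite survival time). Blinking is not modeled.
#'
#' @param donor_bleach_rate,acceptor_bleach_rate bleach rates, s^-1 (>= 0).
#' @return an object of class `photophysics_model`.
#' @export
photophysics_model <- function(donor_bleach_rate = 0.01,
                               acceptor_bleach_rate = 0.01) {
  if (donor_bleach_rate < 0 || acceptor_bleach_rate < 0)
    stop("bleach rates must be >= 0")
  structure(list(donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate),
            class = "photophysics_model")
}

#' @rdname photophysics_model
#' @param model a `photophysics_model`.
#' @param seed optional integer seed.
#' @return `simulate_photophysics()`: list with `donor_bleach_time` and
#'   `acceptor_bleach_time`, s (`Inf` when the rate is 0).
#' @export
simulate_photophysics <- function(model, seed = NULL) {
  stopifnot(inherits(model, "photophysics_model"))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(rate) if (rate > 0) stats::rexp(1, rate) else Inf
  list(donor_bleach_time = draw(model$donor_bleach_rate),
       acceptor_bleach_time = draw(model$acceptor_bleach_rate))
}
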