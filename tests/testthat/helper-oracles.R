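# Independent oracles and shared fixture builders for the test suite.

# Exhaustive Viterbi: maximize the joint log-probability over all K^T state
# sequences by enumeration (small T only).
brute_force_viterbi <- function(model, fe) {
  K <- model$K; T_len <- length(fe)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  logB <- sapply(seq_len(K), function(k)
    stats::dnorm(fe, model$means[k], model$sds[k], log = TRUE))
  logB <- matrix(logB, nrow = T_len)
  best <- NULL; best_lp <- -Inf
  for (i in seq_len(nrow(grid))) {
    s <- grid[i, ]
    lp <- log(model$init[s[1]]) + logB[1, s[1]]
    if (T_len > 1) for (t in 2:T_len)
      lp <- lp + log(model$trans[s[t - 1], s[t]]) + logB[t, s[t]]
    if (lp > best_lp) { best_lp <- lp; best <- s }
  }
  unname(best)
}

# Brute-force mutual-nearest-neighbour matching by definition.
brute_force_match <- function(don, acc, max_disp = 1.25) {
  pairs <- list()
  if (nrow(don) == 0 || nrow(acc) == 0)
    return(matrix(integer(0), ncol = 2))
  for (i in seq_len(nrow(don))) {
    d_i <- sqrt((acc$x - don$x[i])^2 + (acc$y - don$y[i])^2)
    j <- which.min(d_i)
    d_j <- sqrt((don$x - acc$x[j])^2 + (don$y - acc$y[j])^2)
    if (which.min(d_j) == i && d_i[j] <= max_disp)
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (length(pairs) == 0)
    return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# Random small HMM with sorted means (valid fret_hmm shape).
random_small_hmm <- function(K) {
  trans <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  trans <- trans / rowSums(trans)
  init <- stats::runif(K, 0.05, 1); init <- init / sum(init)
  structure(list(K = K, means = sort(stats::runif(K, 0, 1)),
                 sds = stats::runif(K, 0.05, 0.2), trans = trans,
                 init = init), class = "fret_hmm")
}

# Noiseless forward-model trajectory for given true FE series and factors:
# the algebra that correct_and_compute_fe must invert exactly.
synthetic_trajectory <- function(E, alpha = 0.1, delta = 0.05, gamma = 1.3,
                                 I_tot = 1000, A641 = I_tot,
                                 molecule_id = 1L, frame_period = 0.375) {
  n <- length(E)
  I_D <- I_tot * (1 - E)
  I_A641 <- rep(A641, n)
  I_A <- gamma * I_tot * E + alpha * I_D + delta * I_A641
  structure(list(molecule_id = molecule_id,
                 frame = seq_len(n) - 1L,
                 time = (seq_len(n) - 1) * frame_period,
                 I_D = I_D, I_A = I_A, I_A_641 = I_A641,
                 t641 = (seq_len(n) - 1) * frame_period,
                 raw641 = I_A641,
                 fe = rep(NA_real_, n), truncation_frame = n,
                 qc_status = "pending", qc_reason = NA_character_),
            class = "fret_trajectory")
}

# Shared movie fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Collision-free detection fixture: bright static molecules on a jittered
# grid (spacing 12 px >> 4 * psf_sigma), no bleaching, SNR >= 5.
grid_movie <- function() {
  set.seed(99)
  grid <- expand.grid(x = 8 + (0:3) * 13, y = 8 + (0:3) * 13)
  grid$x <- grid$x + stats::runif(16, -1, 1)
  grid$y <- grid$y + stats::runif(16, -1, 1)
  model <- closed_open_model(k_open = 0.05, k_close = 0.5,
                             total_intensity = 800)
  acq <- acquisition_config(movie_duration = 6, image_shape = c(64, 64),
                            channel_shift = c(1.5, 0.5))
  suppressWarnings(simulate_smfret_movie(
    model, photophysics_model(0, 0), acq, n_molecules = nrow(grid),
    seed = 11, positions = grid))
}
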