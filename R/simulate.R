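#' Ideal per-frame donor/acceptor intensities for one molecule
#'
#' Forward model of the spectroscopic corrections: on 532 nm frames the donor
#' channel carries `I_tot * (1 - E)` from the FRET pair (plus full donor
#' brightness once the acceptor has bleached), and the acceptor channel
#' carries the sensitized emission `gamma * I_tot * E`, donor bleedthrough
#' `alpha *` (donor signal) and direct acceptor excitation `delta *` (641 nm
#' acceptor brightness). On 641 nm frames the acceptor channel reports the
#' direct acceptor brightness while the acceptor is unbleached. Bleaching
#' inside an exposure scales signals by the alive fraction of the window.
#'
#' @param truth list with elements `path` (a `state_path`),
#'   `donor_bleach_times`, `acceptor_bleach_times` (numeric vectors, one per
#'   fluorophore; `Inf` = never), and optionally `n_donor`, `n_acceptor`
#'   (default 1; 0 makes a acceptor-only/donor-only calibration molecule).
#' @param model a [kinetic_model()].
#' @param acquisition an [acquisition_config()].
#' @return data.frame with one row per frame: `frame`, `time`, `excitation`,
#'   `donor`, `acceptor` (ideal pre-camera channel intensities, counts) and
#'   `fe_ideal`.
#' @export
emit_intensities <- function(truth, model, acquisition) {
  dtimes <- truth$donor_bleach_times
  atimes <- truth$acceptor_bleach_times
  n_donor <- if (is.null(truth$n_donor)) length(dtimes) else truth$n_donor
  n_acceptor <- if (is.null(truth$n_acceptor)) length(atimes) else truth$n_acceptor
  disc <- discretize_path(truth$path, model, acquisition)
  exposure <- acquisition$exposure
  starts <- disc$time
  alive_frac <- function(t_bleach) {
    pmin(1, pmax(0, (t_bleach - starts) / exposure))
  }
  d_alive <- if (n_donor > 0) {
    rowSums(vapply(dtimes[seq_len(n_donor)], alive_frac, numeric(length(starts))))
  } else rep(0, length(starts))
  a_alive <- if (n_acceptor > 0) {
    rowSums(vapply(atimes[seq_len(n_acceptor)], alive_frac, numeric(length(starts))))
  } else rep(0, length(starts))
  # FRET occurs between the first donor and first acceptor only
  f_pair <- if (n_donor > 0 && n_acceptor > 0) {
    pmin(alive_frac(dtimes[1]), alive_frac(atimes[1]))
  } else rep(0, length(starts))

  I_tot <- model$total_intensity
  A641 <- acquisition$acceptor_brightness_641
  if (is.null(A641)) A641 <- I_tot
  alpha <- acquisition$bleedthrough_alpha
  delta <- acquisition$direct_excitation_delta
  gamma <- acquisition$gamma
  E <- ifelse(is.na(disc$fe_ideal), 0, disc$fe_ideal)

  is532 <- disc$excitation == 532
  donor <- numeric(nrow(disc))
  acceptor <- numeric(nrow(disc))
  # 532 frames: FRET pair + any non-FRET donors emit; acceptor channel sums
  # sensitized emission, bleedthrough and direct excitation.
  donor_sig <- I_tot * ((1 - E) * f_pair + pmax(d_alive - f_pair, 0))
  acc_sig <- gamma * I_tot * E * f_pair + alpha * donor_sig +
    delta * A641 * a_alive
  donor[is532] <- donor_sig[is532]
  acceptor[is532] <- acc_sig[is532]
  # 641 frames: direct acceptor excitation only
  acceptor[!is532] <- (A641 * a_alive)[!is532]

  data.frame(frame = disc$frame, time = disc$time,
             excitation = disc$excitation,
             donor = donor, acceptor = acceptor, fe_ideal = disc$fe_ideal)
}

# Render one Gaussian PSF (total mass = amplitude) into an image, in place.
# x, y are 0-based pixel-center coordinates.
add_psf <- function(img, x, y, amplitude, sigma) {
  if (amplitude <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(5 * sigma)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - r):min(w - 1, cx + r)
  ys <- max(0, cy - r):min(h - 1, cy + r)
  gx <- exp(-((xs - x)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y)^2) / (2 * sigma^2))
  patch <- outer(gy, gx)
  patch <- patch / sum(patch) * amplitude
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + patch
  img
}

#' Render a two-channel TIRF movie from molecule ground truths
#'
#' Each molecule is rendered as a symmetric 2D Gaussian point-spread function
#' at its donor-channel position, and at position + `channel_shift` in the
#' acceptor channel. Pixel values are `Poisson(signal + background) +
#' Normal(0, read_noise_sd)`. Molecules closer than `4 * psf_sigma` are kept
#' but flagged as collisions in the truth table.
#'
#' @param truths list of molecules; each has `id`, `x`, `y` (0-based donor
#'   frame pixel-center coordinates) and `intensities` (from
#'   [emit_intensities()]).
#' @param acquisition an [acquisition_config()].
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param noise logical; `FALSE` renders noiseless expected images (testing).
#' @return list with `donor`, `acceptor` (arrays `[height, width, frame]`),
#'   `excitation` (per-frame labels) and `molecules` (truth table with
#'   collision flags).
#' @export
render_movie <- function(truths, acquisition, seed = 1, noise = TRUE) {
  set.seed(seed)
  h <- acquisition$image_shape[1]; w <- acquisition$image_shape[2]
  n_frames <- frame_count(acquisition)
  labels <- frame_excitation(acquisition, n_frames)
  sigma <- acquisition$psf_sigma
  shift <- acquisition$channel_shift
  margin <- 3 * sigma
  xs <- vapply(truths, `[[`, numeric(1), "x")
  ys <- vapply(truths, `[[`, numeric(1), "y")
  if (length(truths) > 0 &&
      any(xs < margin | xs > w - 1 - margin | ys < margin | ys > h - 1 - margin))
    stop("molecule positions must lie >= 3*psf_sigma inside the image bounds")
  collision <- rep(FALSE, length(truths))
  if (length(truths) > 1) {
    d <- as.matrix(stats::dist(cbind(xs, ys)))
    diag(d) <- Inf
    collision <- apply(d < 4 * sigma, 1, any)
    if (any(collision))
      warning(sprintf("%d molecules closer than 4*psf_sigma flagged as collisions",
                      sum(collision)))
  }
  donor <- array(0, c(h, w, n_frames))
  acceptor <- array(0, c(h, w, n_frames))
  for (f in seq_len(n_frames)) {
    img_d <- matrix(acquisition$background, h, w)
    img_a <- matrix(acquisition$background, h, w)
    for (m in truths) {
      I <- m$intensities[f, ]
      img_d <- add_psf(img_d, m$x, m$y, I$donor, sigma)
      img_a <- add_psf(img_a, m$x + shift[1], m$y + shift[2], I$acceptor, sigma)
    }
    if (noise) {
      img_d <- matrix(stats::rpois(h * w, img_d), h, w) +
        matrix(stats::rnorm(h * w, 0, acquisition$read_noise_sd), h, w)
      img_a <- matrix(stats::rpois(h * w, img_a), h, w) +
        matrix(stats::rnorm(h * w, 0, acquisition$read_noise_sd), h, w)
    }
    donor[, , f] <- img_d
    acceptor[, , f] <- img_a
  }
  molecules <- do.call(rbind, lapply(seq_along(truths), function(i) {
    m <- truths[[i]]
    data.frame(id = as.numeric(m$id %||% i), x = xs[i], y = ys[i],
               n_donor = as.numeric(m$n_donor %||% 1),
               n_acceptor = as.numeric(m$n_acceptor %||% 1),
               donor_bleach_time = min(c(m$donor_bleach_times, Inf)),
               acceptor_bleach_time = min(c(m$acceptor_bleach_times, Inf)),
               collision = collision[i])
  }))
  list(donor = donor, acceptor = acceptor, excitation = labels,
       molecules = molecules, acquisition = acquisition)
}

#' Simulate a complete ground-truthed smFRET movie
#'
#' Draws molecule positions, state paths, bleach times and camera noise, and
#' renders the two-channel movie. A fraction of molecules can carry two
#' acceptors (multi-fluorophore QC cases) or be donor-only/acceptor-only
#' (correction-factor calibration cases).
#'
#' @param model a [kinetic_model()].
#' @param photophysics a [photophysics_model()].
#' @param acquisition an [acquisition_config()].
#' @param n_molecules number of molecules.
#' @param seed integer seed.
#' @param fraction_double_acceptor,fraction_donor_only,fraction_acceptor_only
#'   expected fractions of the respective molecule species (the remainder are
#'   standard single donor + single acceptor FRET pairs).
#' @param positions optional data.frame with `x`, `y` (0-based donor-frame
#'   coordinates) fixing molecule positions instead of drawing them
#'   uniformly at random.
#' @param noise logical; `FALSE` for noiseless expected images.
#' @return the [render_movie()] result, plus `truths` (per-molecule ground
#'   truth: paths, bleach times, ideal intensities) and `model`.
#' @export
simulate_smfret_movie <- function(model, photophysics, acquisition,
                                  n_molecules, seed = 1,
                                  fraction_double_acceptor = 0,
                                  fraction_donor_only = 0,
                                  fraction_acceptor_only = 0,
                                  positions = NULL,
                                  noise = TRUE) {
  set.seed(seed)
  h <- acquisition$image_shape[1]; w <- acquisition$image_shape[2]
  # margin accommodates both the PSF footprint and a 7 px photometry annulus
  margin <- max(ceiling(3 * acquisition$psf_sigma) + 1, 8)
  shift <- acquisition$channel_shift
  truths <- vector("list", n_molecules)
  species_draw <- stats::runif(n_molecules)
  p1 <- fraction_double_acceptor
  p2 <- p1 + fraction_donor_only
  p3 <- p2 + fraction_acceptor_only
  for (i in seq_len(n_molecules)) {
    if (!is.null(positions)) {
      x <- positions$x[i]; y <- positions$y[i]
    } else {
      # keep both channel footprints inside the frame
      x <- stats::runif(1, margin + max(0, -shift[1]),
                        w - 1 - margin - max(0, shift[1]))
      y <- stats::runif(1, margin + max(0, -shift[2]),
                        h - 1 - margin - max(0, shift[2]))
    }
    species <- if (species_draw[i] < p1) "double_acceptor"
      else if (species_draw[i] < p2) "donor_only"
      else if (species_draw[i] < p3) "acceptor_only"
      else "fret_pair"
    n_donor <- if (species == "acceptor_only") 0L else 1L
    n_acceptor <- switch(species, double_acceptor = 2L, donor_only = 0L, 1L)
    path <- simulate_state_path(model, acquisition$movie_duration)
    dbt <- if (n_donor > 0)
      vapply(seq_len(n_donor), function(j)
        simulate_photophysics(photophysics)$donor_bleach_time, numeric(1))
      else numeric(0)
    abt <- if (n_acceptor > 0)
      vapply(seq_len(n_acceptor), function(j)
        simulate_photophysics(photophysics)$acceptor_bleach_time, numeric(1))
      else numeric(0)
    truth <- list(id = i, x = x, y = y, species = species,
                  n_donor = n_donor, n_acceptor = n_acceptor,
                  path = path, donor_bleach_times = dbt,
                  acceptor_bleach_times = abt)
    truth$intensities <- emit_intensities(truth, model, acquisition)
    truths[[i]] <- truth
  }
  movie <- render_movie(truths, acquisition, seed = seed + 1L, noise = noise)
  movie$molecules$species <- vapply(truths, `[[`, character(1), "species")
  movie$truths <- truths
  movie$model <- model
  movie
}

#' Simulate FRET-efficiency trajectories at the frame level
#'
#' Trajectory-level generator that skips the imaging stages: hidden states
#' follow a discrete-time Markov chain at the FE-frame period, emissions are
#' Gaussian around the state means, and trajectories are truncated at an
#' exponential photobleach time (capped at the movie duration). This is the
#' generator used to benchmark the HMM and kinetics stages directly.
#'
#' @param n_traj number of trajectories.
#' @param means,sds per-state emission mean and SD of FE.
#' @param trans K x K per-frame transition probability matrix, or a vector of
#'   per-state stay probabilities (off-diagonal mass split equally).
#' @param frame_period time between FE frames, s.
#' @param movie_duration maximum observation, s.
#' @param bleach_rate first-bleach rate, s^-1 (0 = no bleaching).
#' @param seed integer seed.
#' @param min_frames trajectories shorter than this after truncation are
#'   redrawn bleach-wise (keeps every trajectory usable).
#' @return list with `fe` (list of numeric vectors), `states` (list of true
#'   integer paths), `trans`, `means`, `sds`, `frame_period`.
#' @export
simulate_fe_dataset <- function(n_traj, means, sds, trans,
                                frame_period = 0.25, movie_duration = 300,
                                bleach_rate = 0.01, seed = 1,
                                min_frames = 5) {
  set.seed(seed)
  K <- length(means)
  if (is.null(dim(trans))) {
    stay <- trans
    trans <- matrix(0, K, K)
    for (k in seq_len(K)) {
      trans[k, ] <- (1 - stay[k]) / (K - 1)
      trans[k, k] <- stay[k]
    }
  }
  if (length(sds) == 1) sds <- rep(sds, K)
  max_frames <- floor(movie_duration / frame_period)
  # stationary distribution of the discrete chain for the initial state
  ev <- Re(eigen(t(trans))$vectors[, 1])
  pi0 <- pmax(ev / sum(ev), 0); pi0 <- pi0 / sum(pi0)
  fe <- vector("list", n_traj)
  states <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    repeat {
      n_i <- if (bleach_rate > 0)
        min(max_frames, ceiling(stats::rexp(1, bleach_rate) / frame_period))
      else max_frames
      if (n_i >= min_frames) break
    }
    s <- integer(n_i)
    s[1] <- sample.int(K, 1, prob = pi0)
    if (n_i > 1) {
      u <- stats::runif(n_i - 1)
      cum <- apply(trans, 1, cumsum)  # K x K, column = from-state
      for (t in 2:n_i)
        s[t] <- findInterval(u[t - 1], cum[, s[t - 1]], left.open = TRUE) + 1L
    }
    states[[i]] <- s
    fe[[i]] <- stats::rnorm(n_i, means[s], sds[s])
  }
  list(fe = fe, states = states, trans = trans, means = means, sds = sds,
       frame_period = frame_period)
}
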