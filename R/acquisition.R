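#' Acquisition configuration for alternating-excitation TIRF movies
#'
#' Describes the camera/illumination scheme: acquisition alternates between
#' donor-excitation frames (532 nm) and direct acceptor-excitation frames
#' (641 nm) in a repeating cycle. The default mirrors a 4 s^-1 frame rate
#' with 250 ms exposure and a `[532, 532, 641]` cycle; a fast mode (10 s^-1,
#' 100 ms) is used for constructs with fast dynamics.
#'
#' @param frame_rate frames per second.
#' @param exposure exposure time per frame, s (must be <= 1/frame_rate).
#' @param cycle ordered excitation wavelengths (nm) repeated over the movie.
#' @param movie_duration total movie length, s.
#' @param image_shape `c(height, width)` in pixels.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param channel_shift `c(dx, dy)` translation (pixels) mapping donor-channel
#'   coordinates to acceptor-channel coordinates.
#' @param bleedthrough_alpha fraction of donor signal detected in the acceptor
#'   channel (`[0, 1)`).
#' @param direct_excitation_delta fraction of the acceptor's 641 nm brightness
#'   excited directly by the 532 nm laser (`[0, 1)`).
#' @param gamma relative acceptor/donor detection-and-quantum-yield factor.
#' @param acceptor_brightness_641 mean acceptor photons per frame under
#'   641 nm excitation; `NULL` (default) means equal to the donor-excitation
#'   photon budget of the molecule.
#' @param read_noise_sd camera read noise SD, counts.
#' @param background mean background, counts/pixel.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 4, exposure = 0.25,
                               cycle = c(532, 532, 641),
                               movie_duration = 150,
                               image_shape = c(64, 64),
                               psf_sigma = 1.3,
                               channel_shift = c(0, 0),
                               bleedthrough_alpha = 0.1,
                               direct_excitation_delta = 0.05,
                               gamma = 1.0,
                               acceptor_brightness_641 = NULL,
                               read_noise_sd = 2,
                               background = 20) {
  if (exposure > 1 / frame_rate + 1e-12)
    stop("exposure must be <= 1/frame_rate")
  if (length(cycle) == 0) stop("cycle must be non-empty")
  if (!all(cycle %in% c(532, 641)))
    stop("cycle labels must be 532 or 641")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (bleedthrough_alpha < 0 || bleedthrough_alpha >= 1 ||
      direct_excitation_delta < 0 || direct_excitation_delta >= 1)
    stop("alpha and delta must lie in [0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(
    list(frame_rate = frame_rate, exposure = exposure, cycle = cycle,
         movie_duration = movie_duration,
         image_shape = as.integer(image_shape), psf_sigma = psf_sigma,
         channel_shift = as.numeric(channel_shift),
         bleedthrough_alpha = bleedthrough_alpha,
         direct_excitation_delta = direct_excitation_delta,
         gamma = gamma, acceptor_brightness_641 = acceptor_brightness_641,
         read_noise_sd = read_noise_sd, background = background),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %g s^-1, %g ms exposure, cycle [%s], %g s, %dx%d px\n",
    x$frame_rate, 1000 * x$exposure, paste(x$cycle, collapse = ","),
    x$movie_duration, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Number of frames in a movie
#' @param acquisition an [acquisition_config()].
#' @return integer frame count.
#' @export
frame_count <- function(acquisition) {
  as.integer(floor(acquisition$movie_duration * acquisition$frame_rate + 1e-9))
}

#' Excitation label of each frame
#' @param acquisition an [acquisition_config()].
#' @param n_frames number of frames (defaults to [frame_count()]).
#' @return integer vector of wavelengths (nm), one per frame.
#' @export
frame_excitation <- function(acquisition, n_frames = frame_count(acquisition)) {
  rep_len(acquisition$cycle, n_frames)
}

#' Mean spacing between consecutive FRET (532 nm) frames
#'
#' The excitation cycle interleaves 641 nm frames among the 532 nm frames, so
#' FE samples are not strictly equidistant; dwell durations use the mean
#' spacing cycle_length / (frame_rate * n_532_per_cycle).
#'
#' @param acquisition an [acquisition_config()].
#' @return period in seconds.
#' @export
fe_frame_period <- function(acquisition) {
  n532 <- sum(acquisition$cycle == 532)
  if (n532 == 0) stop("cycle contains no 532 nm frames")
  length(acquisition$cycle) / (acquisition$frame_rate * n532)
}
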