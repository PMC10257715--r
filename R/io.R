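#' Write a two-channel movie as multi-page TIFFs with a JSON sidecar
#'
#' One TIFF per channel (`donor.tif`, `acceptor.tif`) plus
#' `movie_meta.json` carrying the per-frame excitation labels, the
#' acquisition configuration and the intensity scale used to pack counts
#' into the TIFF range.
#'
#' @param movie a movie list ([render_movie()] / [simulate_smfret_movie()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(1, max(movie$donor), max(movie$acceptor))
  pack <- function(arr) {
    lapply(seq_len(dim(arr)[3]),
           function(f) pmin(pmax(arr[, , f] / scale, 0), 1))
  }
  tiff::writeTIFF(pack(movie$donor), file.path(dir, "donor.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(pack(movie$acceptor), file.path(dir, "acceptor.tif"),
                  bits.per.sample = 16L)
  meta <- list(excitation = movie$excitation, intensity_scale = scale,
               acquisition = unclass(movie$acquisition))
  jsonlite::write_json(meta, file.path(dir, "movie_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(movie$molecules)) {
    mol <- movie$molecules
    mol$donor_bleach_time[!is.finite(mol$donor_bleach_time)] <- NA
    mol$acceptor_bleach_time[!is.finite(mol$acceptor_bleach_time)] <- NA
    utils::write.csv(mol, file.path(dir, "truth_molecules.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#' @param dir directory containing `donor.tif`, `acceptor.tif`,
#'   `movie_meta.json`.
#' @return a movie list (`donor`, `acceptor`, `excitation`, `acquisition`).
#' @export
read_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie_meta.json"),
                              simplifyVector = TRUE)
  unpack <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(dim(frames[[1]]), length(frames)))
    for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
    arr * meta$intensity_scale
  }
  acq <- meta$acquisition
  acquisition <- acquisition_config(
    frame_rate = acq$frame_rate, exposure = acq$exposure, cycle = acq$cycle,
    movie_duration = acq$movie_duration, image_shape = acq$image_shape,
    psf_sigma = acq$psf_sigma, channel_shift = acq$channel_shift,
    bleedthrough_alpha = acq$bleedthrough_alpha,
    direct_excitation_delta = acq$direct_excitation_delta,
    gamma = acq$gamma,
    acceptor_brightness_641 = acq$acceptor_brightness_641,
    read_noise_sd = acq$read_noise_sd, background = acq$background)
  list(donor = unpack(file.path(dir, "donor.tif")),
       acceptor = unpack(file.path(dir, "acceptor.tif")),
       excitation = meta$excitation, acquisition = acquisition)
}

#' Read a per-frame trajectory table into trajectory objects
#'
#' Accepts the CSV layout written by [trajectory_table()] (one row per
#' 532 nm frame: `molecule_id`, `frame`, `time_s`, `I_D`, `I_A`, `I_A_641`,
#' optionally `FE`). This is the "trajectory-table" input mode that skips
#' all imaging stages.
#'
#' @param path CSV file.
#' @return list of `fret_trajectory` objects (uncorrected; FE retained when
#'   present).
#' @export
read_trajectory_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("molecule_id", "time_s", "I_D", "I_A", "I_A_641")
  if (!all(need %in% names(tab)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$molecule_id), function(d) {
    d <- d[order(d$time_s), ]
    structure(list(
      molecule_id = d$molecule_id[1],
      frame = if ("frame" %in% names(d)) d$frame else seq_len(nrow(d)) - 1L,
      time = d$time_s, I_D = d$I_D, I_A = d$I_A, I_A_641 = d$I_A_641,
      t641 = d$time_s, raw641 = d$I_A_641,
      fe = if ("FE" %in% names(d)) d$FE else rep(NA_real_, nrow(d)),
      truncation_frame = nrow(d),
      qc_status = "pending", qc_reason = NA_character_),
      class = "fret_trajectory")
  })
}

#' Save an FE-histogram / mixture overlay plot
#' @param histogram an [fe_histogram()].
#' @param mixture optional [fit_mixture()] result to overlay.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_fe_histogram <- function(histogram, mixture = NULL, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(histogram$mid, histogram$density, type = "h", lwd = 3,
                 col = "grey60", xlab = "FRET efficiency",
                 ylab = "Probability density", main = "FE distribution")
  if (!is.null(mixture)) {
    xs <- seq(min(histogram$mid), max(histogram$mid), length.out = 400)
    graphics::lines(xs, mixture_density(mixture, xs), col = "black", lwd = 2)
    for (k in seq_along(mixture$means))
      graphics::lines(xs, mixture_density(mixture, xs, k), lty = 2,
                      col = if (mixture$means[k] >= 0.6) "blue" else "red")
  }
  invisible(path)
}

#' Save a transition-density heat map
#' @param tdp a [transition_density()] result.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_transition_density <- function(tdp, path) {
  grDevices::png(path, width = 600, height = 550)
  on.exit(grDevices::dev.off())
  mids <- utils::head(tdp$breaks, -1) + diff(tdp$breaks) / 2
  graphics::image(mids, mids, tdp$density,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "FE before transition", ylab = "FE after transition",
                  main = sprintf("Transition density (%d events / %.0f s)",
                                 tdp$n_events, tdp$total_time_s))
  invisible(path)
}
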