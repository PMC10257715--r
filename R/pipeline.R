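#' Default pipeline configuration
#'
#' Every stage parameter of the analysis appears here explicitly; user
#' configs (lists or YAML files) are merged over these defaults. Defaults
#' mirror the standard acquisition (4 s^-1, 250 ms exposure,
#' `[532, 532, 641]` cycle) and the documented analysis settings
#' (1.25 px matching, ellipticity window 1-1.2, bleach step fraction 0.5,
#' minimum 20 FE frames, R0 = 54 angstroms).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    input = list(mode = "simulate", path = NULL),
    seed = 1,
    out_dir = NULL,
    simulate = list(
      n_molecules = 16,
      k_open = 0.05, k_close = 0.5,
      fe_means = NULL, fe_sds = NULL, rate_matrix = NULL,
      fe_closed = 0.8, fe_open = 0.35, fe_sd = 0.08,
      total_intensity = 500,
      donor_bleach_rate = 0.005, acceptor_bleach_rate = 0.005,
      fraction_double_acceptor = 0, fraction_donor_only = 0,
      fraction_acceptor_only = 0),
    acquisition = list(
      frame_rate = 4, exposure = 0.25, cycle = c(532, 532, 641),
      movie_duration = 90, image_shape = c(64, 64), psf_sigma = 1.3,
      channel_shift = c(1.5, 0.5), bleedthrough_alpha = 0.1,
      direct_excitation_delta = 0.05, gamma = 1,
      read_noise_sd = 2, background = 20),
    detection = list(
      pick_both = FALSE, n_avg_frames = 5, min_separation_px = 5,
      threshold_k = 5, search_radius_px = 5, max_displacement = 1.25,
      ellipticity_bounds = c(1.0, 1.2), window_px = 7),
    photometry = list(aperture_radius_px = 3, annulus_radii_px = c(5, 7)),
    corrections = list(alpha = 0.1, delta = 0.05, gamma = 1,
                       estimate = FALSE),
    bleach = list(frac = 0.5, min_persist = 4),
    qc = list(min_frames = 20),
    hmm = list(K = 2, tol = 1e-6, max_iter = 500),
    mixture = list(K = 2, bin_width = 0.02, range = c(-0.2, 1.2)),
    kinetics = list(min_persist_frames = 2, tdp_bin_width = 0.05,
                    min_dwells = 5),
    forster = list(R0 = 54,
                   assignments = list(closed = c(0.8, 1),
                                      open = c(0.2, 0.5))),
    output = list(write_movie = FALSE, plots = FALSE))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file with any subset of [default_config()] entries.
#' @return full configuration list (defaults merged).
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

build_kinetic_model <- function(sim) {
  if (!is.null(sim$rate_matrix)) {
    kinetic_model(matrix(unlist(sim$rate_matrix),
                         nrow = length(sim$fe_means), byrow = TRUE),
                  fe_means = sim$fe_means, fe_sds = sim$fe_sds,
                  total_intensity = sim$total_intensity)
  } else {
    closed_open_model(k_open = sim$k_open, k_close = sim$k_close,
                      fe_closed = sim$fe_closed, fe_open = sim$fe_open,
                      fe_sd = sim$fe_sd,
                      total_intensity = sim$total_intensity)
  }
}

#' Run the full smFRET analysis pipeline
#'
#' Executes simulate/load -> detect -> extract -> correct/QC -> HMM ->
#' kinetics -> structural classification as a configured, seeded run. With
#' `config$out_dir` set, every intermediate table is written (CSV/JSON) and
#' plots are produced when `config$output$plots` is `TRUE`.
#'
#' @param config configuration list (merged over [default_config()]) or a
#'   YAML path.
#' @param seed overrides `config$seed` when given.
#' @return a `run_report` list: per-stage counts, correction factors, HMM /
#'   mixture parameters, dwell fits, transition-density summary, population
#'   summary and state classification. Identical config + seed reproduce
#'   identical reports.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  out_dir <- cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, mode = cfg$input$mode)
  emit <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (grepl("\\.csv$", name)) utils::write.csv(obj, path, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null")
    invisible(path)
  }

  acquisition <- do.call(acquisition_config, cfg$acquisition)
  trajs <- NULL
  movie <- NULL

  if (cfg$input$mode == "simulate") {
    model <- build_kinetic_model(cfg$simulate)
    phot <- photophysics_model(cfg$simulate$donor_bleach_rate,
                               cfg$simulate$acceptor_bleach_rate)
    movie <- simulate_smfret_movie(
      model, phot, acquisition, n_molecules = cfg$simulate$n_molecules,
      seed = cfg$seed,
      fraction_double_acceptor = cfg$simulate$fraction_double_acceptor,
      fraction_donor_only = cfg$simulate$fraction_donor_only,
      fraction_acceptor_only = cfg$simulate$fraction_acceptor_only)
    if (!is.null(out_dir) && isTRUE(cfg$output$write_movie))
      write_movie(movie, file.path(out_dir, "movie"))
  } else if (cfg$input$mode == "movie") {
    if (is.null(cfg$input$path) || !dir.exists(cfg$input$path))
      stop("pipeline stage input: movie directory not found: ",
           cfg$input$path)
    movie <- read_movie(cfg$input$path)
  } else if (cfg$input$mode == "trajectory_table") {
    if (is.null(cfg$input$path) || !file.exists(cfg$input$path))
      stop("pipeline stage input: trajectory table not found: ",
           cfg$input$path)
    trajs <- read_trajectory_table(cfg$input$path)
  } else stop("unknown input mode: ", cfg$input$mode)

  # -- detection + extraction (movie modes) ----------------------------------
  if (!is.null(movie)) {
    det <- do.call(detect_pairs, c(list(movie = movie), cfg$detection))
    report$n_particles <- nrow(det$particles$acceptor)
    report$n_pairs <- nrow(det$pairs)
    report$channel_shift <- as.numeric(det$shift)
    report$n_rejected_ellipticity <- det$n_rejected_ellipticity
    emit(det$particles$acceptor, "particles_acceptor.csv")
    emit(det$pairs, "pairs.csv")
    trajs <- lapply(seq_len(nrow(det$pairs)), function(i)
      extract_traces(movie, det$pairs$x_donor[i], det$pairs$y_donor[i],
                     shift = as.numeric(det$shift), molecule_id = i,
                     aperture_radius_px = cfg$photometry$aperture_radius_px,
                     annulus_radii_px = cfg$photometry$annulus_radii_px))
  }
  if (length(trajs) == 0) stop("pipeline stage extract: no trajectories")

  # -- corrections, truncation, QC -------------------------------------------
  factors <- correction_factors(cfg$corrections$alpha,
                                cfg$corrections$delta,
                                cfg$corrections$gamma)
  trajs <- lapply(trajs, correct_and_compute_fe, factors = factors)
  trajs <- lapply(trajs, detect_bleach, gamma = factors$gamma,
                  bleach_frac = cfg$bleach$frac,
                  min_persist = cfg$bleach$min_persist)
  trajs <- lapply(trajs, qc_trajectory, min_frames = cfg$qc$min_frames)
  qc <- qc_summary(trajs)
  report$corrections <- unclass(factors)
  report$qc <- qc
  report$n_extracted <- qc$n_total
  report$n_accepted <- qc$n_accepted
  emit(trajectory_table(trajs), "trajectories.csv")
  emit(qc, "qc_summary.json")
  accepted <- Filter(function(tr) tr$qc_status == "accepted", trajs)
  if (length(accepted) == 0)
    stop("pipeline stage qc: no trajectories passed quality control")

  # -- state inference -------------------------------------------------------
  fe_list <- lapply(accepted, usable_fe)
  hmm <- fit_hmm(fe_list, K = cfg$hmm$K, tol = cfg$hmm$tol,
                 max_iter = cfg$hmm$max_iter, seed = cfg$seed)
  paths <- lapply(fe_list, function(x) viterbi(hmm, x))
  all_fe <- unlist(fe_list)
  histo <- fe_histogram(all_fe, bin_width = cfg$mixture$bin_width,
                        range = cfg$mixture$range)
  mix <- fit_mixture(all_fe, K = cfg$mixture$K, seed = cfg$seed,
                     range = cfg$mixture$range)
  report$hmm <- unclass(hmm)
  report$mixture <- unclass(mix)
  emit(unclass(hmm), "hmm_model.json")
  emit(unclass(mix), "mixture.json")

  # -- kinetics --------------------------------------------------------------
  period <- fe_frame_period(acquisition)
  dwells <- extract_dwells(paths, period, fe = fe_list,
                           molecule_ids = vapply(accepted, `[[`, 1,
                                                 "molecule_id"))
  fits <- dwell_fits(dwells, min_dwells = cfg$kinetics$min_dwells)
  tdp <- transition_density(paths, fe_list, period,
                            min_persist_frames = cfg$kinetics$min_persist_frames,
                            bin_width = cfg$kinetics$tdp_bin_width)
  pop <- population_summary(paths, period, K = cfg$hmm$K)
  report$dwell_fits <- lapply(fits, unclass)
  report$tdp <- list(n_events = tdp$n_events,
                     total_time_s = tdp$total_time_s,
                     events_per_s = tdp$n_events / tdp$total_time_s)
  report$population <- pop
  emit(dwells, "dwells.csv")
  emit(as.data.frame(tdp$density), "tdp_matrix.csv")
  emit(lapply(fits, unclass), "dwell_fits.json")
  emit(pop, "population_summary.json")

  # -- structural classification ---------------------------------------------
  fp <- forster_params(cfg$forster$R0)
  assign_tab <- state_assignments(cfg$forster$assignments, fp)
  report$state_classification <- classify_states(hmm, assign_tab, fp)
  emit(report$state_classification, "state_classification.csv")

  if (!is.null(out_dir) && isTRUE(cfg$output$plots)) {
    plot_fe_histogram(histo, mix, file.path(out_dir, "fe_histogram.png"))
    plot_transition_density(tdp, file.path(out_dir, "tdp.png"))
  }
  report$version <- as.character(utils::packageVersion("smfretr"))
  if (!is.null(out_dir))
    emit(report[setdiff(names(report), "config")], "report.json")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> mode %s: %d trajectories extracted, %d accepted\n",
              x$mode, x$n_extracted %||% NA, x$n_accepted %||% NA))
  cat(sprintf("  HMM means: %s\n",
              paste(sprintf("%.3f", x$hmm$means), collapse = ", ")))
  cat(sprintf("  occupancy: %s\n",
              paste(sprintf("%.3f", x$population$occupancy), collapse = ", ")))
  invisible(x)
}

#' Deterministic test fixtures
#'
#' Small ground-truthed datasets (at most 64 x 64 px, 400 frames and 30
#' molecules) covering the scenarios the test-suite exercises:
#'
#' * `"wt"` — rare, short-lived openings: dominant high-FRET state.
#' * `"dynamic-mutant"` — opening much faster than closing: dominant
#'   low-FRET state with frequent transitions.
#' * `"three-state"` — closed / partially open / open, three FE components.
#' * `"calibration"` — donor-only and acceptor-only fields plus a FRET
#'   field with photobleaching, for correction-factor estimation.
#'
#' @param scenario scenario name.
#' @param seed integer seed; same seed gives an identical bundle.
#' @param out_dir optional directory: movies and truth tables are written
#'   there ([write_movie()]).
#' @return list with the scenario's movies, kinetic model and ground truth.
#' @export
make_fixtures <- function(scenario = c("wt", "dynamic-mutant", "three-state",
                                       "calibration"),
                          seed = 1, out_dir = NULL) {
  scenario <- match.arg(scenario)
  acq <- acquisition_config(movie_duration = 90, image_shape = c(64, 64),
                            channel_shift = c(1.5, 0.5))
  phot <- photophysics_model(0.005, 0.005)
  bundle <- switch(scenario,
    "wt" = {
      model <- closed_open_model(k_open = 0.01, k_close = 0.5)
      list(movie = simulate_smfret_movie(model, phot, acq, 16, seed = seed),
           model = model)
    },
    "dynamic-mutant" = {
      model <- closed_open_model(k_open = 0.3, k_close = 0.05)
      list(movie = simulate_smfret_movie(model, phot, acq, 16, seed = seed),
           model = model)
    },
    "three-state" = {
      Q <- matrix(c(0, 0.1, 0,
                    0.1, 0, 0.1,
                    0, 0.1, 0), 3, 3, byrow = TRUE)
      model <- kinetic_model(Q, fe_means = c(0.25, 0.55, 0.85),
                             fe_sds = rep(0.07, 3),
                             state_names = c("open", "partial", "closed"))
      list(movie = simulate_smfret_movie(model, phot, acq, 20, seed = seed),
           model = model)
    },
    "calibration" = {
      acq_c <- acquisition_config(movie_duration = 60,
                                  image_shape = c(64, 64),
                                  channel_shift = c(1.5, 0.5),
                                  bleedthrough_alpha = 0.1,
                                  direct_excitation_delta = 0.05,
                                  gamma = 1.3)
      model <- closed_open_model(k_open = 0.05, k_close = 0.5)
      list(donor_only = simulate_smfret_movie(
             model, photophysics_model(0, 0), acq_c, 12, seed = seed,
             fraction_donor_only = 1),
           acceptor_only = simulate_smfret_movie(
             model, photophysics_model(0, 0), acq_c, 12, seed = seed + 1,
             fraction_acceptor_only = 1),
           fret = simulate_smfret_movie(
             model, photophysics_model(0.001, 0.02), acq_c, 24,
             seed = seed + 2),
           model = model, factors = correction_factors(0.1, 0.05, 1.3))
    })
  bundle$scenario <- scenario
  bundle$acquisition <- acq
  if (!is.null(out_dir)) {
    for (nm in names(bundle))
      if (is.list(bundle[[nm]]) && !is.null(bundle[[nm]]$donor))
        write_movie(bundle[[nm]], file.path(out_dir, paste0(scenario, "_", nm)))
  }
  bundle
}
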