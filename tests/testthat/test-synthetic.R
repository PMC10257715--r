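make_const_truth <- function(E, duration, dbt = Inf, abt = Inf,
                             fe_pair = c(0.8, 0.2)) {
  # constant-state path in a 2-state model whose first state has FE = E
  m <- closed_open_model(fe_closed = fe_pair[1], fe_open = fe_pair[2],
                         total_intensity = 1000)
  m$fe_means[1] <- E
  list(id = 1, x = 10, y = 10, n_donor = 1, n_acceptor = 1,
       path = structure(data.frame(state = 1, t_start = 0, t_end = duration),
                        class = c("state_path", "data.frame")),
       donor_bleach_times = dbt, acceptor_bleach_times = abt,
       model = m)
}

test_that("emitted intensities follow the stated forward model", {
  acq0 <- acquisition_config(bleedthrough_alpha = 0, gamma = 1,
                             direct_excitation_delta = 0,
                             movie_duration = 3)
  tr <- make_const_truth(0.5, 3)
  I <- emit_intensities(tr, tr$model, acq0)
  on532 <- I$excitation == 532
  expect_equal(I$donor[on532], rep(500, sum(on532)))
  expect_equal(I$acceptor[on532], rep(500, sum(on532)))

  # bleedthrough only: E = 0 puts 10% of the donor signal in the acceptor
  acq_a <- acquisition_config(bleedthrough_alpha = 0.1, gamma = 1,
                              direct_excitation_delta = 0, movie_duration = 3)
  tr0 <- make_const_truth(0, 3, fe_pair = c(0.8, 0))
  tr0$model$fe_means <- c(0.8, 0); tr0$path$state <- 2
  I0 <- emit_intensities(tr0, tr0$model, acq_a)
  expect_equal(I0$donor[on532], rep(1000, sum(on532)))
  expect_equal(I0$acceptor[on532], rep(100, sum(on532)))

  # direct excitation rides on the 641 nm acceptor brightness
  acq_d <- acquisition_config(bleedthrough_alpha = 0, gamma = 1,
                              direct_excitation_delta = 0.05,
                              movie_duration = 3)
  I_d <- emit_intensities(tr, tr$model, acq_d)
  expect_equal(I_d$acceptor[on532], rep(500 + 0.05 * 1000, sum(on532)))
  expect_equal(I_d$acceptor[!on532], rep(1000, sum(!on532)))
})

test_that("acceptor bleach recovers the full donor signal (factor 1/(1-E))", {
  acq <- acquisition_config(bleedthrough_alpha = 0, gamma = 1,
                            direct_excitation_delta = 0, movie_duration = 6)
  # acceptor bleaches exactly between frames at t = 3 s; E = 0.8 before
  tr <- make_const_truth(0.8, 6, abt = 3)
  I <- emit_intensities(tr, tr$model, acq)
  pre <- I$excitation == 532 & I$time + acq$exposure <= 3
  post <- I$excitation == 532 & I$time >= 3
  expect_equal(unique(I$donor[pre]), 200)
  expect_equal(unique(I$donor[post]), 1000)
  expect_equal(unique(I$donor[post]) / unique(I$donor[pre]), 1 / (1 - 0.8))
  expect_equal(I$acceptor[post], rep(0, sum(post)))
  # after donor bleach the FRET signal ceases entirely
  tr_d <- make_const_truth(0.8, 6, dbt = 3)
  I_d <- emit_intensities(tr_d, tr_d$model, acq)
  expect_equal(I_d$donor[post], rep(0, sum(post)))
  expect_equal(I_d$acceptor[post], rep(0, sum(post)))
})

test_that("rendering conserves photons and respects the seed", {
  acq <- acquisition_config(movie_duration = 0.75, image_shape = c(32, 32),
                            background = 10, read_noise_sd = 0)
  truth <- make_const_truth(0.5, 0.75)
  truth$x <- 15; truth$y <- 13.5
  truth$intensities <- emit_intensities(truth, truth$model, acq)

  # noiseless: integrated spot mass equals the ideal intensity
  mv0 <- render_movie(list(truth), acq, seed = 1, noise = FALSE)
  frame1 <- mv0$donor[, , 1] - acq$background
  expect_equal(sum(frame1), truth$intensities$donor[1], tolerance = 1e-6)

  # empty field: mean pixel value = background within 3 SE
  mv_bg <- render_movie(list(), acq, seed = 2, noise = TRUE)
  n_px <- length(mv_bg$donor[, , 1])
  expect_lt(abs(mean(mv_bg$donor[, , 1]) - 10), 3 * sqrt(10 / n_px))

  # Monte-Carlo photon conservation: expected integrated counts = ideal
  sums <- vapply(1:40, function(s) {
    mv <- render_movie(list(truth), acq, seed = s, noise = TRUE)
    sum(mv$donor[, , 1]) - acq$background * n_px
  }, numeric(1))
  ideal <- truth$intensities$donor[1]
  se <- stats::sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - ideal), 3 * se)

  # determinism: same seed, bit-identical stacks
  mv_a <- render_movie(list(truth), acq, seed = 9)
  mv_b <- render_movie(list(truth), acq, seed = 9)
  expect_identical(mv_a$donor, mv_b$donor)
  expect_identical(mv_a$acceptor, mv_b$acceptor)
})

test_that("close molecules are flagged as collisions but kept", {
  acq <- acquisition_config(movie_duration = 0.75, image_shape = c(32, 32))
  t1 <- make_const_truth(0.5, 0.75); t1$x <- 15; t1$y <- 15
  t2 <- make_const_truth(0.5, 0.75); t2$x <- 17; t2$y <- 15; t2$id <- 2
  t1$intensities <- emit_intensities(t1, t1$model, acq)
  t2$intensities <- emit_intensities(t2, t2$model, acq)
  expect_warning(mv <- render_movie(list(t1, t2), acq, seed = 1),
                 "collision")
  expect_equal(nrow(mv$molecules), 2)
  expect_true(all(mv$molecules$collision))
})

test_that("frame-level FE generator hits the requested mixture and kinetics", {
  d <- simulate_fe_dataset(150, c(0.3, 0.8), 0.05, c(0.9, 0.9),
                           frame_period = 0.25, movie_duration = 100,
                           bleach_rate = 0, seed = 8)
  s <- unlist(d$states); x <- unlist(d$fe)
  # symmetric chain: occupancy 1/2 each
  expect_lt(abs(mean(s == 1) - 0.5), 0.02)
  expect_lt(abs(mean(x[s == 2]) - 0.8), 0.005)
  # per-frame stay frequency matches the requested stay probability
  stays <- unlist(lapply(d$states, function(z)
    if (length(z) > 1) diff(z) == 0 else logical(0)))
  expect_lt(abs(mean(stays) - 0.9), 0.01)
  # seeded reproducibility
  d2 <- simulate_fe_dataset(150, c(0.3, 0.8), 0.05, c(0.9, 0.9),
                            frame_period = 0.25, movie_duration = 100,
                            bleach_rate = 0, seed = 8)
  expect_identical(d, d2)
})
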