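test_that("aperture photometry recovers spot mass and is deterministic", {
  acq <- acquisition_config(movie_duration = 1.5, image_shape = c(32, 32),
                            background = 20, read_noise_sd = 0,
                            channel_shift = c(0, 0))
  m <- closed_open_model(total_intensity = 1000)
  path <- structure(data.frame(state = 1, t_start = 0, t_end = 1.5),
                    class = c("state_path", "data.frame"))
  truth <- list(id = 1, x = 15, y = 15, n_donor = 1, n_acceptor = 1,
                path = path, donor_bleach_times = Inf,
                acceptor_bleach_times = Inf)
  truth$intensities <- emit_intensities(truth, m, acq)
  mv <- render_movie(list(truth), acq, seed = 1, noise = FALSE)
  tr <- extract_traces(mv, 15, 15, aperture_radius_px = 4)
  # acceptor on 532 carries FRET + bleedthrough + direct excitation
  ideal_a <- truth$intensities$acceptor[truth$intensities$excitation == 532][1]
  expect_lt(abs(tr$I_A[1] - ideal_a) / ideal_a, 0.02)
  ideal_d <- truth$intensities$donor[truth$intensities$excitation == 532][1]
  expect_lt(abs(tr$I_D[1] - ideal_d) / ideal_d, 0.02)

  # empty field: traces are zero-mean
  mv0 <- render_movie(list(), acq, seed = 2, noise = TRUE)
  tr0 <- extract_traces(mv0, 15, 15)
  expect_lt(abs(mean(tr0$I_D)), 3 * stats::sd(tr0$I_D) / sqrt(length(tr0$I_D)) + 3)

  # determinism
  tr_a <- extract_traces(mv, 15, 15)
  tr_b <- extract_traces(mv, 15, 15)
  expect_identical(tr_a, tr_b)

  # off-image aperture is rejected with reason "edge"
  tr_e <- extract_traces(mv, 2, 2)
  expect_equal(tr_e$qc_reason, "edge")
})

test_that("correction and FE computation handle the canonical cases", {
  id1 <- correction_factors(0, 0, 1)
  tr <- synthetic_trajectory(rep(0.5, 30), alpha = 0, delta = 0, gamma = 1,
                             I_tot = 200)
  tr <- correct_and_compute_fe(tr, id1)
  expect_equal(tr$fe, rep(0.5, 30))

  # I_A = 0 -> FE = 0
  tr0 <- synthetic_trajectory(rep(0, 30), alpha = 0, delta = 0, gamma = 1,
                              A641 = 0)
  tr0 <- correct_and_compute_fe(tr0, id1)
  expect_equal(tr0$fe, rep(0, 30))

  # zero denominator -> NA, not an error
  tr_na <- synthetic_trajectory(rep(0, 5), alpha = 0, delta = 0, gamma = 1,
                                I_tot = 0, A641 = 0)
  tr_na <- correct_and_compute_fe(tr_na, id1)
  expect_true(all(is.na(tr_na$fe)))

  expect_error(correction_factors(alpha = 1.2), "alpha")
  expect_error(correction_factors(gamma = 0), "gamma")
})

test_that("three-factor correction inverts the forward model exactly", {
  set.seed(5)
  E_true <- sample(c(0.2, 0.35, 0.8), 200, replace = TRUE)
  tr <- synthetic_trajectory(E_true, alpha = 0.1, delta = 0.05, gamma = 1.3)
  tr <- correct_and_compute_fe(tr, correction_factors(0.1, 0.05, 1.3))
  expect_lt(max(abs(tr$fe - E_true)), 1e-9)

  # constant high-FRET: mean corrected FE equals the true state FE
  tr8 <- synthetic_trajectory(rep(0.8, 100), alpha = 0.1, delta = 0.05,
                              gamma = 1.3)
  tr8 <- correct_and_compute_fe(tr8, correction_factors(0.1, 0.05, 1.3))
  expect_equal(mean(tr8$fe), 0.8, tolerance = 1e-6)
})

test_that("correction factors are recovered from calibration fields", {
  fx <- cached_fixture("calibration", function()
    suppressWarnings(make_fixtures("calibration", seed = 5)))
  grab <- function(mv) {
    det <- suppressWarnings(detect_pairs(mv, threshold_k = 5))
    lapply(seq_len(nrow(det$pairs)), function(i)
      extract_traces(mv, det$pairs$x_donor[i], det$pairs$y_donor[i],
                     shift = as.numeric(det$shift), molecule_id = i))
  }
  # donor-only molecules are invisible in the 641 nm channel; pick them in
  # the donor channel instead and carry positions over
  don_img <- average_first_frames(fx$donor_only, "donor")
  don_picks <- pick_particles(don_img)
  donor_trs <- lapply(seq_len(nrow(don_picks)), function(i)
    extract_traces(fx$donor_only, don_picks$x[i], don_picks$y[i],
                   shift = c(1.5, 0.5), molecule_id = i))
  acc_trs <- grab(fx$acceptor_only)
  fret_trs <- grab(fx$fret)
  est <- suppressWarnings(
    estimate_corrections(donor_trs, acc_trs, fret_trs, fallback_gamma = 1.3))
  expect_lt(abs(est$alpha - 0.1), 0.01)
  expect_lt(abs(est$delta - 0.05), 0.01)
  expect_lt(abs(est$gamma - 1.3), 0.13)

  # single noiseless donor-only trace with I_A = 0.2 * I_D: alpha exact
  d1 <- synthetic_trajectory(rep(0, 50), alpha = 0.2, delta = 0, gamma = 1,
                             A641 = 0)
  a1 <- synthetic_trajectory(rep(0.5, 50), alpha = 0, delta = 0.3, gamma = 1)
  a1$I_D <- rep(0, 50); a1$I_A <- 0.3 * a1$I_A_641
  est2 <- suppressWarnings(estimate_corrections(list(d1), list(a1)))
  expect_equal(est2$alpha, 0.2)
  expect_equal(est2$delta, 0.3)
})

test_that("bleach steps are located and counted; traces truncate at the earliest", {
  # noiseless acceptor step 1000 -> 0 at 641-frame 57
  tr <- synthetic_trajectory(rep(0.5, 120), alpha = 0, delta = 0, gamma = 1)
  tr$raw641 <- c(rep(1000, 56), rep(0, 64))
  tr <- detect_bleach(tr, gamma = 1)
  expect_equal(tr$acceptor_steps, 1)
  # 641-frame 57 occurs at t641[57]; usable 532 frames precede it
  expect_equal(tr$truncation_time, tr$t641[57])
  expect_equal(tr$truncation_frame, 56)

  # constant traces: no steps, truncation at movie end
  tr_c <- synthetic_trajectory(rep(0.5, 60), alpha = 0, delta = 0, gamma = 1)
  tr_c <- detect_bleach(tr_c, gamma = 1)
  expect_equal(tr_c$acceptor_steps, 0)
  expect_equal(tr_c$donor_steps, 0)
  expect_equal(tr_c$truncation_frame, 60)

  # two acceptor steps 2000 -> 1000 -> 0
  tr2 <- synthetic_trajectory(rep(0.5, 120), alpha = 0, delta = 0, gamma = 1)
  tr2$raw641 <- c(rep(2000, 40), rep(1000, 40), rep(0, 40))
  tr2 <- detect_bleach(tr2, gamma = 1)
  expect_equal(tr2$acceptor_steps, 2)

  # donor bleach shows as a step in the state-free total intensity
  E <- rep(c(0.8, 0.3), each = 30)
  tr_d <- synthetic_trajectory(c(E, E), alpha = 0, delta = 0, gamma = 1)
  tr_d$I_D[61:120] <- 0; tr_d$I_A[61:120] <- 0
  tr_d <- detect_bleach(tr_d, gamma = 1)
  expect_equal(tr_d$donor_steps, 1)
  expect_equal(tr_d$truncation_frame, 60)
})

test_that("QC rejects multi-fluorophore and acceptor-dark trajectories", {
  ok <- synthetic_trajectory(rep(0.5, 60))
  ok$raw641 <- c(rep(1000, 40), rep(0, 20))
  ok <- qc_trajectory(detect_bleach(
    correct_and_compute_fe(ok, correction_factors(0.1, 0.05, 1.3))))
  expect_equal(ok$qc_status, "accepted")

  multi <- synthetic_trajectory(rep(0.5, 90))
  multi$raw641 <- c(rep(2000, 30), rep(1000, 30), rep(0, 30))
  multi <- qc_trajectory(detect_bleach(
    correct_and_compute_fe(multi, correction_factors(0.1, 0.05, 1.3))))
  expect_equal(multi$qc_status, "rejected")
  expect_equal(multi$qc_reason, "multi_fluorophore")

  dark <- synthetic_trajectory(rep(0, 60), alpha = 0, delta = 0, gamma = 1,
                               A641 = 0)
  set.seed(1)
  dark$raw641 <- stats::rnorm(60, 0, 20)
  dark$I_A_641 <- dark$raw641
  dark <- qc_trajectory(detect_bleach(
    correct_and_compute_fe(dark, correction_factors(0, 0, 1))))
  expect_equal(dark$qc_reason, "no_acceptor")

  short <- synthetic_trajectory(rep(0.5, 25))
  short$raw641 <- c(rep(1000, 8), rep(0, 17))
  short <- qc_trajectory(detect_bleach(
    correct_and_compute_fe(short, correction_factors(0.1, 0.05, 1.3))))
  expect_equal(short$qc_reason, "too_short")

  expect_error(qc_trajectory(synthetic_trajectory(rep(0.5, 30))),
               "detect_bleach")
})

test_that("a doubly-labeled subpopulation is rejected at its true rate", {
  set.seed(31)
  n <- 400
  is_double <- stats::runif(n) < 0.05
  trajs <- lapply(seq_len(n), function(i) {
    tr <- synthetic_trajectory(rep(0.5, 90), molecule_id = i)
    bleach1 <- sample(30:60, 1)
    if (is_double[i]) {
      bleach2 <- sample(61:80, 1)
      tr$raw641 <- c(rep(2000, bleach1), rep(1000, bleach2 - bleach1),
                     rep(0, 90 - bleach2))
    } else {
      tr$raw641 <- c(rep(1000, bleach1), rep(0, 90 - bleach1))
    }
    tr$raw641 <- tr$raw641 + stats::rnorm(90, 0, 25)
    tr$I_A_641 <- tr$raw641
    qc_trajectory(detect_bleach(
      correct_and_compute_fe(tr, correction_factors(0.1, 0.05, 1.3))))
  })
  rej <- vapply(trajs, function(tr)
    identical(tr$qc_reason, "multi_fluorophore"), logical(1))
  p_hat <- mean(rej)
  expect_lt(abs(p_hat - mean(is_double)), 3 * sqrt(0.05 * 0.95 / n))
  # bookkeeping: acceptance + rejection fractions sum to one
  qs <- qc_summary(trajs)
  expect_equal(qs$fraction_accepted + sum(qs$fraction_rejected), 1)
})

test_that("usable FE stops at truncation and the table flags pre-truncation rows", {
  tr <- synthetic_trajectory(rep(0.5, 60))
  tr$raw641 <- c(rep(1000, 40), rep(0, 20))
  tr <- detect_bleach(
    correct_and_compute_fe(tr, correction_factors(0.1, 0.05, 1.3)))
  expect_equal(length(usable_fe(tr)), tr$truncation_frame)
  tab <- trajectory_table(list(tr))
  expect_equal(sum(tab$pre_truncation), tr$truncation_frame)
  expect_named(tab, c("molecule_id", "frame", "time_s", "excitation_nm",
                      "I_D", "I_A", "I_A_641", "FE", "pre_truncation"))
})
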