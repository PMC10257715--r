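test_that("frame averaging is an exact per-pixel mean", {
  mv <- list(donor = array(7, c(4, 4, 9)), acceptor = array(0, c(4, 4, 9)),
             excitation = rep(c(532, 532, 641), 3))
  expect_equal(average_first_frames(mv, "donor"), matrix(7, 4, 4))

  mv$donor[, , 1] <- 0; mv$donor[, , 2] <- 10
  expect_equal(average_first_frames(mv, "donor", n_frames = 2),
               matrix(5, 4, 4))

  set.seed(1)
  mv$acceptor <- array(stats::rnorm(4 * 4 * 9), c(4, 4, 9))
  idx <- which(mv$excitation == 641)[1:3]
  manual <- (mv$acceptor[, , idx[1]] + mv$acceptor[, , idx[2]] +
               mv$acceptor[, , idx[3]]) / 3
  expect_equal(average_first_frames(mv, "acceptor", n_frames = 3), manual)
  expect_error(average_first_frames(mv, "acceptor", n_frames = 5), "only 3")
})

test_that("particle picking finds well-separated emitters and suppresses close ones", {
  expect_equal(nrow(pick_particles(matrix(5, 48, 48))), 0)

  # two rendered emitters 20 px apart at high SNR
  img <- matrix(10, 48, 48)
  img <- smfretr:::add_psf(img, 12, 14, 800, 1.3)
  img <- smfretr:::add_psf(img, 32, 14, 800, 1.3)
  set.seed(2)
  img <- matrix(stats::rpois(length(img), img), nrow(img))
  p <- pick_particles(img)
  expect_equal(nrow(p), 2)
  d1 <- min(sqrt((p$x - 12)^2 + (p$y - 14)^2))
  d2 <- min(sqrt((p$x - 32)^2 + (p$y - 14)^2))
  expect_lt(max(d1, d2), 1)

  # 1 px apart with min_separation 5: exactly one survives suppression
  img2 <- matrix(10, 48, 48)
  img2 <- smfretr:::add_psf(img2, 20, 20, 800, 1.3)
  img2 <- smfretr:::add_psf(img2, 21, 20, 800, 1.3)
  p2 <- pick_particles(img2, min_separation_px = 5)
  expect_equal(nrow(p2), 1)
})

test_that("channel registration recovers translations to sub-pixel accuracy", {
  set.seed(3)
  base <- gaussian_blur(matrix(stats::runif(64 * 64), 64, 64), 2)
  expect_equal(as.numeric(estimate_channel_shift(base, base)), c(0, 0))

  # integer translation by (dx, dy) = (3, -2)
  shifted <- matrix(stats::median(base), 64, 64)
  for (i in 1:64) for (j in 1:64) {
    si <- i - (-2); sj <- j - 3
    if (si >= 1 && si <= 64 && sj >= 1 && sj <= 64)
      shifted[i, j] <- base[si, sj]
  }
  est <- estimate_channel_shift(base, shifted)
  expect_equal(round(as.numeric(est)), c(3, -2))

  # simulator movie with sub-pixel channel shift (1.5, 0.5)
  mv <- cached_fixture("grid_movie", grid_movie)
  img_d <- average_first_frames(mv, "donor")
  img_a <- average_first_frames(mv, "acceptor")
  est2 <- estimate_channel_shift(img_d, img_a)
  expect_lt(abs(est2[["dx"]] - 1.5), 0.2)
  expect_lt(abs(est2[["dy"]] - 0.5), 0.2)
})

test_that("matching respects the 1.25 px threshold", {
  don <- data.frame(x = 10, y = 10)
  acc <- data.frame(x = 10.5, y = 11.0)
  m <- match_particles(don, acc)
  expect_equal(nrow(m), 1)
  expect_equal(m$displacement, sqrt(0.5^2 + 1^2))  # 1.118 <= 1.25

  m2 <- match_particles(don, data.frame(x = 11, y = 11))
  expect_equal(nrow(m2), 0)  # sqrt(2) = 1.414 > 1.25

  expect_equal(nrow(match_particles(don, data.frame(x = numeric(0),
                                                    y = numeric(0)))), 0)
})

test_that("matching is symmetric and equals the brute-force mutual-NN oracle", {
  set.seed(14)
  for (rep in 1:25) {
    nd <- sample(0:20, 1); na <- sample(0:20, 1)
    don <- data.frame(x = stats::runif(nd, 0, 30), y = stats::runif(nd, 0, 30))
    acc <- data.frame(x = stats::runif(na, 0, 30), y = stats::runif(na, 0, 30))
    got <- match_particles(don, acc)
    oracle <- brute_force_match(don, acc)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got) > 0) {
      got_set <- got[order(got$donor_idx), c("donor_idx", "acceptor_idx")]
      ora_set <- oracle[order(oracle[, 1]), , drop = FALSE]
      expect_equal(unname(as.matrix(got_set)), unname(ora_set))
    }
    # symmetry: swap channels, pairs flip
    rev <- match_particles(acc, don)
    expect_equal(nrow(rev), nrow(got))
    if (nrow(got) > 0) {
      rev_set <- rev[order(rev$acceptor_idx), c("acceptor_idx", "donor_idx")]
      expect_equal(unname(as.matrix(rev_set)), unname(as.matrix(got_set)))
    }
  }
})

test_that("spot fits recover width, ellipticity and the overlap signature", {
  img <- matrix(5, 21, 21)
  img <- smfretr:::add_psf(img, 10, 10, 1000, 1.3)
  f <- fit_spot(img, c(10, 10), window_px = 11)
  expect_true(f$converged)
  expect_equal(f$sigma_x, 1.3, tolerance = 1e-3)
  expect_equal(f$sigma_y, 1.3, tolerance = 1e-3)
  expect_lt(abs(f$ellipticity_0 - 1), 0.01)
  expect_lt(abs(f$ellipticity_45 - 1), 0.05)  # interpolation tolerance

  # anisotropic Gaussian, sigma (1.0, 1.5): ellipticity_0 = 1.5
  yy <- matrix(rep(0:20, 21), 21, 21)
  xx <- t(yy)
  img_e <- 5 + 80 * exp(-((xx - 10)^2 / (2 * 1^2) + (yy - 10)^2 / (2 * 1.5^2)))
  f_e <- fit_spot(img_e, c(10, 10), window_px = 11)
  expect_equal(f_e$ellipticity_0, 1.5, tolerance = 0.01)

  # two overlapping emitters 2 px apart elongate the apparent spot
  img_o <- matrix(5, 21, 21)
  img_o <- smfretr:::add_psf(img_o, 9, 10, 800, 1.3)
  img_o <- smfretr:::add_psf(img_o, 11, 10, 800, 1.3)
  f_o <- fit_spot(img_o, c(10, 10), window_px = 11)
  expect_gt(max(f_o$ellipticity_0, f_o$ellipticity_45), 1.2)

  expect_error(fit_spot(img, c(1, 1), window_px = 11), "outside")
})

test_that("ellipticity filter bounds are inclusive", {
  mk <- function(e0, e45) structure(list(ellipticity_0 = e0,
                                         ellipticity_45 = e45,
                                         converged = TRUE),
                                    class = "spot_fit")
  expect_true(ellipticity_filter(mk(1.05, 1.1)))
  expect_false(ellipticity_filter(mk(1.05, 1.3)))
  expect_true(ellipticity_filter(mk(1.0, 1.0)))
  expect_true(ellipticity_filter(mk(1.2, 1.2)))
  expect_false(ellipticity_filter(structure(list(converged = FALSE),
                                            class = "spot_fit")))
})

test_that("detection achieves high recall and precision on a clean field", {
  mv <- cached_fixture("grid_movie", grid_movie)
  truth <- mv$molecules[!mv$molecules$collision, ]
  det <- detect_pairs(mv)
  got <- det$pairs
  hits <- 0
  for (i in seq_len(nrow(got))) {
    d <- sqrt((truth$x - got$x_donor[i])^2 + (truth$y - got$y_donor[i])^2)
    if (min(d) <= 1) hits <- hits + 1
  }
  recall <- hits / nrow(truth)
  precision <- hits / nrow(got)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
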