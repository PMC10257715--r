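# -- small image primitives (edge-replicated) --------------------------------

pad_replicate <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1, r), seq_len(h), rep(h, r))
  ci <- c(rep(1, r), seq_len(w), rep(w, r))
  img[ri, ci]
}

#' Separable Gaussian smoothing of an image
#' @param img numeric matrix.
#' @param sigma kernel SD in pixels.
#' @return smoothed matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  P <- pad_replicate(img, r)
  tmp <- matrix(0, h, w + 2 * r)
  for (j in seq_along(k))  # convolve rows
    tmp <- tmp + k[j] * P[(j - 1) + seq_len(h), ]
  out <- matrix(0, h, w)
  for (j in seq_along(k))  # convolve cols
    out <- out + k[j] * tmp[, (j - 1) + seq_len(w)]
  out
}

# Rolling-median background estimate (square window of halfwidth r).
rolling_median_bg <- function(img, r = 7) {
  h <- nrow(img); w <- ncol(img)
  P <- pad_replicate(img, r)
  n <- (2 * r + 1)^2
  stack <- matrix(0, h * w, n)
  idx <- 1
  for (dy in -r:r) for (dx in -r:r) {
    stack[, idx] <- as.vector(P[r + dy + seq_len(h), r + dx + seq_len(w)])
    idx <- idx + 1
  }
  matrix(apply(stack, 1, stats::median), h, w)
}

# Grayscale max filter over a square window of halfwidth r.
max_filter <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  P <- pad_replicate(img, r)
  out <- matrix(-Inf, h, w)
  for (dy in -r:r) for (dx in -r:r)
    out <- pmax(out, P[r + dy + seq_len(h), r + dx + seq_len(w)])
  out
}

# -- operations ---------------------------------------------------------------

#' Average the first frames of one channel of a movie
#'
#' Particle picking operates on an averaged stack of the first few frames of
#' the movie (default five) restricted to the excitation type that lights up
#' the requested channel (641 nm for the acceptor channel, 532 nm for donor).
#'
#' @param movie a movie list as returned by [render_movie()] (`donor` /
#'   `acceptor` arrays plus per-frame `excitation` labels).
#' @param channel `"acceptor"` or `"donor"`.
#' @param n_frames number of frames to average.
#' @param excitation excitation label selecting frames; defaults to 641 for
#'   the acceptor channel and 532 for the donor channel.
#' @return averaged image (matrix).
#' @export
average_first_frames <- function(movie, channel = c("acceptor", "donor"),
                                 n_frames = 5, excitation = NULL) {
  channel <- match.arg(channel)
  if (is.null(excitation))
    excitation <- if (channel == "acceptor") 641 else 532
  idx <- which(movie$excitation == excitation)
  if (length(idx) < n_frames)
    stop(sprintf("channel '%s' has only %d frames of %d nm excitation (need %d)",
                 channel, length(idx), excitation, n_frames))
  idx <- idx[seq_len(n_frames)]
  stack <- movie[[channel]][, , idx, drop = FALSE]
  apply(stack, c(1, 2), mean)
}

#' Pick particle candidates as intensity peaks
#'
#' The image is Gaussian-smoothed and background-subtracted (rolling median),
#' then local maxima above `median + threshold_k * MAD` are kept, with
#' non-maximum suppression at `min_separation_px`. Sub-pixel positions come
#' from a 3x3 centroid around each peak.
#'
#' @param image 2D numeric matrix.
#' @param min_separation_px minimum peak separation, pixels.
#' @param threshold_k MAD multiplier for the detection threshold.
#' @param smooth_sigma denoising kernel SD, pixels.
#' @param bg_halfwidth halfwidth of the rolling-median background window.
#' @return data.frame of particles sorted by descending peak intensity:
#'   `x`, `y` (0-based pixel-center coordinates), `peak` (counts above
#'   background).
#' @export
pick_particles <- function(image, min_separation_px = 5, threshold_k = 5,
                           smooth_sigma = 1, bg_halfwidth = 7) {
  sm <- gaussian_blur(image, smooth_sigma)
  bg <- rolling_median_bg(sm, bg_halfwidth)
  sub <- sm - bg
  thr <- stats::median(sub) + threshold_k * stats::mad(sub)
  r <- max(1L, floor(min_separation_px))
  is_max <- sub >= max_filter(sub, r) & sub > thr
  if (!any(is_max))
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0)))
  peaks <- which(is_max, arr.ind = TRUE)
  vals <- sub[is_max]
  ord <- order(vals, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]; vals <- vals[ord]
  # non-maximum suppression by descending intensity
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1):nrow(peaks)
      d2 <- (peaks[later, 1] - peaks[i, 1])^2 + (peaks[later, 2] - peaks[i, 2])^2
      keep[later][d2 < min_separation_px^2] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]; vals <- vals[keep]
  # 3x3 centroid refinement on the background-subtracted image
  h <- nrow(sub); w <- ncol(sub)
  xs <- ys <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ry <- peaks[i, 1]; cx <- peaks[i, 2]
    yy <- max(1, ry - 1):min(h, ry + 1)
    xx <- max(1, cx - 1):min(w, cx + 1)
    wts <- pmax(sub[yy, xx, drop = FALSE], 0)
    if (sum(wts) == 0) wts[] <- 1
    ys[i] <- sum(outer(yy - 1, rep(1, length(xx))) * wts) / sum(wts)
    xs[i] <- sum(outer(rep(1, length(yy)), xx - 1) * wts) / sum(wts)
  }
  data.frame(x = xs, y = ys, peak = vals)
}

#' Estimate the donor-to-acceptor channel shift by image correlation
#'
#' Finds the integer translation of the acceptor image that maximizes the
#' normalized cross-correlation with the donor image inside
#' `search_radius_px`, then refines it to sub-pixel precision with a
#' quadratic fit around the optimum. The returned `(dx, dy)` maps
#' donor-channel coordinates to acceptor-channel coordinates (a feature at
#' donor `(x, y)` sits at acceptor `(x + dx, y + dy)`); subtract it from
#' acceptor coordinates to bring them into the donor frame.
#'
#' @param donor_image,acceptor_image equally sized matrices.
#' @param search_radius_px maximum |shift| searched per axis, pixels.
#' @return numeric `c(dx, dy)` with attribute `reliable` (FALSE when the
#'   correlation peak sat on the search boundary, with a warning).
#' @export
estimate_channel_shift <- function(donor_image, acceptor_image,
                                   search_radius_px = 5) {
  if (!all(dim(donor_image) == dim(acceptor_image)))
    stop("images must have equal shapes")
  h <- nrow(donor_image); w <- ncol(donor_image)
  r <- as.integer(search_radius_px)
  cc <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)  # [dy + r + 1, dx + r + 1]
  for (dy in -r:r) for (dx in -r:r) {
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    a <- donor_image[ys - dy, xs - dx]
    b <- acceptor_image[ys, xs]
    cc[dy + r + 1, dx + r + 1] <- stats::cor(as.vector(a), as.vector(b))
  }
  best <- unname(which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ])
  dy0 <- best[1] - r - 1; dx0 <- best[2] - r - 1
  reliable <- TRUE
  if (abs(dy0) == r || abs(dx0) == r) {
    warning("correlation peak on search boundary; shift estimate unreliable")
    reliable <- FALSE
  }
  refine <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (!is.finite(den) || den >= 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  ddx <- ddy <- 0
  if (abs(dx0) < r)
    ddx <- refine(cc[best[1], best[2] - 1], cc[best[1], best[2]],
                  cc[best[1], best[2] + 1])
  if (abs(dy0) < r)
    ddy <- refine(cc[best[1] - 1, best[2]], cc[best[1], best[2]],
                  cc[best[1] + 1, best[2]])
  structure(c(dx = dx0 + ddx, dy = dy0 + ddy), reliable = reliable)
}

#' Match donor and acceptor particles by mutual nearest neighbours
#'
#' Particles from the two channels (already mapped into the donor coordinate
#' frame) are paired when each is the other's nearest neighbour and their
#' centroids are displaced by no more than `max_displacement` pixels. Ties
#' are broken by smaller displacement, then lower particle index.
#'
#' @param donor_particles,acceptor_particles data.frames with `x`, `y`
#'   columns in the same (donor) coordinate frame.
#' @param max_displacement pairing tolerance, pixels (default 1.25).
#' @return data.frame with one row per pair: `donor_idx`, `acceptor_idx`,
#'   `x_donor`, `y_donor`, `x_acceptor`, `y_acceptor`, `displacement`.
#' @export
match_particles <- function(donor_particles, acceptor_particles,
                            max_displacement = 1.25) {
  nd <- nrow(donor_particles); na <- nrow(acceptor_particles)
  empty <- data.frame(donor_idx = integer(0), acceptor_idx = integer(0),
                      x_donor = numeric(0), y_donor = numeric(0),
                      x_acceptor = numeric(0), y_acceptor = numeric(0),
                      displacement = numeric(0))
  if (nd == 0 || na == 0) return(empty)
  D <- sqrt(outer(donor_particles$x, acceptor_particles$x, "-")^2 +
            outer(donor_particles$y, acceptor_particles$y, "-")^2)
  nn_of_donor <- apply(D, 1, which.min)
  nn_of_acceptor <- apply(D, 2, which.min)
  di <- which(nn_of_acceptor[nn_of_donor] == seq_len(nd))
  ai <- nn_of_donor[di]
  disp <- D[cbind(di, ai)]
  ok <- disp <= max_displacement
  di <- di[ok]; ai <- ai[ok]; disp <- disp[ok]
  ord <- order(disp, di)
  data.frame(donor_idx = di[ord], acceptor_idx = ai[ord],
             x_donor = donor_particles$x[di[ord]],
             y_donor = donor_particles$y[di[ord]],
             x_acceptor = acceptor_particles$x[ai[ord]],
             y_acceptor = acceptor_particles$y[ai[ord]],
             displacement = disp[ord])
}

# Rotate a square window by `angle` degrees about its center (bilinear
# interpolation; samples falling outside the window take its median).
rotate_window <- function(win, angle = 45) {
  n <- nrow(win); m <- ncol(win)
  c0 <- (n + 1) / 2; c1 <- (m + 1) / 2
  th <- -angle * pi / 180  # inverse mapping
  fill <- stats::median(win)
  out <- matrix(fill, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    dy <- i - c0; dx <- j - c1
    sy <- c0 + dy * cos(th) + dx * sin(th)
    sx <- c1 - dy * sin(th) + dx * cos(th)
    y0 <- floor(sy); x0 <- floor(sx)
    if (y0 < 1 || x0 < 1 || y0 + 1 > n || x0 + 1 > m) next
    fy <- sy - y0; fx <- sx - x0
    out[i, j] <- (1 - fy) * ((1 - fx) * win[y0, x0] + fx * win[y0, x0 + 1]) +
      fy * ((1 - fx) * win[y0 + 1, x0] + fx * win[y0 + 1, x0 + 1])
  }
  out
}

# Elliptical Gaussian least-squares fit on a window (rows = y, cols = x,
# coordinates local 0-based). Returns NULL on non-convergence.
fit_gauss2d <- function(win) {
  n <- nrow(win); m <- ncol(win)
  yy <- matrix(rep(0:(n - 1), m), n, m)
  xx <- matrix(rep(0:(m - 1), each = n), n, m)
  b0 <- stats::median(win)
  a0 <- max(win) - b0
  if (a0 <= 0) return(NULL)
  wpos <- pmax(win - b0, 0)
  x0 <- sum(xx * wpos) / sum(wpos); y0 <- sum(yy * wpos) / sum(wpos)
  s0 <- sqrt(max(0.3, sum(((xx - x0)^2 + (yy - y0)^2) * wpos) / (2 * sum(wpos))))
  obj <- function(p) {
    mu <- p[6] + p[1] * exp(-((xx - p[2])^2 / (2 * p[4]^2) +
                              (yy - p[3])^2 / (2 * p[5]^2)))
    sum((win - mu)^2)
  }
  fit <- try(stats::optim(c(a0, x0, y0, s0, s0, b0), obj, method = "L-BFGS-B",
                          lower = c(1e-6, -1, -1, 0.2, 0.2, -Inf),
                          upper = c(Inf, m, n, m, n, Inf),
                          control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- list(par = c(a0, x0, y0, s0, s0, b0), convergence = 1)
  if (fit$convergence != 0) {
    # L-BFGS-B line search can abort near the optimum; polish simplex-style
    fit2 <- try(stats::optim(fit$par, obj,
                             control = list(maxit = 2000)), silent = TRUE)
    if (inherits(fit2, "try-error") || fit2$convergence != 0) return(NULL)
    fit <- fit2
    fit$par[4:5] <- abs(fit$par[4:5])
    if (any(fit$par[4:5] < 0.2) || fit$par[1] <= 0) return(NULL)
  }
  p <- fit$par
  list(amplitude = p[1], x = p[2], y = p[3], sigma_x = p[4], sigma_y = p[5],
       background = p[6],
       residual_sd = sqrt(fit$value / max(1, n * m - 6)))
}

#' Fit an elliptical 2D Gaussian to a particle image
#'
#' Least-squares fit of an elliptical Gaussian plus constant background on a
#' square window around the particle, repeated on the same window rotated by
#' 45 degrees. The two ellipticity scores (long/short axis ratio, >= 1) feed
#' the single-fluorophore filter: overlapping emitters elongate the apparent
#' spot in at least one orientation.
#'
#' @param image 2D matrix.
#' @param center `c(x, y)` 0-based approximate particle position.
#' @param window_px odd window edge length, pixels.
#' @return list of class `spot_fit`: `amplitude`, `center` (refined, image
#'   coordinates), `sigma_x`, `sigma_y`, `background`, `ellipticity_0`,
#'   `ellipticity_45`, `converged`.
#' @export
fit_spot <- function(image, center, window_px = 7) {
  r <- (window_px - 1) / 2
  cx <- round(center[1]); cy <- round(center[2])
  if (cx - r < 0 || cy - r < 0 ||
      cx + r > ncol(image) - 1 || cy + r > nrow(image) - 1)
    stop("fit window extends outside the image")
  win <- image[(cy - r):(cy + r) + 1, (cx - r):(cx + r) + 1]
  f0 <- fit_gauss2d(win)
  f45 <- if (!is.null(f0)) fit_gauss2d(rotate_window(win, 45)) else NULL
  if (is.null(f0) || is.null(f45)) {
    return(structure(list(converged = FALSE), class = "spot_fit"))
  }
  ell <- function(f) max(f$sigma_x, f$sigma_y) / min(f$sigma_x, f$sigma_y)
  structure(list(
    amplitude = f0$amplitude,
    center = c(x = cx - r + f0$x, y = cy - r + f0$y),
    sigma_x = f0$sigma_x, sigma_y = f0$sigma_y, background = f0$background,
    ellipticity_0 = ell(f0), ellipticity_45 = ell(f45),
    fit_snr = f0$amplitude / max(f0$residual_sd, 1e-12),
    converged = TRUE), class = "spot_fit")
}

#' Single-fluorophore ellipticity filter
#'
#' A spot is accepted only if both ellipticity scores (from the 0 and 45
#' degree fits) lie inside `bounds` (default `[1, 1.2]`, boundaries
#' inclusive); larger values indicate more than one emitter under the spot.
#'
#' @param fit a `spot_fit` from [fit_spot()].
#' @param bounds inclusive acceptance interval for both ellipticities.
#' @return `TRUE` (accept) or `FALSE` (reject; non-converged fits reject).
#' @export
ellipticity_filter <- function(fit, bounds = c(1.0, 1.2)) {
  if (!isTRUE(fit$converged)) return(FALSE)
  all(c(fit$ellipticity_0, fit$ellipticity_45) >= bounds[1] &
      c(fit$ellipticity_0, fit$ellipticity_45) <= bounds[2])
}

#' Detect and pair single-molecule spots in a two-channel movie
#'
#' Full detection stage: average the first frames of each channel, pick
#' acceptor particles, register the channels, locate donors (by default via
#' registration of the acceptor picks, optionally by independent picking and
#' mutual-nearest matching), fit spots, and apply the ellipticity filter.
#'
#' @param movie a movie list ([render_movie()] / [read_movie()]).
#' @param pick_both if `TRUE`, donors are picked independently in the donor
#'   channel and matched to acceptors; otherwise donor positions are the
#'   registered acceptor positions.
#' @param n_avg_frames frames averaged for picking.
#' @param min_separation_px,threshold_k picker settings ([pick_particles()]).
#' @param search_radius_px registration search radius.
#' @param max_displacement pairing tolerance, pixels.
#' @param ellipticity_bounds passed to [ellipticity_filter()].
#' @param window_px spot-fit window.
#' @param min_fit_snr minimum amplitude-to-residual ratio for a channel's
#'   ellipticity score to be considered assessable; a dim channel (e.g. the
#'   donor of a high-FRET molecule) yields a noise-dominated shape estimate
#'   and is skipped rather than rejected (multi-fluorophore QC still happens
#'   at the bleach-step stage).
#' @return list with `pairs` (data.frame of accepted pairs, donor-frame
#'   0-based coordinates), `shift` (estimated channel shift), `particles`
#'   (raw picks) and `n_rejected_ellipticity`.
#' @export
detect_pairs <- function(movie, pick_both = FALSE, n_avg_frames = 5,
                         min_separation_px = 5, threshold_k = 5,
                         search_radius_px = 5, max_displacement = 1.25,
                         ellipticity_bounds = c(1.0, 1.2), window_px = 7,
                         min_fit_snr = 10) {
  img_a <- average_first_frames(movie, "acceptor", n_avg_frames)
  img_d <- average_first_frames(movie, "donor", n_avg_frames)
  shift <- estimate_channel_shift(img_d, img_a, search_radius_px)
  acc <- pick_particles(img_a, min_separation_px, threshold_k)
  acc_in_donor <- acc
  acc_in_donor$x <- acc$x - shift[["dx"]]
  acc_in_donor$y <- acc$y - shift[["dy"]]
  if (pick_both) {
    don <- pick_particles(img_d, min_separation_px, threshold_k)
    pairs <- match_particles(don, acc_in_donor, max_displacement)
  } else {
    pairs <- data.frame(donor_idx = seq_len(nrow(acc)),
                        acceptor_idx = seq_len(nrow(acc)),
                        x_donor = acc_in_donor$x, y_donor = acc_in_donor$y,
                        x_acceptor = acc_in_donor$x,
                        y_acceptor = acc_in_donor$y,
                        displacement = 0)
  }
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ok <- TRUE
    n_assessed <- 0
    for (ch in c("acceptor", "donor")) {
      img <- if (ch == "acceptor") img_a else img_d
      ctr <- c(pairs$x_donor[i], pairs$y_donor[i])
      if (ch == "acceptor") ctr <- ctr + as.numeric(shift)
      fit <- try(fit_spot(img, ctr, window_px), silent = TRUE)
      if (inherits(fit, "try-error") || !isTRUE(fit$converged)) {
        ok <- FALSE; break
      }
      if (fit$fit_snr < min_fit_snr) next  # too dim to assess shape
      n_assessed <- n_assessed + 1
      if (!ellipticity_filter(fit, ellipticity_bounds)) { ok <- FALSE; break }
    }
    keep[i] <- ok && n_assessed >= 1
  }
  list(pairs = pairs[keep, , drop = FALSE], shift = shift,
       particles = list(acceptor = acc,
                        donor = if (pick_both) don else NULL),
       n_rejected_ellipticity = sum(!keep))
}
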