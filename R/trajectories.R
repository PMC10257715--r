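#' Spectral correction factors for FRET efficiency
#'
#' @param alpha donor bleedthrough fraction into the acceptor channel.
#' @param delta direct acceptor excitation by the 532 nm laser, as a fraction
#'   of the acceptor's 641 nm brightness.
#' @param gamma acceptor/donor detection-and-quantum-yield ratio.
#' @return object of class `correction_factors`.
#' @export
correction_factors <- function(alpha = 0, delta = 0, gamma = 1) {
  if (alpha < 0 || alpha >= 1 || delta < 0 || delta >= 1)
    stop("alpha and delta must lie in [0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(alpha = alpha, delta = delta, gamma = gamma),
            class = "correction_factors")
}

# Pixel offsets of a circular aperture / annulus around (0, 0).
disk_offsets <- function(r_in, r_out = NULL) {
  r <- ceiling(if (is.null(r_out)) r_in else r_out)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d <- sqrt(g$dx^2 + g$dy^2)
  if (is.null(r_out)) g[d <= r_in, ] else g[d > r_in & d <= r_out, ]
}

# Background-subtracted aperture photometry of one position in one stack.
aperture_series <- function(stack, x, y, aperture, annulus) {
  h <- dim(stack)[1]; w <- dim(stack)[2]; n <- dim(stack)[3]
  cx <- round(x); cy <- round(y)
  ap <- disk_offsets(aperture)
  an <- disk_offsets(annulus[1], annulus[2])
  if (cx - annulus[2] < 0 || cy - annulus[2] < 0 ||
      cx + annulus[2] > w - 1 || cy + annulus[2] > h - 1)
    return(NULL)
  ap_idx <- (cx + ap$dx) * h + (cy + ap$dy) + 1  # column-major linear index
  an_idx <- (cx + an$dx) * h + (cy + an$dy) + 1
  flat <- matrix(stack, h * w, n)
  ap_sum <- colSums(flat[ap_idx, , drop = FALSE])
  bg_med <- apply(flat[an_idx, , drop = FALSE], 2, stats::median)
  ap_sum - bg_med * nrow(ap)
}

#' Extract a raw donor/acceptor intensity trajectory for one matched pair
#'
#' Aperture photometry: per frame, the sum over a circular aperture at the
#' particle position minus the annulus median times the aperture area, for
#' the donor channel at the donor position and the acceptor channel at the
#' registered acceptor position. Frames are split by excitation label; the
#' acceptor intensity on the nearest 641 nm frame is aligned to each 532 nm
#' frame for the direct-excitation correction.
#'
#' @param movie a movie list.
#' @param x,y donor-frame particle position (0-based).
#' @param shift channel shift `c(dx, dy)` mapping donor to acceptor frame.
#' @param molecule_id identifier carried into the output.
#' @param aperture_radius_px aperture radius, pixels.
#' @param annulus_radii_px inner/outer annulus radii, pixels.
#' @return object of class `fret_trajectory` (or `NULL`-QC "edge" trajectory
#'   when the annulus leaves the image): raw `I_D`, `I_A` per 532 frame,
#'   `I_A_641` aligned per 532 frame, `raw641` series, times, and empty QC
#'   fields to be filled by the downstream steps.
#' @export
extract_traces <- function(movie, x, y, shift = c(0, 0), molecule_id = 1L,
                           aperture_radius_px = 3,
                           annulus_radii_px = c(5, 7)) {
  exc <- movie$excitation
  fps <- movie$acquisition$frame_rate
  times <- (seq_along(exc) - 1) / fps
  don <- aperture_series(movie$donor, x, y,
                         aperture_radius_px, annulus_radii_px)
  acc <- aperture_series(movie$acceptor, x + shift[1], y + shift[2],
                         aperture_radius_px, annulus_radii_px)
  traj <- structure(list(molecule_id = molecule_id, x = x, y = y),
                    class = "fret_trajectory")
  if (is.null(don) || is.null(acc)) {
    traj$qc_status <- "rejected"; traj$qc_reason <- "edge"
    return(traj)
  }
  is532 <- exc == 532
  i641 <- which(!is532)
  nn641 <- if (length(i641)) {
    vapply(which(is532), function(i) i641[which.min(abs(i641 - i))], integer(1))
  } else integer(0)
  traj$frame <- which(is532) - 1L
  traj$time <- times[is532]
  traj$I_D <- don[is532]
  traj$I_A <- acc[is532]
  traj$I_A_641 <- if (length(i641)) acc[nn641] else rep(0, sum(is532))
  traj$t641 <- times[i641]
  traj$raw641 <- acc[i641]
  traj$fe <- rep(NA_real_, sum(is532))
  traj$truncation_frame <- length(traj$time)
  traj$qc_status <- "pending"; traj$qc_reason <- NA_character_
  traj
}

#' Estimate correction factors from calibration molecules
#'
#' * `alpha` (donor bleedthrough): median over donor-only molecules of the
#'   per-molecule median `I_A / I_D` on 532 nm frames.
#' * `delta` (direct excitation): median over acceptor-only molecules of the
#'   per-molecule median `I_A(532) / I_A(641)`.
#' * `gamma`: median over acceptor-photobleach events in FRET-pair
#'   trajectories of the ratio of the acceptor drop to the donor rise across
#'   the bleach step, after bleedthrough/direct-excitation correction of the
#'   acceptor signal. Without a usable bleach step, `fallback_gamma` is
#'   returned with a warning.
#'
#' @param donor_only,acceptor_only lists of `fret_trajectory` objects from
#'   the calibration fields.
#' @param fret_pairs optional list of FRET-pair trajectories for gamma.
#' @param fallback_gamma gamma used when no bleach step is found.
#' @param min_signal frames with `I_D` (or `I_A_641`) below this fraction of
#'   the molecule's median signal are ignored in the ratios.
#' @return a [correction_factors()] object.
#' @export
estimate_corrections <- function(donor_only, acceptor_only,
                                 fret_pairs = NULL, fallback_gamma = 1,
                                 min_signal = 0.2) {
  if (length(donor_only) == 0 || length(acceptor_only) == 0)
    stop("calibration trace sets must be non-empty")
  med_ratio <- function(num, den) {
    keep <- den > min_signal * stats::median(den)
    if (!any(keep)) return(NA_real_)
    stats::median(num[keep] / den[keep])
  }
  alpha <- stats::median(vapply(donor_only, function(tr)
    med_ratio(tr$I_A, tr$I_D), numeric(1)), na.rm = TRUE)
  delta <- stats::median(vapply(acceptor_only, function(tr)
    med_ratio(tr$I_A, tr$I_A_641), numeric(1)), na.rm = TRUE)
  alpha <- max(0, alpha); delta <- max(0, delta)
  gammas <- numeric(0)
  for (tr in fret_pairs %||% list()) {
    steps <- find_down_steps(tr$raw641)
    if (length(steps) != 1) next
    t_bleach <- tr$t641[steps[1]]
    pre <- tr$time < t_bleach - 1e-9
    post <- tr$time > t_bleach + 1e-9
    # skip the frames nearest the step (partial-exposure mixing)
    if (sum(pre) < 3 || sum(post) < 3) next
    pre[max(which(pre))] <- FALSE
    post[min(which(post))] <- FALSE
    f_a <- tr$I_A - alpha * tr$I_D - delta * tr$I_A_641
    dFA <- stats::median(f_a[pre]) - stats::median(f_a[post])
    dID <- stats::median(tr$I_D[post]) - stats::median(tr$I_D[pre])
    if (is.finite(dFA) && is.finite(dID) && dID > 0)
      gammas <- c(gammas, dFA / dID)
  }
  gamma <- if (length(gammas) > 0) stats::median(gammas) else {
    warning("no usable acceptor-bleach step; falling back to configured gamma")
    fallback_gamma
  }
  correction_factors(alpha = alpha, delta = delta, gamma = max(gamma, 1e-6))
}

#' Apply corrections and compute the FRET efficiency series
#'
#' `F_A = I_A - alpha * I_D - delta * I_A_641` (nearest 641 nm frame), and
#' `FE = F_A / (F_A + gamma * I_D)` per 532 nm frame. FE is not clamped:
#' values outside `[0, 1]` are preserved (and counted in
#' `n_fe_out_of_range`); frames with `F_A + gamma * I_D <= 0` get `NA`.
#'
#' @param traj a `fret_trajectory` from [extract_traces()].
#' @param factors a [correction_factors()] object.
#' @return the trajectory with `fe` filled in.
#' @export
correct_and_compute_fe <- function(traj, factors) {
  stopifnot(inherits(factors, "correction_factors"))
  if (identical(traj$qc_reason, "edge")) return(traj)
  f_a <- traj$I_A - factors$alpha * traj$I_D - factors$delta * traj$I_A_641
  den <- f_a + factors$gamma * traj$I_D
  fe <- ifelse(den > 0, f_a / den, NA_real_)
  traj$fe <- fe
  traj$n_fe_out_of_range <- sum(fe < 0 | fe > 1, na.rm = TRUE)
  traj$factors <- factors
  traj
}

# Downward mean-shift steps by recursive binary segmentation.
# Returns 1-based indices of the first sample after each accepted step.
# A step must drop by >= bleach_frac of the pre-step level AND by more than
# min_step (default: 6 x the series' frame-to-frame noise scale), so noise
# around zero after a bleach cannot fake further steps.
find_down_steps <- function(x, bleach_frac = 0.5, min_persist = 4,
                            min_step = NULL) {
  n <- length(x)
  if (is.null(min_step)) {
    min_step <- if (n > 2) 6 * stats::mad(diff(x)) / sqrt(2) else 0
  }
  steps <- integer(0)
  seg <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_persist) return()
    xs <- x[lo:hi]
    cs <- cumsum(xs); tot <- cs[len]
    ks <- min_persist:(len - min_persist)
    m1 <- cs[ks] / ks
    m2 <- (tot - cs[ks]) / (len - ks)
    # SSE reduction of a two-mean fit, maximized over the split
    gain <- ks * (len - ks) / len * (m1 - m2)^2
    k <- ks[which.max(gain)]
    pre <- cs[k] / k; post <- (tot - cs[k]) / (len - k)
    if (pre > 0 && (pre - post) >= bleach_frac * pre &&
        (pre - post) >= min_step) {
      steps <<- c(steps, lo + k)
      seg(lo, lo + k - 1)
      seg(lo + k, hi)
    }
  }
  seg(1, n)
  sort(steps)
}

#' Detect photobleaching events and truncate a trajectory
#'
#' Change-point detection (binary segmentation for sustained downward mean
#' shifts of at least `bleach_frac` of the pre-step level) runs on the
#' 641 nm acceptor series (acceptor bleach) and on the total 532 nm
#' intensity `I_D + I_A / gamma` (donor bleach; this sum is insensitive to
#' FRET state changes, so truncation is independent of state inference).
#' The trajectory is truncated at the earliest bleach; the number of distinct
#' downward steps per fluorophore is kept for multi-fluorophore QC.
#'
#' @param traj a `fret_trajectory`.
#' @param gamma gamma factor used for the state-free total (defaults to the
#'   corrected trajectory's factor, else 1).
#' @param bleach_frac minimum fractional drop of a step.
#' @param min_persist minimum frames a level must persist.
#' @return the trajectory with `truncation_frame` (number of usable 532
#'   frames), `truncation_time`, `donor_steps`, `acceptor_steps`.
#' @export
detect_bleach <- function(traj, gamma = NULL, bleach_frac = 0.5,
                          min_persist = 4) {
  if (identical(traj$qc_reason, "edge")) return(traj)
  if (is.null(gamma))
    gamma <- if (!is.null(traj$factors)) traj$factors$gamma else 1
  acc_steps <- find_down_steps(traj$raw641, bleach_frac, min_persist)
  total <- traj$I_D + traj$I_A / gamma
  don_steps <- find_down_steps(total, bleach_frac, min_persist)
  t_acc <- if (length(acc_steps)) traj$t641[acc_steps[1]] else Inf
  t_don <- if (length(don_steps)) traj$time[don_steps[1]] else Inf
  t_trunc <- min(t_acc, t_don)
  traj$acceptor_steps <- length(acc_steps)
  traj$donor_steps <- length(don_steps)
  traj$truncation_time <- t_trunc
  traj$truncation_frame <- sum(traj$time < t_trunc - 1e-9)
  traj
}

#' Usable (pre-truncation) FE frames of a trajectory
#' @param traj a corrected, bleach-truncated `fret_trajectory`.
#' @return numeric vector of FE values before the truncation frame, `NA`
#'   frames dropped.
#' @export
usable_fe <- function(traj) {
  if (is.null(traj$fe) || is.null(traj$truncation_frame)) return(numeric(0))
  fe <- traj$fe[seq_len(traj$truncation_frame)]
  fe[!is.na(fe)]
}

#' Quality-control a trajectory
#'
#' Rejects trajectories with more than one donor or acceptor bleach step
#' (`multi_fluorophore`), with no acceptor signal on 641 nm frames before
#' truncation (`no_acceptor`), or with fewer than `min_frames` usable FE
#' frames (`too_short`).
#'
#' @param traj a `fret_trajectory` after [detect_bleach()] and
#'   [correct_and_compute_fe()].
#' @param min_frames minimum usable FE frames.
#' @return the trajectory with `qc_status` (`"accepted"`/`"rejected"`) and
#'   `qc_reason` set.
#' @export
qc_trajectory <- function(traj, min_frames = 20) {
  if (identical(traj$qc_reason, "edge")) return(traj)
  reject <- function(tr, reason) {
    tr$qc_status <- "rejected"; tr$qc_reason <- reason; tr
  }
  if (is.null(traj$donor_steps))
    stop("run detect_bleach() before qc_trajectory()")
  if (traj$donor_steps > 1 || traj$acceptor_steps > 1)
    return(reject(traj, "multi_fluorophore"))
  pre641 <- traj$raw641[traj$t641 < traj$truncation_time - 1e-9]
  if (length(pre641) == 0) pre641 <- traj$raw641[1]
  sig <- stats::median(pre641)
  noise <- stats::mad(diff(traj$raw641)) / sqrt(2)
  if (!is.finite(sig) || sig <= 0 || (noise > 0 && sig < 5 * noise))
    return(reject(traj, "no_acceptor"))
  if (length(usable_fe(traj)) < min_frames)
    return(reject(traj, "too_short"))
  traj$qc_status <- "accepted"; traj$qc_reason <- NA_character_
  traj
}

#' Summarize QC outcomes over a trajectory set
#' @param trajs list of QC'ed trajectories.
#' @return list with `n_total`, `n_accepted`, `fraction_accepted` and a
#'   named vector `fraction_rejected` per reason (fractions sum to 1).
#' @export
qc_summary <- function(trajs) {
  status <- vapply(trajs, `[[`, character(1), "qc_status")
  reason <- vapply(trajs, function(tr)
    if (is.na(tr$qc_reason %||% NA)) "accepted" else tr$qc_reason,
    character(1))
  n <- length(trajs)
  reasons <- table(reason[status == "rejected"])
  list(n_total = n, n_accepted = sum(status == "accepted"),
       fraction_accepted = sum(status == "accepted") / n,
       fraction_rejected = if (length(reasons)) reasons / n else
         stats::setNames(numeric(0), character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten trajectories to a per-frame table
#'
#' @param trajs list of `fret_trajectory` objects.
#' @return data.frame with columns `molecule_id`, `frame`, `time_s`,
#'   `excitation_nm`, `I_D`, `I_A`, `I_A_641`, `FE`, `pre_truncation`.
#' @export
trajectory_table <- function(trajs) {
  rows <- lapply(trajs, function(tr) {
    if (is.null(tr$time)) return(NULL)
    data.frame(molecule_id = tr$molecule_id, frame = tr$frame,
               time_s = tr$time, excitation_nm = 532,
               I_D = tr$I_D, I_A = tr$I_A, I_A_641 = tr$I_A_641,
               FE = tr$fe,
               pre_truncation = seq_along(tr$time) <= tr$truncation_frame)
  })
  do.call(rbind, rows)
}
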