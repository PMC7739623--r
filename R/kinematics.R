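# Whole-body kinematic aggregation: COM, inertia and angular momentum about
# the COM, and the average angular velocity of the body. These are the
# quantities every balance metric is built from.

#' Construct a segment state
#'
#' A segment state bundles the instantaneous mechanical description of one
#' body segment: mass, COM position and velocity, inertia tensor about the
#' segment COM (expressed in the world frame) and angular velocity.
#'
#' @param m mass (kg), positive.
#' @param r COM position (m), length-3.
#' @param v COM velocity (m/s), length-3.
#' @param J 3x3 inertia tensor about the segment COM in world axes
#'   (kg m^2); must be symmetric positive semidefinite.
#' @param omega angular velocity (rad/s), length-3.
#' @return an object of class `segment_state`.
#' @export
segment_state <- function(m, r, v = c(0, 0, 0), J = diag(0, 3), omega = c(0, 0, 0)) {
  stopifnot(is.numeric(m), length(m) == 1L, m > 0,
            length(r) == 3L, length(v) == 3L, length(omega) == 3L,
            is.matrix(J), all(dim(J) == c(3L, 3L)))
  if (max(abs(J - t(J))) > 1e-9 * max(1, max(abs(J))))
    stop("segment inertia tensor must be symmetric")
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(1, max(abs(ev))))
    stop("segment inertia tensor must be positive semidefinite")
  structure(list(m = m, r = as.numeric(r), v = as.numeric(v),
                 J = J, omega = as.numeric(omega)),
            class = "segment_state")
}

#' Whole-body centre of mass position and velocity
#'
#' Mass-weighted mean of the segment COM positions and velocities.
#'
#' @param segments list of [segment_state()] objects.
#' @return list with `r_C` and `v_C` (length-3 each).
#' @export
whole_body_com <- function(segments) {
  if (length(segments) < 1L) stop("need at least one segment")
  M <- sum(vapply(segments, `[[`, numeric(1), "m"))
  r_C <- Reduce(`+`, lapply(segments, function(s) s$m * s$r)) / M
  v_C <- Reduce(`+`, lapply(segments, function(s) s$m * s$v)) / M
  list(r_C = r_C, v_C = v_C)
}

#' Whole-body inertia tensor about the COM
#'
#' Sums each segment's own inertia with its parallel-axis (point mass)
#' contribution: `J_C = sum_i J_i + m_i ((rho' rho) I - rho rho')` where
#' `rho` is the vector from the whole-body COM to segment i's COM, all in
#' world axes.
#'
#' @inheritParams whole_body_com
#' @param r_C whole-body COM; computed from `segments` when `NULL`.
#' @return 3x3 inertia tensor (kg m^2).
#' @export
inertia_about_com <- function(segments, r_C = NULL) {
  if (is.null(r_C)) r_C <- whole_body_com(segments)$r_C
  J <- matrix(0, 3, 3)
  I3 <- diag(3)
  for (s in segments) {
    rho <- s$r - r_C
    J <- J + s$J + s$m * (sum(rho * rho) * I3 - tcrossprod(rho))
  }
  J
}

#' Whole-body angular momentum about the COM
#'
#' `H_C = sum_i J_i omega_i + rho x (m_i rho_dot)` with `rho` the position
#' and `rho_dot` the velocity of segment i's COM relative to the whole-body
#' COM.
#'
#' @inheritParams inertia_about_com
#' @param v_C whole-body COM velocity; computed when `NULL`.
#' @return length-3 angular momentum vector (kg m^2/s).
#' @export
angular_momentum_about_com <- function(segments, r_C = NULL, v_C = NULL) {
  if (is.null(r_C) || is.null(v_C)) {
    com <- whole_body_com(segments)
    r_C <- r_C %||% com$r_C
    v_C <- v_C %||% com$v_C
  }
  H <- c(0, 0, 0)
  for (s in segments) {
    rho <- s$r - r_C
    H <- H + as.numeric(s$J %*% s$omega) + cross3(rho, s$m * (s$v - v_C))
  }
  H
}

#' Average angular velocity of the body
#'
#' Solves the linear system `J_C omega_avg = H_C`. The solution is the
#' angular velocity of the single rigid body that carries the same angular
#' momentum as the multibody system -- an average over the segments' angular
#' momentum contributions, in the same sense that the COM velocity averages
#' the segment velocities.
#'
#' @param J_C 3x3 whole-body inertia about the COM.
#' @param H_C length-3 angular momentum about the COM.
#' @param rcond_min reciprocal condition number below which the sample is
#'   flagged as near-singular and `NA` is returned rather than an unstable
#'   solution.
#' @return length-3 `omega_avg` (rad/s), or `NA`s when `J_C` is
#'   numerically singular.
#' @export
average_angular_velocity <- function(J_C, H_C, rcond_min = 1e-12) {
  if (!all(is.finite(J_C)) || rcond(J_C) < rcond_min) return(rep(NA_real_, 3L))
  as.numeric(solve(J_C, H_C))
}

#' Full single-sample whole-body state
#'
#' Convenience wrapper aggregating a list of segment states into the
#' whole-body quantities used by the balance metrics, including the angular
#' momentum about the COM ground projection (`H_G`) needed by the travel
#' frame.
#'
#' @inheritParams whole_body_com
#' @return list with `r_C`, `v_C`, `h` (COM height), `J_C`, `H_C`,
#'   `omega_avg`, `H_G` and total mass `m`.
#' @export
whole_body_state <- function(segments) {
  com <- whole_body_com(segments)
  J_C <- inertia_about_com(segments, com$r_C)
  H_C <- angular_momentum_about_com(segments, com$r_C, com$v_C)
  m <- sum(vapply(segments, `[[`, numeric(1), "m"))
  h <- com$r_C[3L]
  # H about G: shift of moment point by h z-hat
  H_G <- H_C + cross3(c(0, 0, h), m * com$v_C)
  list(r_C = com$r_C, v_C = com$v_C, h = h, J_C = J_C, H_C = H_C,
       omega_avg = average_angular_velocity(J_C, H_C), H_G = H_G, m = m)
}

# ---------------------------------------------------------------------------
# Signal conditioning

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth filter forwards and
#' backwards (`signal::filtfilt`), doubling the effective order and
#' cancelling phase lag. NA-free input is required.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate (Hz).
#' @param cutoff cut-off frequency (Hz), strictly below the Nyquist rate.
#' @param order filter order for a single pass (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 10, order = 4L) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filt1 <- function(v) {
    if (anyNA(v)) stop("cannot filter a signal containing gaps (NA)")
    mu <- mean(v)  # detrend by mean to limit edge transients
    as.numeric(signal::filtfilt(bf, v - mu)) + mu
  }
  if (is.matrix(x)) apply(x, 2L, filt1) else filt1(x)
}

#' Central-difference derivative
#'
#' @param x numeric vector or matrix (rows are time samples).
#' @param dt sample interval (s).
#' @return derivative of `x`, one-sided differences at the two ends.
#' @export
central_diff <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2L, central_diff, dt = dt))
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' Filter and synchronize a trial recording
#'
#' Applies the zero-phase low-pass filter to all marker trajectories and
#' force-plate channels, then decimates the force streams to the marker
#' clock (the force rate must be an integer multiple of the marker rate; the
#' low-pass filter provides the anti-aliasing). The unfiltered seat-plate
#' vertical force is kept, decimated, alongside the filtered one: the
#' seat-off event test runs on the raw force so the sharp contact-break is
#' not smeared by the filter.
#'
#' @param trial an `sts_trial` (see [generate_sts_trial()] or
#'   [read_trial_tsv()]).
#' @param cutoff_hz filter cut-off (Hz), default 10.
#' @param order Butterworth order per pass, default 4.
#' @param max_gap_s longest tolerated marker gap (s); a longer gap aborts
#'   with an error of class `stsbalance_gap_error`.
#' @return the trial with filtered markers/forces on the common marker
#'   clock and `preprocessed = TRUE`.
#' @export
preprocess <- function(trial, cutoff_hz = 10, order = 4L, max_gap_s = 0.1) {
  stopifnot(inherits(trial, "sts_trial"))
  fs_m <- trial$fs_marker
  fs_f <- trial$fs_force
  L <- fs_f / fs_m
  if (abs(L - round(L)) > 1e-9)
    stop("force rate must be an integer multiple of the marker rate")
  L <- as.integer(round(L))

  for (nm in names(trial$markers)) {
    m <- trial$markers[[nm]]
    if (anyNA(m)) {
      runs <- rle(rowSums(is.na(m)) > 0)
      gap <- max(c(0L, runs$lengths[runs$values]))
      if (gap > max_gap_s * fs_m) {
        stop(structure(class = c("stsbalance_gap_error", "error", "condition"),
                       list(message = sprintf(
                         "marker %s has a gap of %d samples (> %.0f ms)",
                         nm, gap, 1000 * max_gap_s), call = sys.call(-1))))
      }
      m <- apply(m, 2L, function(col) stats::approx(seq_along(col), col,
                                                    seq_along(col), rule = 2)$y)
    }
    trial$markers[[nm]] <- lowpass_filter(m, fs_m, cutoff_hz, order)
  }

  nm_samp <- nrow(trial$markers[[1L]])
  dec <- seq(1L, by = L, length.out = nm_samp)
  for (pl in c("seat", "foot")) {
    p <- trial[[pl]]
    raw_fz <- p$fz
    p$fz <- lowpass_filter(p$fz, fs_f, cutoff_hz, order)[dec]
    p$cop <- lowpass_filter(p$cop, fs_f, cutoff_hz, order)[dec, , drop = FALSE]
    # raw channel decimated by block averaging: keeps the sharp contact
    # break while shrinking the noise floor by sqrt(L)
    p$fz_raw <- colMeans(matrix(raw_fz[seq_len(nm_samp * L)], nrow = L))
    p$time <- trial$time
    trial[[pl]] <- p
  }
  trial$fs_force <- fs_m
  trial$preprocessed <- TRUE
  trial
}
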