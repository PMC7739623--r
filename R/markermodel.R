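# Reconstruction of per-segment states from the package's planar link
# marker model, and the vectorized whole-body state series built on top.
#
# Marker dialect: per-foot IOR-style markers (L/R prefix) FAL, TAM (ankle
# malleoli), FM1, FM2, FM5 (metatarsals), FCC (heel), plus mid-line joint
# markers KJC (knee), HJC (hip) and C7 (top of trunk). The three moving
# segments (shank, thigh, HAT) run between ankle-knee, knee-hip and hip-C7;
# their orientation is the sagittal-plane angle of the joint-to-joint axis.

.require_markers <- function(trial, names) {
  miss <- setdiff(names, names(trial$markers))
  if (length(miss)) stop("trial is missing markers: ", paste(miss, collapse = ", "))
}

joint_centers <- function(trial) {
  .require_markers(trial, c("LFAL", "LTAM", "RFAL", "RTAM", "KJC", "HJC", "C7"))
  mk <- trial$markers
  list(ankle = (mk$LFAL + mk$LTAM + mk$RFAL + mk$RTAM) / 4,
       knee = mk$KJC, hip = mk$HJC, c7 = mk$C7)
}

# sagittal-plane angle of a (n x 3) axis series, measured from vertical
# (+z) toward +x, unwrapped so finite differencing is safe
.sagittal_angle <- function(u) {
  th <- atan2(u[, 1L], u[, 3L])
  # unwrap
  dth <- diff(th)
  jump <- c(0, cumsum(ifelse(dth > pi, -2 * pi, ifelse(dth < -pi, 2 * pi, 0))))
  th + jump
}

.row_unit <- function(x) x / sqrt(rowSums(x^2))

# Build the per-segment kinematic series (COM position/velocity, axis,
# angular rate, inertia constants) used by whole_body_series().
segment_series <- function(trial) {
  stopifnot(isTRUE(trial$preprocessed))
  jc <- joint_centers(trial)
  dt <- 1 / trial$fs_marker
  bp <- trial$body_params
  mk <- trial$markers

  ends <- list(
    hat    = list(prox = jc$hip,  dist = jc$c7,   up = jc$c7),
    thigh  = list(prox = jc$hip,  dist = jc$knee, up = jc$hip),
    shank  = list(prox = jc$knee, dist = jc$ankle, up = jc$knee),
    foot_l = list(prox = mk$LFCC, dist = mk$LFM2, up = NULL),
    foot_r = list(prox = mk$RFCC, dist = mk$RFM2, up = NULL)
  )

  segs <- list()
  for (i in seq_len(nrow(bp))) {
    nm <- bp$segment[i]
    e <- ends[[nm]]
    r <- e$prox + bp$com_ratio[i] * (e$dist - e$prox)
    v <- central_diff(r, dt)
    # segment axis points proximal->distal for feet (forward), and towards
    # the "up" end for the chain segments so standing angles are near zero
    ax <- if (is.null(e$up)) e$dist - e$prox else {
      lo <- if (identical(e$up, e$prox)) e$dist else e$prox
      e$up - lo
    }
    u <- .row_unit(ax)
    th <- .sagittal_angle(u)
    thd <- central_diff(th, dt)
    m <- bp$mass[i]
    segs[[nm]] <- list(name = nm, m = m, r = r, v = v, u = u, theta_dot = thd,
                       I_t = m * bp$r_gyr_t[i]^2, I_l = m * bp$r_gyr_l[i]^2)
  }
  segs
}

# single-sample segment_state objects (the list-of-segments API) extracted
# from the series at sample i
segment_states_at <- function(segs, i) {
  lapply(segs, function(s) {
    u <- s$u[i, ]
    J <- s$I_t * (diag(3) - tcrossprod(u)) + s$I_l * tcrossprod(u)
    segment_state(s$m, s$r[i, ], s$v[i, ], J, c(0, s$theta_dot[i], 0))
  })
}

#' Whole-body state series of a preprocessed trial
#'
#' Reconstructs segment states from the planar link marker model and
#' aggregates them, per sample, into the whole-body COM position/velocity,
#' inertia about the COM, angular momentum about the COM and about the COM
#' ground projection, and the average angular velocity (solution of
#' `J_C omega_avg = H_C`). Fully vectorized except for the per-sample 3x3
#' linear solve.
#'
#' @param trial a preprocessed `sts_trial` (see [preprocess()]).
#' @return an object of class `wbs_series`: list with `time`, `m` (total
#'   mass), `r_C`, `v_C` (n x 3), `h`, `com_speed` (n), `J_C` (n x 3 x 3),
#'   `H_C`, `H_G`, `omega_avg` (n x 3) and `singular` (logical n).
#' @export
whole_body_series <- function(trial) {
  segs <- segment_series(trial)
  n <- nrow(segs[[1L]]$r)
  M <- sum(vapply(segs, `[[`, numeric(1), "m"))

  r_C <- Reduce(`+`, lapply(segs, function(s) s$m * s$r)) / M
  v_C <- Reduce(`+`, lapply(segs, function(s) s$m * s$v)) / M

  J11 <- J22 <- J33 <- J12 <- J13 <- J23 <- numeric(n)
  H <- matrix(0, n, 3L)
  for (s in segs) {
    u <- s$u
    dI <- s$I_l - s$I_t
    J11 <- J11 + s$I_t + dI * u[, 1L]^2
    J22 <- J22 + s$I_t + dI * u[, 2L]^2
    J33 <- J33 + s$I_t + dI * u[, 3L]^2
    J12 <- J12 + dI * u[, 1L] * u[, 2L]
    J13 <- J13 + dI * u[, 1L] * u[, 3L]
    J23 <- J23 + dI * u[, 2L] * u[, 3L]
    rho <- s$r - r_C
    J11 <- J11 + s$m * (rho[, 2L]^2 + rho[, 3L]^2)
    J22 <- J22 + s$m * (rho[, 1L]^2 + rho[, 3L]^2)
    J33 <- J33 + s$m * (rho[, 1L]^2 + rho[, 2L]^2)
    J12 <- J12 - s$m * rho[, 1L] * rho[, 2L]
    J13 <- J13 - s$m * rho[, 1L] * rho[, 3L]
    J23 <- J23 - s$m * rho[, 2L] * rho[, 3L]
    # segment spin J_i omega_i with omega_i = theta_dot * y-hat
    su <- u[, 2L] * s$theta_dot            # u . omega
    H[, 1L] <- H[, 1L] + (s$I_l - s$I_t) * u[, 1L] * su
    H[, 2L] <- H[, 2L] + s$I_t * s$theta_dot + (s$I_l - s$I_t) * u[, 2L] * su
    H[, 3L] <- H[, 3L] + (s$I_l - s$I_t) * u[, 3L] * su
    # transport term rho x m (v_i - v_C)
    dv <- s$v - v_C
    H[, 1L] <- H[, 1L] + s$m * (rho[, 2L] * dv[, 3L] - rho[, 3L] * dv[, 2L])
    H[, 2L] <- H[, 2L] + s$m * (rho[, 3L] * dv[, 1L] - rho[, 1L] * dv[, 3L])
    H[, 3L] <- H[, 3L] + s$m * (rho[, 1L] * dv[, 2L] - rho[, 2L] * dv[, 1L])
  }

  J_C <- array(0, c(n, 3L, 3L))
  J_C[, 1L, 1L] <- J11; J_C[, 2L, 2L] <- J22; J_C[, 3L, 3L] <- J33
  J_C[, 1L, 2L] <- J_C[, 2L, 1L] <- J12
  J_C[, 1L, 3L] <- J_C[, 3L, 1L] <- J13
  J_C[, 2L, 3L] <- J_C[, 3L, 2L] <- J23

  omega_avg <- matrix(NA_real_, n, 3L)
  singular <- logical(n)
  for (i in seq_len(n)) {
    Ji <- matrix(J_C[i, , ], 3L, 3L)
    if (rcond(Ji) < 1e-12) { singular[i] <- TRUE; next }
    omega_avg[i, ] <- solve(Ji, H[i, ])
  }

  h <- r_C[, 3L]
  H_G <- H
  H_G[, 1L] <- H[, 1L] - M * h * v_C[, 2L]
  H_G[, 2L] <- H[, 2L] + M * h * v_C[, 1L]

  structure(list(time = trial$time, n = n, m = M, r_C = r_C, v_C = v_C,
                 h = h, com_speed = sqrt(rowSums(v_C^2)), J_C = J_C,
                 H_C = H, H_G = H_G, omega_avg = omega_avg,
                 singular = singular),
            class = "wbs_series")
}

# single-sample view of a wbs_series, shaped like whole_body_state()
wbs_at <- function(wbs, i) {
  list(r_C = wbs$r_C[i, ], v_C = wbs$v_C[i, ], h = wbs$h[i],
       J_C = matrix(wbs$J_C[i, , ], 3L, 3L), H_C = wbs$H_C[i, ],
       H_G = wbs$H_G[i, ], omega_avg = wbs$omega_avg[i, ], m = wbs$m)
}
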