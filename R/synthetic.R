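# Synthetic STS recordings with known ground truth.
#
# The generator drives a planar three-link chain (shank, thigh, and a
# combined head-arms-trunk segment) plus two static feet through smooth
# prescribed joint trajectories from sitting to standing. Because the
# trajectories are analytic, every segment state (position, velocity,
# angular velocity, inertia) is known exactly, which yields exact event
# times, COM trajectories and whole-body momentum ground truth. Marker and
# force-plate noise is added last.

#' Specification of a synthetic STS cohort
#'
#' Defines cohort sizes, repetition counts, sensor noise and the additive
#' effects applied to the older group's motion plans. Offsets are given on
#' the scale of the seat-off metric they target: `d_bg` and `d_bf` (m) map
#' to a stance-geometry shift (feet placed closer under the body, which
#' moves both BOS-relative margins together -- they are physically
#' inseparable for a feet-fixed task), `com_speed` (m/s) maps to a
#' dilation of the rise time.
#'
#' @param n_young,n_old subjects per group (>= 1).
#' @param reps_per_subject STS repetitions per subject (default 5).
#' @param seat_height_frac stool height as a fraction of knee height
#'   (1 = knee-epicondyle height, the measurement protocol's setting).
#' @param group_offsets named list of additive shifts for the older group:
#'   `d_bg`, `com_speed`, `d_bf`.
#' @param noise_sd_marker marker noise SD per axis (m).
#' @param noise_sd_force force-plate noise SD (N).
#' @param seed base RNG seed; everything derives deterministically from it.
#' @return object of class `sts_cohort_spec`.
#' @export
sts_cohort_spec <- function(n_young = 10L, n_old = 8L, reps_per_subject = 5L,
                            seat_height_frac = 1.0,
                            group_offsets = list(d_bg = 0.03,
                                                 com_speed = -0.08,
                                                 d_bf = 0.02),
                            noise_sd_marker = 3e-4, noise_sd_force = 0.5,
                            seed = 1L) {
  stopifnot(n_young >= 1L, n_old >= 1L, reps_per_subject >= 1L,
            noise_sd_marker >= 0, noise_sd_force >= 0,
            seat_height_frac > 0.5, seat_height_frac <= 1.2)
  go <- utils::modifyList(list(d_bg = 0, com_speed = 0, d_bf = 0),
                          as.list(group_offsets))
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 reps_per_subject = as.integer(reps_per_subject),
                 seat_height_frac = seat_height_frac, group_offsets = go,
                 noise_sd_marker = noise_sd_marker,
                 noise_sd_force = noise_sd_force, seed = as.integer(seed)),
            class = "sts_cohort_spec")
}

# quintic smoothstep and derivative (zero velocity and acceleration at the
# ends of the rise)
.q5 <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}
.dq5 <- function(tau) ifelse(tau <= 0 | tau >= 1, 0, 30 * tau^2 * (1 - tau)^2)

# smooth-start ramp for the seat force: C1 at onset, finite slope at the
# contact break so the +/-1 N seat-off test localizes the event sharply
.ramp <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^2 * (2 - u)
}

# asymmetric trunk-lean bump: zero at both ends of the rise, peaking at
# the seat-off fraction of the rise (maximum trunk flexion at seat-off)
.bump <- function(tau, pk = 0.45) {
  b <- numeric(length(tau)); db <- numeric(length(tau))
  i1 <- tau > 0 & tau < pk
  th <- (pi / 2) * tau[i1] / pk
  b[i1] <- sin(th)^2
  db[i1] <- sin(2 * th) * (pi / 2) / pk
  i2 <- tau >= pk & tau < 1
  th <- (pi / 2) * (1 + (tau[i2] - pk) / (1 - pk))
  b[i2] <- sin(th)^2
  db[i2] <- sin(2 * th) * (pi / 2) / (1 - pk)
  list(b = b, db = db)
}

# reference young seat-off COM speed used to translate a com_speed offset
# into a rise-time dilation
.V_REF <- 0.50

#' Deterministic per-subject parameters
#'
#' @param spec an [sts_cohort_spec()].
#' @param subject_index 1-based subject index; subjects `1..n_young` are
#'   young, the rest old.
#' @return list of anthropometric and motion-plan parameters.
#' @export
subject_params <- function(spec, subject_index) {
  stopifnot(subject_index >= 1L,
            subject_index <= spec$n_young + spec$n_old)
  group <- if (subject_index <= spec$n_young) "young" else "old"
  off <- spec$group_offsets
  with_local_seed(derive_seed(spec$seed, 1L, subject_index), {
    H <- min(1.95, max(1.50, stats::rnorm(1, 1.72, 0.06)))
    M <- min(110, max(45, stats::rnorm(1, 72, 10)))
    lean_max <- stats::rnorm(1, 0.80, 0.05)
    T_base <- min(2.2, max(1.3, stats::rnorm(1, 1.70, 0.12)))
    p_sit_off <- stats::rnorm(1, 0.03, 0.008)
    g_jit <- stats::rnorm(1, 0, 0.008)
    speed_off <- if (group == "old") off$com_speed else 0
    g_shift <- g_jit + if (group == "old") off$d_bg + off$d_bf else 0
    list(subject = subject_index, group = group, height = H, mass = M,
         weight = M * GRAVITY, lean_max = lean_max,
         T_rise = T_base * .V_REF / (.V_REF + speed_off),
         p_sit_off = p_sit_off, g_shift = g_shift,
         foot_l = 0.147 * H, foot_w = 0.36 * 0.147 * H,
         L_shank = 0.246 * H, L_thigh = 0.245 * H, L_hat = 0.30 * H,
         ankle_h = 0.039 * H, hip_half = 0.10)
  })
}

# world-frame foot marker layout for one static foot; ankle midpoint at
# (ax, ay, ankle_h); toes point +x
.foot_markers <- function(side, ax, ay, ankle_h, foot_l, foot_w) {
  med <- if (side == "left") -1 else 1   # medial is towards y = 0
  a <- 0.47 * foot_w; b <- 0.53 * foot_w
  list(
    FAL = c(ax, ay - med * a, ankle_h),
    TAM = c(ax, ay + med * a, ankle_h),
    FM1 = c(ax + 0.64 * foot_l, ay + med * b, 0.025),
    FM5 = c(ax + 0.64 * foot_l, ay - med * b, 0.025),
    FM2 = c(ax + 0.76 * foot_l, ay + med * 0.01, 0.028),
    FCC = c(ax - 0.24 * foot_l, ay, 0.045))
}

# assemble an sts_trial object
.new_trial <- function(time, fs_m, fs_f, markers, seat, foot, body_params,
                       body_mass, ground_truth, meta) {
  structure(list(time = time, fs_marker = fs_m, fs_force = fs_f,
                 markers = markers, seat = seat, foot = foot,
                 body_params = body_params, body_mass = body_mass,
                 body_weight = body_mass * GRAVITY,
                 ground_truth = ground_truth, meta = meta,
                 preprocessed = FALSE),
            class = "sts_trial")
}

# chain kinematics for given angle series; returns joint positions and
# velocities and the analytic segment state series
.chain_series <- function(sub, th_sh, dth_sh, th_th, dth_th, phi, dphi) {
  A <- c(0, 0, sub$ankle_h)
  Ls <- sub$L_shank; Lt <- sub$L_thigh; Lh <- sub$L_hat
  K <- cbind(A[1] + Ls * sin(th_sh), 0, A[3] + Ls * cos(th_sh))
  dK <- cbind(Ls * cos(th_sh) * dth_sh, 0, -Ls * sin(th_sh) * dth_sh)
  Hp <- cbind(K[, 1] - Lt * sin(th_th), 0, K[, 3] + Lt * cos(th_th))
  dHp <- cbind(dK[, 1] - Lt * cos(th_th) * dth_th, 0,
               dK[, 3] - Lt * sin(th_th) * dth_th)
  C7 <- cbind(Hp[, 1] + Lh * sin(phi), 0, Hp[, 3] + Lh * cos(phi))
  dC7 <- cbind(dHp[, 1] + Lh * cos(phi) * dphi, 0,
               dHp[, 3] - Lh * sin(phi) * dphi)
  list(A = A, K = K, dK = dK, Hp = Hp, dHp = dHp, C7 = C7, dC7 = dC7)
}

# analytic whole-body COM series (position, velocity) and seat-off segment
# states from the chain plus static feet
.analytic_segments_at <- function(sub, ch, i, bp, foot_com) {
  segs <- list()
  row <- function(Mt, j) Mt[j, ]
  mk <- function(nm, prox, dist, vprox, vdist, ang_rate) {
    irow <- bp[bp$segment == nm, ]
    r <- prox + irow$com_ratio * (dist - prox)
    v <- vprox + irow$com_ratio * (vdist - vprox)
    up <- dist - prox
    u <- up / sqrt(sum(up^2))
    J <- irow$mass * irow$r_gyr_t^2 * (diag(3) - tcrossprod(u)) +
      irow$mass * irow$r_gyr_l^2 * tcrossprod(u)
    segment_state(irow$mass, r, v, J, c(0, ang_rate, 0))
  }
  A <- ch$A
  segs$hat <- mk("hat", row(ch$Hp, i), row(ch$C7, i), row(ch$dHp, i),
                 row(ch$dC7, i), attr(ch, "dphi")[i])
  segs$thigh <- mk("thigh", row(ch$Hp, i), row(ch$K, i), row(ch$dHp, i),
                   row(ch$dK, i), -attr(ch, "dth_th")[i])
  segs$shank <- mk("shank", row(ch$K, i), A, row(ch$dK, i), c(0, 0, 0),
                   attr(ch, "dth_sh")[i])
  for (side in c("l", "r")) {
    nm <- paste0("foot_", side)
    irow <- bp[bp$segment == nm, ]
    u <- c(1, 0, 0)
    J <- irow$mass * irow$r_gyr_t^2 * (diag(3) - tcrossprod(u)) +
      irow$mass * irow$r_gyr_l^2 * tcrossprod(u)
    segs[[nm]] <- segment_state(irow$mass, foot_com[[side]], c(0, 0, 0), J,
                                c(0, 0, 0))
  }
  segs
}

#' Generate one synthetic STS trial
#'
#' Produces a full trial recording (markers at 150 Hz, seat and foot plate
#' wrenches at 900 Hz, body parameter table) for one repetition of one
#' subject, with exact ground truth: designed event times, analytic COM
#' position/velocity series, and the complete segment states at seat-off.
#' `trial_type` selects the designed movement: a clean STS, a sit-back
#' failure followed by a successful rise, a clean rise during which one
#' foot lifts (to be rejected by the foot rule), or a rise with too short
#' a standing plateau.
#'
#' @param spec an [sts_cohort_spec()].
#' @param subject_index,rep_index 1-based indices.
#' @param trial_type one of `"clean"`, `"sit_back"`, `"foot_lift"`,
#'   `"short_stand"`.
#' @param fs_marker,fs_force sampling rates (Hz); the force rate must be
#'   an integer multiple of the marker rate.
#' @return an `sts_trial` with a `ground_truth` element.
#' @export
generate_sts_trial <- function(spec, subject_index, rep_index,
                               trial_type = c("clean", "sit_back",
                                              "foot_lift", "short_stand"),
                               fs_marker = 150, fs_force = 900) {
  trial_type <- match.arg(trial_type)
  sub <- subject_params(spec, subject_index)
  rs <- derive_seed(spec$seed, 2L, subject_index, rep_index,
                    match(trial_type, c("clean", "sit_back", "foot_lift",
                                        "short_stand")))
  rp <- with_local_seed(rs, list(
    T_rise = sub$T_rise * exp(stats::rnorm(1, 0, 0.03)),
    lean = sub$lean_max + stats::rnorm(1, 0, 0.01)))
  T_rise <- rp$T_rise

  t_sit <- 2.0
  t_att <- 1.2   # sit-back attempt duration
  t_resit <- 1.5
  stand_hold <- if (trial_type == "short_stand") 0.35 else 2.5
  t_init <- switch(trial_type, sit_back = t_sit + t_att + t_resit, t_sit)
  f_so <- 0.45
  t_so <- t_init + f_so * T_rise
  t_stance <- t_init + T_rise
  T_total <- t_stance + stand_hold +
    if (trial_type == "short_stand") T_rise + 1.5 else 0
  if (t_so >= T_total) stop("designed seat-off falls outside the trial window")

  n <- as.integer(round(T_total * fs_marker))
  tt <- (seq_len(n) - 1L) / fs_marker
  nf <- n * as.integer(fs_force / fs_marker)
  tf <- (seq_len(nf) - 1L) / fs_force

  # progress q(t) and trunk-lean bump on both clocks
  prog <- function(t) {
    q <- .q5((t - t_init) / T_rise)
    dq <- .dq5((t - t_init) / T_rise) / T_rise
    bb <- .bump((t - t_init) / T_rise, pk = f_so)
    lean <- bb$b
    dlean <- bb$db / T_rise
    if (trial_type == "sit_back") {
      ta <- (t - t_sit) / t_att
      inatt <- ta > 0 & ta < 1
      q <- q + ifelse(inatt, 0.45 * sin(pi * ta)^2, 0)
      dq <- dq + ifelse(inatt, 0.45 * pi * sin(2 * pi * ta) / t_att, 0)
      lean <- lean + ifelse(inatt, sin(pi * ta)^2, 0)
      dlean <- dlean + ifelse(inatt, pi * sin(2 * pi * ta) / t_att, 0)
    }
    if (trial_type == "short_stand") {
      td <- (t - (t_stance + stand_hold)) / T_rise
      q <- q - .q5(td)
      dq <- dq - .dq5(pmin(1, pmax(0, td))) / T_rise
      lean <- lean + ifelse(td > 0 & td < 1, sin(pi * td)^2, 0)
      dlean <- dlean + ifelse(td > 0 & td < 1, pi * sin(2 * pi * td) / T_rise, 0)
    }
    list(q = q, dq = dq, lean = lean, dlean = dlean)
  }
  pm <- prog(tt)

  # seated shank angle: base dorsiflexion plus the stance-geometry shift
  sin_a0 <- 0.10 + sub$g_shift / ((1 - .q5(f_so)) * 0.9 * sub$L_shank)
  a0 <- asin(pmin(0.6, pmax(-0.6, sin_a0)))
  # seated thigh angle from the stool height: at knee height (frac = 1)
  # the thigh is horizontal; higher stools leave it partly extended
  knee_z <- sub$ankle_h + sub$L_shank * cos(a0)
  th_t0 <- acos(pmin(1, pmax(-1, (spec$seat_height_frac - 1) * knee_z /
                               sub$L_thigh)))

  angles <- function(p) {
    list(th_sh = a0 * (1 - p$q), dth_sh = -a0 * p$dq,
         th_th = th_t0 * (1 - p$q), dth_th = -th_t0 * p$dq,
         phi = rp$lean * p$lean, dphi = rp$lean * p$dlean)
  }
  am <- angles(pm)
  ch <- .chain_series(sub, am$th_sh, am$dth_sh, am$th_th, am$dth_th,
                      am$phi, am$dphi)
  attr(ch, "dphi") <- am$dphi
  attr(ch, "dth_th") <- am$dth_th
  attr(ch, "dth_sh") <- am$dth_sh

  # feet and body parameter table
  bp <- default_body_params(sub$mass, c(hat = sub$L_hat, thigh = sub$L_thigh,
                                        shank = sub$L_shank, foot = sub$foot_l))
  mkL <- .foot_markers("left", 0, sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  mkR <- .foot_markers("right", 0, -sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  foot_com <- list(l = (mkL$FCC + mkL$FM2) / 2, r = (mkR$FCC + mkR$FM2) / 2)

  # analytic whole-body COM series from the segment masses
  m_hat <- bp$mass[bp$segment == "hat"]
  m_th <- bp$mass[bp$segment == "thigh"]
  m_sh <- bp$mass[bp$segment == "shank"]
  m_ft <- bp$mass[bp$segment == "foot_l"]
  M <- sum(bp$mass)
  cr <- function(nm) bp$com_ratio[bp$segment == nm]
  r_hat <- ch$Hp + cr("hat") * (ch$C7 - ch$Hp)
  v_hat <- ch$dHp + cr("hat") * (ch$dC7 - ch$dHp)
  r_th <- ch$Hp + cr("thigh") * (ch$K - ch$Hp)
  v_th <- ch$dHp + cr("thigh") * (ch$dK - ch$dHp)
  Arow <- matrix(ch$A, n, 3L, byrow = TRUE)
  r_sh <- ch$K + cr("shank") * (Arow - ch$K)
  v_sh <- (1 - cr("shank")) * ch$dK
  feet_term <- m_ft * (foot_com$l + foot_com$r)
  com <- (m_hat * r_hat + m_th * r_th + m_sh * r_sh +
            matrix(feet_term, n, 3L, byrow = TRUE)) / M
  v_com <- (m_hat * v_hat + m_th * v_th + m_sh * v_sh) / M

  # force profiles on the force clock
  F0 <- 0.70 * sub$weight
  seat_fz <- rep(F0, nf)
  in_decay <- tf >= t_init & tf < t_so
  seat_fz[in_decay] <- F0 * (1 - .ramp((tf[in_decay] - t_init) / (t_so - t_init)))
  seat_fz[tf >= t_so] <- 0
  if (trial_type == "sit_back") {
    ta <- (tf - t_sit) / t_att
    inatt <- ta > 0 & ta < 1
    seat_fz[inatt] <- F0 * (1 - 0.9 * sin(pi * ta[inatt])^2)
  }
  if (trial_type == "short_stand") {
    td <- (tf - (t_stance + stand_hold)) / T_rise
    reload <- td > 0.6
    seat_fz[reload] <- F0 * .q5((td[reload] - 0.6) / 0.4)
  }
  foot_fz <- M * GRAVITY - seat_fz

  # foot-plate COP: blends from a seated point under the ankles to a point
  # tracking the COM ground projection in standing
  pf <- prog(tf)
  com_f <- stats::approx(tt, com[, 1L], tf, rule = 2)$y
  cop_x <- (1 - pf$q) * (0 + sub$p_sit_off) + pf$q * (com_f - 0.005)
  cop_foot <- cbind(cop_x, 0)
  cop_seat <- cbind(rep(-0.35, nf), 0)

  # markers on the marker clock
  markers <- list(KJC = ch$K, HJC = ch$Hp, C7 = ch$C7)
  for (nm in names(mkL)) markers[[paste0("L", nm)]] <- matrix(mkL[[nm]], n, 3L, byrow = TRUE)
  for (nm in names(mkR)) markers[[paste0("R", nm)]] <- matrix(mkR[[nm]], n, 3L, byrow = TRUE)
  if (trial_type == "foot_lift") {
    tb <- (tt - t_init) / T_rise
    bump <- ifelse(tb > 0 & tb < 1, 0.020 * sin(pi * tb)^2, 0)
    for (nm in c("LFAL", "LTAM", "LFM1", "LFM5"))
      markers[[nm]][, 3L] <- markers[[nm]][, 3L] + bump
  }

  # the designed events describe the successful rise, which every type
  # except short_stand contains (the sit-back trial ends with a clean rise)
  events <- list(t_init = t_init, t_seatoff = t_so, t_stance = t_stance,
                 accepted = trial_type != "short_stand")
  i_so <- which.min(abs(tt - t_so))
  gt <- list(events = events, com = com, v_com = v_com,
             com_speed = sqrt(rowSums(v_com^2)), h = com[, 3L],
             i_seatoff = i_so,
             seatoff_segments = .analytic_segments_at(sub, ch, i_so, bp, foot_com),
             cop_foot_150 = cbind(stats::approx(tf, cop_foot[, 1L], tt, rule = 2)$y, 0),
             subject = sub, trial_type = trial_type)

  # sensor noise, added last
  with_local_seed(derive_seed(rs, 9L), {
    if (spec$noise_sd_marker > 0) {
      for (nm in names(markers))
        markers[[nm]] <- markers[[nm]] +
          matrix(stats::rnorm(3L * n, 0, spec$noise_sd_marker), n, 3L)
    }
    if (spec$noise_sd_force > 0) {
      seat_fz <- seat_fz + stats::rnorm(nf, 0, spec$noise_sd_force)
      foot_fz <- foot_fz + stats::rnorm(nf, 0, spec$noise_sd_force)
      cop_foot <- cop_foot + matrix(stats::rnorm(2L * nf, 0, 5e-4), nf, 2L)
    }
  })

  .new_trial(tt, fs_marker, fs_force, markers,
             seat = list(time = tf, fz = seat_fz, cop = cop_seat),
             foot = list(time = tf, fz = foot_fz, cop = cop_foot),
             body_params = bp, body_mass = M, ground_truth = gt,
             meta = list(subject = subject_index, group = sub$group,
                         rep = rep_index, trial_type = trial_type))
}

#' Generate a synthetic quiet-standing trial
#'
#' Small-amplitude band-limited sagittal COM sway about an upright pose
#' (an ankle-strategy inverted pendulum: the whole chain rotates rigidly
#' about the ankles), feet flat, seat plate unloaded. The sway is a sum of
#' random-phase sinusoids below 1.2 Hz scaled to the requested COM
#' displacement SD, so velocities are analytic.
#'
#' @param spec an [sts_cohort_spec()].
#' @param subject_index subject.
#' @param duration_s trial length (s), default 10.
#' @param sway_sd target SD of the COM horizontal displacement (m).
#' @param fs_marker,fs_force sampling rates (Hz).
#' @return an `sts_trial`.
#' @export
generate_quiet_standing <- function(spec, subject_index, duration_s = 10,
                                    sway_sd = 0.004, fs_marker = 150,
                                    fs_force = 900) {
  stopifnot(duration_s > 0)
  sub <- subject_params(spec, subject_index)
  n <- as.integer(round(duration_s * fs_marker))
  tt <- (seq_len(n) - 1L) / fs_marker
  nf <- n * as.integer(fs_force / fs_marker)
  tf <- (seq_len(nf) - 1L) / fs_force

  bp <- default_body_params(sub$mass, c(hat = sub$L_hat, thigh = sub$L_thigh,
                                        shank = sub$L_shank, foot = sub$foot_l))
  mkL <- .foot_markers("left", 0, sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  mkR <- .foot_markers("right", 0, -sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  foot_com <- list(l = (mkL$FCC + mkL$FM2) / 2, r = (mkR$FCC + mkR$FM2) / 2)

  # band-limited sway as sum of sinusoids (analytic derivative)
  ps <- with_local_seed(derive_seed(spec$seed, 3L, subject_index), {
    nk <- 8L
    list(f = stats::runif(nk, 0.1, 1.2), ph = stats::runif(nk, 0, 2 * pi),
         a = stats::runif(nk, 0.3, 1))
  })
  sway_of <- function(t) {
    s <- 0; ds <- 0
    for (k in seq_along(ps$f)) {
      w <- 2 * pi * ps$f[k]
      s <- s + ps$a[k] * sin(w * t + ps$ph[k])
      ds <- ds + ps$a[k] * w * cos(w * t + ps$ph[k])
    }
    list(s = s, ds = ds)
  }
  sd_theory <- sqrt(sum(ps$a^2 / 2))
  scl <- if (sway_sd > 0) sway_sd / sd_theory else 0

  # standing chain, rotated rigidly about the ankle by alpha(t)
  A <- c(0, 0, sub$ankle_h)
  K0 <- A + c(0, 0, sub$L_shank)
  Hp0 <- K0 + c(0, 0, sub$L_thigh)
  C70 <- Hp0 + c(0, 0, sub$L_hat)
  m_of <- function(nm) bp$mass[bp$segment == nm]
  cr <- function(nm) bp$com_ratio[bp$segment == nm]
  chain_com0 <- (m_of("hat") * (Hp0 + cr("hat") * (C70 - Hp0)) +
                   m_of("thigh") * (Hp0 + cr("thigh") * (K0 - Hp0)) +
                   m_of("shank") * (K0 + cr("shank") * (A - K0)))
  M <- sum(bp$mass)
  h_lever <- (chain_com0 / (M - 2 * m_of("foot_l")))[3L] - A[3L]
  sw <- sway_of(tt)
  alpha <- scl * sw$s / h_lever
  dalpha <- scl * sw$ds / h_lever

  rot <- function(P0) {
    rel <- P0 - A
    x <- A[1L] + rel[1L] * cos(alpha) + rel[3L] * sin(alpha)
    z <- A[3L] - rel[1L] * sin(alpha) + rel[3L] * cos(alpha)
    cbind(x, P0[2L], z)
  }
  drot <- function(P0) {
    rel <- P0 - A
    dx <- (-rel[1L] * sin(alpha) + rel[3L] * cos(alpha)) * dalpha
    dz <- (-rel[1L] * cos(alpha) - rel[3L] * sin(alpha)) * dalpha
    cbind(dx, 0, dz)
  }
  markers <- list(KJC = rot(K0), HJC = rot(Hp0), C7 = rot(C70))
  for (nm in names(mkL)) markers[[paste0("L", nm)]] <- matrix(mkL[[nm]], n, 3L, byrow = TRUE)
  for (nm in names(mkR)) markers[[paste0("R", nm)]] <- matrix(mkR[[nm]], n, 3L, byrow = TRUE)

  chain_m <- M - 2 * m_of("foot_l")
  com <- (rot(chain_com0 / chain_m) * chain_m +
            matrix(m_of("foot_l") * (foot_com$l + foot_com$r), n, 3L, byrow = TRUE)) / M
  v_com <- drot(chain_com0 / chain_m) * chain_m / M

  swf <- sway_of(tf)
  alpha_f <- scl * swf$s / h_lever
  com_xf <- A[1L] + (chain_com0[1L] / chain_m - A[1L]) * cos(alpha_f) +
    (chain_com0[3L] / chain_m - A[3L]) * sin(alpha_f)
  cop_x <- (com_xf * chain_m + m_of("foot_l") * (foot_com$l[1L] + foot_com$r[1L])) / M +
    scl * 0.2 * sin(2 * pi * 0.7 * tf)   # small COP-COM misalignment
  seat_fz <- rep(0, nf)
  foot_fz <- rep(M * GRAVITY, nf)
  cop_foot <- cbind(cop_x, 0)

  gt <- list(com = com, v_com = v_com, com_speed = sqrt(rowSums(v_com^2)),
             h = com[, 3L], alpha = alpha, dalpha = dalpha, sway_sd = sway_sd,
             subject = sub, trial_type = "quiet")

  with_local_seed(derive_seed(spec$seed, 4L, subject_index), {
    if (spec$noise_sd_marker > 0) {
      for (nm in names(markers))
        markers[[nm]] <- markers[[nm]] +
          matrix(stats::rnorm(3L * n, 0, spec$noise_sd_marker), n, 3L)
    }
    if (spec$noise_sd_force > 0) {
      seat_fz <- seat_fz + stats::rnorm(nf, 0, spec$noise_sd_force)
      foot_fz <- foot_fz + stats::rnorm(nf, 0, spec$noise_sd_force)
      cop_foot <- cop_foot + matrix(stats::rnorm(2L * nf, 0, 5e-4), nf, 2L)
    }
  })

  .new_trial(tt, fs_marker, fs_force, markers,
             seat = list(time = tf, fz = seat_fz, cop = cbind(rep(-0.35, nf), 0)),
             foot = list(time = tf, fz = foot_fz, cop = cop_foot),
             body_params = bp, body_mass = M, ground_truth = gt,
             meta = list(subject = subject_index, group = sub$group,
                         trial_type = "quiet"))
}

#' Generate a synthetic COP-excursion trial for BOS template building
#'
#' Emulates the calibration protocol in which a participant sweeps their
#' COP over the full functional range of each foot without stepping. After
#' a 2 s quiet calibration phase the COP densely covers a known
#' rectangular region attached to each foot frame (loaded foot carrying
#' 80% of body weight), interleaved with deliberately tilted-foot episodes
#' (COP beyond the toes) and low-force episodes that the template builder
#' must filter out.
#'
#' @param foot_length,foot_width foot dimensions (m).
#' @param seed RNG seed.
#' @param body_mass body mass (kg).
#' @param per_foot_s seconds of excursion per foot.
#' @param fs_marker,fs_force sampling rates (Hz).
#' @return an `sts_trial`; `meta$foot_windows`, `meta$calib_idx` and
#'   `ground_truth$region_norm` (normalized region polygon) describe the
#'   design.
#' @export
generate_cop_excursion_trial <- function(foot_length = 0.25, foot_width = 0.09,
                                         seed = 1L, body_mass = 72,
                                         per_foot_s = 15, fs_marker = 150,
                                         fs_force = 900) {
  stopifnot(foot_length > 0, foot_width > 0)
  t_cal <- 2
  T_total <- t_cal + 2 * per_foot_s
  n <- as.integer(round(T_total * fs_marker))
  tt <- (seq_len(n) - 1L) / fs_marker
  L <- as.integer(fs_force / fs_marker)
  nf <- n * L
  tf <- (seq_len(nf) - 1L) / fs_force
  BW <- body_mass * GRAVITY

  hip_half <- 0.10
  ankle_h <- 0.067
  mkL <- .foot_markers("left", 0, hip_half, ankle_h, foot_length, foot_width)
  mkR <- .foot_markers("right", 0, -hip_half, ankle_h, foot_length, foot_width)
  markers <- list()
  for (nm in names(mkL)) markers[[paste0("L", nm)]] <- matrix(mkL[[nm]], n, 3L, byrow = TRUE)
  for (nm in names(mkR)) markers[[paste0("R", nm)]] <- matrix(mkR[[nm]], n, 3L, byrow = TRUE)

  # known normalized region (same for both feet; right is mirrored by the
  # template builder)
  region <- cbind(c(-0.45, 0.45, 0.45, -0.45),
                  c(-0.18, -0.18, 0.72, 0.72))

  windows <- list(left = which(tt >= t_cal & tt < t_cal + per_foot_s),
                  right = which(tt >= t_cal + per_foot_s))
  frames <- list(left = foot_frame(mkL, flatten = TRUE),
                 right = foot_frame(mkR, flatten = TRUE))
  # measured dimensions (the same quantities the profile extraction will
  # normalize by), so the designed region is exact in normalized space
  dims <- list(left = foot_dimensions(mkL), right = foot_dimensions(mkR))

  cop_m <- matrix(NA_real_, n, 2L)     # marker-clock COP, world frame
  fz_m <- rep(BW, n)
  tilt_m <- rep(FALSE, n)
  calib <- which(tt < t_cal)
  cop_m[calib, 1L] <- 0.05 * foot_length
  cop_m[calib, 2L] <- 0

  with_local_seed(derive_seed(seed, 5L), {
    for (side in c("left", "right")) {
      idx <- windows[[side]]
      m <- length(idx)
      fr <- frames[[side]]
      # per-sample category: in-region (70%), tilted (15%), low-force (15%)
      cat <- sample(c("region", "tilt", "low"), m, replace = TRUE,
                    prob = c(0.7, 0.15, 0.15))
      xn <- stats::runif(m, region[1L, 1L], region[2L, 1L])
      yn <- stats::runif(m, region[1L, 2L], region[3L, 2L])
      yn[cat == "tilt"] <- stats::runif(sum(cat == "tilt"), 0.8, 1.1)
      xn[cat == "low"] <- stats::runif(sum(cat == "low"), 0.5, 0.8) *
        sample(c(-1, 1), sum(cat == "low"), replace = TRUE)
      fz_m[idx] <- ifelse(cat == "low", 0.3 * BW, 0.8 * BW)
      tilt_m[idx] <- cat == "tilt"
      o <- fr$origin; ex <- fr$x; ey <- fr$y
      wm <- dims[[side]]["w"]; lm <- dims[[side]]["l"]
      cop_m[idx, 1L] <- o[1L] + xn * wm * ex[1L] + yn * lm * ey[1L]
      cop_m[idx, 2L] <- o[2L] + xn * wm * ex[2L] + yn * lm * ey[2L]
    }
  })

  # tilted episodes: pitch the loaded foot's markers about its metatarsal
  # line so the flat-foot test rejects those samples
  for (side in c("left", "right")) {
    idx <- windows[[side]][tilt_m[windows[[side]]]]
    if (length(idx) == 0L) next
    pre <- if (side == "left") "L" else "R"
    base <- if (side == "left") mkL else mkR
    pivot <- (base$FM1 + base$FM5) / 2
    ang <- 0.22   # ~12.6 degrees about the foot x axis (heel lift)
    fr <- frames[[side]]
    for (nm in names(base)) {
      rel <- base[[nm]] - pivot
      # rotate about the (horizontal) foot x axis
      ry <- sum(rel * fr$y); rz <- rel[3L]
      rot <- pivot + sum(rel * fr$x) * fr$x +
        (ry * cos(ang) - rz * sin(ang)) * fr$y +
        c(0, 0, ry * sin(ang) + rz * cos(ang))
      markers[[paste0(pre, nm)]][idx, ] <- matrix(rot, length(idx), 3L, byrow = TRUE)
    }
  }

  # force-clock streams by sample-and-hold of the marker-clock design
  rep_idx <- rep(seq_len(n), each = L)
  foot <- list(time = tf, fz = fz_m[rep_idx], cop = cop_m[rep_idx, , drop = FALSE])
  seat <- list(time = tf, fz = rep(0, nf), cop = cbind(rep(-0.35, nf), 0))

  bp <- default_body_params(body_mass, c(hat = 0.52, thigh = 0.42,
                                         shank = 0.42, foot = foot_length))
  gt <- list(region_norm = region,
             region_area_norm = abs(polygon_area(region)),
             tilt = tilt_m, trial_type = "cop_excursion")
  .new_trial(tt, fs_marker, fs_force, markers, seat, foot, bp, body_mass, gt,
             meta = list(trial_type = "cop_excursion", foot_windows = windows,
                         calib_idx = calib, body_weight = BW))
}

#' Extract per-foot COP profiles from a COP-excursion trial
#'
#' Computes, for each foot: the COP resolved into the flattened foot frame,
#' the per-sample normal force, and the flat-foot flags obtained by
#' comparing each sample's foot frame against the frame calibrated during
#' the initial quiet phase. The result feeds [build_template()].
#'
#' @param trial a [generate_cop_excursion_trial()] recording (raw).
#' @return list of two profile lists (left, right).
#' @export
cop_excursion_profiles <- function(trial) {
  stopifnot(identical(trial$meta$trial_type, "cop_excursion"))
  L <- as.integer(trial$fs_force / trial$fs_marker)
  dec <- seq(1L, by = L, length.out = length(trial$time))
  fz <- trial$foot$fz[dec]
  cop <- trial$foot$cop[dec, , drop = FALSE]
  profiles <- list()
  for (side in c("left", "right")) {
    pre <- if (side == "left") "L" else "R"
    nms <- paste0(pre, c("FAL", "TAM", "FM1", "FM2", "FM5", "FCC"))
    calib_mk <- lapply(stats::setNames(nms, sub(pre, "", nms)), function(nm)
      colMeans(trial$markers[[nm]][trial$meta$calib_idx, , drop = FALSE]))
    fr_ref <- foot_frame(calib_mk, flatten = TRUE)
    # tilt is judged against the calibration-time raw frame (when the foot
    # was known flat): a flat foot's marker frame is itself pitched
    # relative to the ground plane, so the flattened frame is only used
    # for ground-plane geometry
    fr_raw <- foot_frame(calib_mk)
    dims <- foot_dimensions(calib_mk, fr_raw)
    idx <- trial$meta$foot_windows[[side]]
    flat <- logical(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      mk_i <- lapply(stats::setNames(nms, sub(pre, "", nms)), function(nm)
        trial$markers[[nm]][i, ])
      Rrel <- foot_rotation(foot_frame(mk_i), fr_raw)
      flat[k] <- foot_is_flat(Rrel, dims["w"], dims["l"])
    }
    rel <- cbind(cop[idx, 1L] - fr_ref$origin[1L], cop[idx, 2L] - fr_ref$origin[2L])
    cop_ff <- cbind(rel[, 1L] * fr_ref$x[1L] + rel[, 2L] * fr_ref$x[2L],
                    rel[, 1L] * fr_ref$y[1L] + rel[, 2L] * fr_ref$y[2L])
    profiles[[side]] <- list(cop = cop_ff, force = fz[idx], flat = flat,
                             w = unname(dims["w"]), l = unname(dims["l"]),
                             side = side)
  }
  profiles
}
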