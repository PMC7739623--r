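# Foot placement estimator (FPE): travel frame construction, projection of
# the equivalent single-body state onto the vertical travel plane, the
# planar balance residual and its hybrid bisection/Newton solver, the
# post-contact pendulum outcome, and the per-sample dynamic balance
# metrics.
#
# The FPE is the ground point where the COP must be placed so that an
# inverted pendulum carrying the body's mass, COM height, planar inertia
# and momentum passively rotates up into a balanced standing pose:
# momentum is conserved at contact and the post-contact kinetic energy
# exactly matches the potential energy needed to bring the COM over the
# contact point.

#' Travel frame from the whole-body angular momentum about G
#'
#' The turning axis t-hat is the normalized horizontal component of `H_G`;
#' the straight-step axis is `s = t x z`, so forward travel gives positive
#' forward velocity. When the horizontal angular momentum is too small to
#' define a direction, the previous frame is reused; failing that, the
#' horizontal COM velocity heading defines s-hat; failing that the sample
#' is flagged (`NULL` return).
#'
#' @param H_G angular momentum about the COM ground projection (kg m^2/s).
#' @param v_C optional COM velocity for the fallback heading.
#' @param prev optional previous `travel_frame`.
#' @param h_threshold magnitude (kg m^2/s) below which the horizontal
#'   component of `H_G` is considered degenerate.
#' @return list with unit axes `s`, `t`, `z` (class `travel_frame`), or
#'   `NULL` when no direction is defined.
#' @export
travel_frame <- function(H_G, v_C = NULL, prev = NULL, h_threshold = 1e-8) {
  z <- c(0, 0, 1)
  hh <- c(H_G[1L], H_G[2L], 0)
  if (sqrt(sum(hh^2)) > h_threshold) {
    t_hat <- unitv(hh)
    s_hat <- cross3(t_hat, z)
    return(structure(list(s = s_hat, t = t_hat, z = z), class = "travel_frame"))
  }
  if (!is.null(prev)) return(prev)
  if (!is.null(v_C)) {
    vh <- c(v_C[1L], v_C[2L], 0)
    if (sqrt(sum(vh^2)) > 1e-10) {
      s_hat <- unitv(vh)
      t_hat <- cross3(z, s_hat)
      return(structure(list(s = s_hat, t = t_hat, z = z), class = "travel_frame"))
    }
  }
  NULL
}

#' Project the whole-body state onto the travel plane
#'
#' Produces the planar single-body state used by the FPE: mass, COM height,
#' forward and vertical COM velocity, angular rate about the turning axis,
#' and the scalar inertia `J = t' J_C t`.
#'
#' @param state a whole-body state (as from [whole_body_state()] or
#'   `wbs_at`): needs `m`, `h`, `v_C`, `omega_avg`, `J_C`.
#' @param frame a [travel_frame()].
#' @param g gravitational acceleration (m/s^2).
#' @return list of class `fpe_input` with `m`, `h`, `v_s1`, `v_z1`,
#'   `omega1`, `J`, `g`.
#' @export
project_state <- function(state, frame, g = GRAVITY) {
  if (state$h <= 0) stop("COM height must be positive")
  t_hat <- frame$t
  structure(list(
    m = state$m, h = state$h,
    v_s1 = sum(state$v_C * frame$s),
    v_z1 = sum(state$v_C * frame$z),
    omega1 = sum(state$omega_avg * t_hat),
    J = as.numeric(t_hat %*% state$J_C %*% t_hat),
    g = g), class = "fpe_input")
}

#' Planar FPE balance residual
#'
#' The scalar function whose root in the leg angle `phi` (measured from
#' vertical) locates the FPE:
#' `f = (m h (v_s1 c + v_z1 s) c + J w1 c^2)^2 / (m h^2 + J c^2)
#'      + 2 m g h c (c - 1)`
#' with `c = cos(phi)`, `s = sin(phi)`. `f = 0` expresses that the
#' post-contact kinetic energy (after momentum-conserving contact on a leg
#' of length `h/c`) equals the potential energy gained rotating the COM up
#' over the contact.
#'
#' @param phi leg angle(s), rad; vectorized.
#' @param input an `fpe_input` (see [project_state()]).
#' @return residual value(s), units of energy (J).
#' @export
fpe_residual <- function(phi, input) {
  cphi <- cos(phi); sphi <- sin(phi)
  num <- input$m * input$h * (input$v_s1 * cphi + input$v_z1 * sphi) * cphi +
    input$J * input$omega1 * cphi^2
  num^2 / (input$m * input$h^2 + input$J * cphi^2) +
    2 * input$m * input$g * input$h * cphi * (cphi - 1)
}

# analytic derivative of the residual w.r.t. phi (for Newton polishing)
fpe_residual_deriv <- function(phi, input) {
  cphi <- cos(phi); sphi <- sin(phi)
  m <- input$m; h <- input$h; J <- input$J
  A <- input$v_s1 * cphi + input$v_z1 * sphi
  N <- m * h * A * cphi + J * input$omega1 * cphi^2
  D <- m * h^2 + J * cphi^2
  dA <- -input$v_s1 * sphi + input$v_z1 * cphi
  dN <- m * h * (dA * cphi - A * sphi) - 2 * J * input$omega1 * cphi * sphi
  dD <- -2 * J * cphi * sphi
  (2 * N * dN * D - N^2 * dD) / D^2 +
    2 * m * input$g * h * (-sphi) * (2 * cphi - 1)
}

#' Solve the planar FPE
#'
#' Finds the leg angle at which the balance residual vanishes, using
#' bisection on a bracketing interval found by scanning `(0, pi/2)` and
#' Newton polishing with analytic derivative (any Newton step leaving the
#' bracket falls back to a bisection step). Backward travel
#' (`v_s1 < 0`) is solved in the mirrored plane, giving `phi < 0`.
#'
#' @param input an `fpe_input`.
#' @param r_G optional COM ground projection (3-vector or 2-vector) for the
#'   world FPE point.
#' @param s_hat optional straight-step axis for the world FPE point.
#' @param tol_rel dimensionless residual tolerance; convergence requires
#'   `|f| < tol_rel * m g h`.
#' @param scan_n number of scan points used to bracket the root.
#' @return list of class `fpe_solution`: `phi` (rad), `l` (leg length, m),
#'   `omega2` (post-contact rate, rad/s), `residual`, `converged`, and
#'   `r_F` (world FPE point) when `r_G`/`s_hat` are given.
#' @export
solve_fpe <- function(input, r_G = NULL, s_hat = NULL, tol_rel = 1e-10,
                      scan_n = 256L) {
  orient <- function(sgn) {
    inp <- input
    inp$v_s1 <- sgn * input$v_s1
    inp$omega1 <- sgn * input$omega1
    inp
  }
  # the contact momentum numerator: its sign is the sign of the
  # post-contact rotation rate; a physical FPE rotates the model forward
  # over its contact, so only roots with a non-negative numerator qualify
  # (the squared term in the residual hides this sign)
  momentum_num <- function(phi, inp) {
    cphi <- cos(phi); sphi <- sin(phi)
    inp$m * inp$h * (inp$v_s1 * cphi + inp$v_z1 * sphi) * cphi +
      inp$J * inp$omega1 * cphi^2
  }
  solve_half <- function(inp) {
    scale <- inp$m * inp$g * inp$h
    w_scale <- sqrt(inp$g / inp$h) * inp$m * inp$h^2
    f0 <- fpe_residual(0, inp)
    if (abs(f0) <= tol_rel * scale) return(list(phi = 0, found = TRUE))
    grid <- seq(0, pi / 2 - 1e-9, length.out = scan_n)
    fg <- fpe_residual(grid, inp)
    sgn <- fg >= 0
    cross <- which(sgn[-scan_n] != sgn[-1L])
    for (ci in cross) {
      a <- grid[ci]; b <- grid[ci + 1L]; fa <- fg[ci]
      # bisection close to the root, then Newton polishing with a
      # bisection fallback whenever a step leaves the bracket
      for (k in 1:30) {
        mid <- (a + b) / 2
        fm <- fpe_residual(mid, inp)
        if (fa * fm <= 0) b <- mid else { a <- mid; fa <- fm }
      }
      phi <- (a + b) / 2
      conv <- FALSE
      for (k in 1:40) {
        fk <- fpe_residual(phi, inp)
        if (abs(fk) <= tol_rel * scale) { conv <- TRUE; break }
        if (fa * fk <= 0) b <- phi else { a <- phi; fa <- fk }
        cand <- phi - fk / fpe_residual_deriv(phi, inp)
        phi <- if (is.finite(cand) && cand > a && cand < b) cand else (a + b) / 2
      }
      if (!conv) conv <- abs(fpe_residual(phi, inp)) <= tol_rel * scale
      if (conv && momentum_num(phi, inp) >= -1e-8 * w_scale)
        return(list(phi = phi, found = TRUE))
    }
    list(phi = NA_real_, found = FALSE)
  }

  primary <- if (input$v_s1 < 0) -1 else 1
  inp <- orient(primary)
  sol <- solve_half(inp)
  sgn_out <- primary
  if (!sol$found) {
    # no forward-rotation root ahead: the body's spin dominates and the
    # balancing contact lies on the other side of G
    inp <- orient(-primary)
    sol <- solve_half(inp)
    sgn_out <- -primary
  }
  if (!sol$found) {
    out <- list(phi = NA_real_, l = NA_real_, omega2 = NA_real_,
                residual = NA_real_, converged = FALSE, r_F = NULL)
    class(out) <- "fpe_solution"
    return(out)
  }
  phi_h <- sol$phi
  l <- inp$h / cos(phi_h)
  omega2 <- momentum_num(phi_h, inp) /
    (inp$m * inp$h^2 + inp$J * cos(phi_h)^2)
  phi <- sgn_out * phi_h
  out <- list(phi = phi, l = l, omega2 = omega2,
              residual = fpe_residual(phi_h, inp), converged = TRUE)
  if (!is.null(r_G) && !is.null(s_hat)) {
    out$r_F <- as.numeric(r_G) + (input$h * tan(phi)) * as.numeric(s_hat)
  }
  class(out) <- "fpe_solution"
  out
}

#' Post-contact outcome of the inverted pendulum
#'
#' Places the contact point at a given forward offset from the COM ground
#' projection, applies momentum-conserving contact, and classifies the
#' subsequent energy-conserving rotation about the contact: the model
#' `falls_forward` when it carries excess kinetic energy over the top,
#' `falls_backward` when it cannot reach the top (or rotates away from it),
#' and `balances` when it arrives at the upright position with angular
#' speed below tolerance. Stepping exactly on the FPE balances by
#' construction.
#'
#' @param input an `fpe_input`.
#' @param contact_offset contact location along the straight-step axis,
#'   metres ahead of the COM ground projection.
#' @param tol_omega arrival-speed tolerance (rad/s).
#' @return one of `"falls_forward"`, `"falls_backward"`, `"balances"`.
#' @export
post_contact_outcome <- function(input, contact_offset, tol_omega = 1e-4) {
  m <- input$m; h <- input$h; J <- input$J
  d <- contact_offset
  l <- sqrt(h^2 + d^2)
  # angular momentum about the contact point just before impact, divided
  # by the post-contact inertia: positive rotates the model forward
  omega2 <- (m * (h * input$v_s1 + d * input$v_z1) + J * input$omega1) /
    (m * l^2 + J)
  # COM angle relative to the contact (0 = upright over the contact;
  # negative when the contact is ahead of the COM ground projection)
  theta0 <- atan2(-d, h)
  # energy left when the COM arrives upright over the contact
  ke_top <- 0.5 * (J + m * l^2) * omega2^2 - m * input$g * (l - h)
  ke_tol <- 0.5 * (J + m * l^2) * tol_omega^2
  if (theta0 <= 0) {
    # contact ahead of (or under) the COM: balancing needs forward rotation
    # that arrives upright with no energy to spare
    if (abs(ke_top) <= ke_tol && omega2 > -tol_omega) "balances"
    else if (omega2 <= 0) "falls_backward" # rotating away from the contact
    else if (ke_top > 0) "falls_forward"   # excess energy carries it over
    else "falls_backward"                  # reverses before reaching the top
  } else {
    # contact behind the COM: balancing needs backward rotation
    if (abs(ke_top) <= ke_tol && omega2 < tol_omega) "balances"
    else if (omega2 >= 0) "falls_forward"  # toppling away from the contact
    else if (ke_top > 0) "falls_backward"  # carried over, moving backward
    else "falls_forward"                   # reverses back towards +s
  }
}

#' Dynamic balance metric series
#'
#' For every sample: the vertical component of the average angular velocity
#' (`wz`, whose smallness is the 3D-projection applicability condition),
#' the dynamic balance margin `d_bf` (signed distance from the FPE point to
#' the BOS boundary, positive inside), and the COP-to-FPE displacement in
#' the turning (`fpe_cop_t`) and straight-step (`fpe_cop_s`) directions.
#' Samples with a degenerate travel frame or non-converged solver propagate
#' as `NA`.
#'
#' @param wbs a [whole_body_series()].
#' @param bos the whole-body [bos_polygon()].
#' @param cop n x 2 matrix of COP positions on the ground plane (m).
#' @param samples optional integer vector restricting evaluation to a
#'   subset of samples (others stay `NA`); used to keep cohort-scale runs
#'   cheap when only seat-off values are needed.
#' @param g gravitational acceleration (m/s^2).
#' @return data.frame of class `sts_dynamic_metrics` with columns `time`,
#'   `wz`, `d_bf`, `fpe_cop_t`, `fpe_cop_s`, `fpe_x`, `fpe_y`, `phi`,
#'   `converged`.
#' @export
dynamic_metrics <- function(wbs, bos, cop, samples = NULL, g = GRAVITY) {
  n <- wbs$n
  if (is.null(samples)) samples <- seq_len(n)
  out <- data.frame(time = wbs$time, wz = wbs$omega_avg[, 3L],
                    d_bf = NA_real_, fpe_cop_t = NA_real_,
                    fpe_cop_s = NA_real_, fpe_x = NA_real_, fpe_y = NA_real_,
                    phi = NA_real_, converged = NA)
  prev <- NULL
  for (i in samples) {
    if (wbs$singular[i] || anyNA(wbs$omega_avg[i, ])) next
    st <- wbs_at(wbs, i)
    fr <- travel_frame(st$H_G, v_C = st$v_C, prev = prev)
    if (is.null(fr)) next
    prev <- fr
    inp <- project_state(st, fr, g = g)
    r_G <- c(st$r_C[1:2], 0)
    sol <- solve_fpe(inp, r_G = r_G, s_hat = fr$s)
    if (!sol$converged) next
    Fxy <- sol$r_F[1:2]
    out$fpe_x[i] <- Fxy[1L]; out$fpe_y[i] <- Fxy[2L]
    out$phi[i] <- sol$phi
    out$converged[i] <- TRUE
    out$d_bf[i] <- signed_distance(Fxy, bos)
    pf <- c(Fxy - cop[i, ], 0)
    out$fpe_cop_t[i] <- sum(pf * fr$t)
    out$fpe_cop_s[i] <- sum(pf * fr$s)
  }
  class(out) <- c("sts_dynamic_metrics", "data.frame")
  out
}

#' Applicability flags for the 3D FPE projection
#'
#' The planar FPE extends to 3D without information loss only when the
#' vertical component of the average angular velocity is negligible; the
#' still-standing envelope of `wz` operationalizes "negligible". Flagged
#' samples are cautioned, not suppressed.
#'
#' @param wz numeric vector of vertical average angular velocity (rad/s).
#' @param bound still-standing bound on `|wz|` (rad/s).
#' @return logical vector, `TRUE` where the projection assumption holds.
#' @export
applicability_check <- function(wz, bound) {
  abs(wz) <= bound
}
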