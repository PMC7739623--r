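# Travel frame, planar projection, residual, solver, post-contact
# trichotomy and dynamic metrics.

fpe_input <- function(m = 70, h = 0.95, v_s1 = 0.4, v_z1 = 0.2,
                      omega1 = 0.5, J = 8, g = 9.81) {
  structure(list(m = m, h = h, v_s1 = v_s1, v_z1 = v_z1, omega1 = omega1,
                 J = J, g = g), class = "fpe_input")
}

# independent term-by-term coding of the balance residual
residual_oracle <- function(phi, p) {
  cp <- cos(phi); sp <- sin(phi)
  top <- p$m * p$h * (p$v_s1 * cp + p$v_z1 * sp) * cp + p$J * p$omega1 * cp * cp
  top * top / (p$m * p$h * p$h + p$J * cp * cp) +
    2 * p$m * p$g * p$h * cp * (cp - 1)
}

test_that("travel frame follows horizontal H_G with documented fallbacks", {
  fr <- travel_frame(c(0, 5, 0))
  expect_equal(fr$t, c(0, 1, 0))
  expect_equal(fr$s, c(1, 0, 0))
  # purely vertical H_G: previous frame reused, then velocity heading
  prev <- fr
  expect_identical(travel_frame(c(0, 0, 3), prev = prev), prev)
  fr2 <- travel_frame(c(0, 0, 3), v_C = c(0.2, 0.1, 0.5))
  expect_equal(fr2$s, c(0.2, 0.1, 0) / sqrt(0.05), tolerance = 1e-12)
  expect_null(travel_frame(c(0, 0, 3)))
  # yaw equivariance
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  H <- c(2, -1, 0.0)
  fr3 <- travel_frame(H)
  fr4 <- travel_frame(as.numeric(Rz %*% H))
  expect_equal(fr4$t, as.numeric(Rz %*% fr3$t), tolerance = 1e-12)
  expect_equal(fr4$s, as.numeric(Rz %*% fr3$s), tolerance = 1e-12)
})

test_that("state projection extracts the planar quantities", {
  fr <- travel_frame(c(0, 5, 0))
  st <- list(m = 70, h = 0.9, v_C = 0.5 * fr$s, omega_avg = c(0, 0.3, 0),
             J_C = diag(c(4, 7, 9)))
  p <- project_state(st, fr)
  expect_equal(p$v_s1, 0.5)
  expect_equal(p$v_z1, 0)
  expect_equal(p$J, 7)      # t = y picks the (2,2) inertia element
  expect_equal(p$omega1, 0.3)
  set.seed(301)
  for (rep in 1:5) {
    Hh <- c(rnorm(2), 0)
    fr <- travel_frame(Hh)
    A <- matrix(rnorm(9), 3); JC <- crossprod(A) + diag(3)
    st <- list(m = runif(1, 40, 100), h = runif(1, 0.7, 1.2),
               v_C = rnorm(3), omega_avg = rnorm(3), J_C = JC)
    p <- project_state(st, fr)
    expect_equal(p$v_s1, sum(st$v_C * fr$s), tolerance = 1e-12)
    expect_equal(p$v_z1, st$v_C[3], tolerance = 1e-12)
    expect_equal(p$J, as.numeric(t(fr$t) %*% JC %*% fr$t), tolerance = 1e-12)
  }
  st$h <- -0.1
  expect_error(project_state(st, fr), "positive")
})

test_that("residual matches an independent implementation and its known values", {
  p0 <- fpe_input(v_s1 = 0, v_z1 = 0, omega1 = 0)
  expect_equal(fpe_residual(0, p0), 0)
  p1 <- fpe_input(v_s1 = 0.8, v_z1 = 0, omega1 = 0)
  expect_equal(fpe_residual(0, p1),
               (p1$m * p1$h * 0.8)^2 / (p1$m * p1$h^2 + p1$J))
  set.seed(302)
  for (rep in 1:50) {
    p <- random_fpe_input()
    phi <- runif(1, -1.4, 1.4)
    expect_equal(fpe_residual(phi, p), residual_oracle(phi, p),
                 tolerance = 1e-12)
  }
  # analytic derivative agrees with a numerical one
  for (rep in 1:20) {
    p <- random_fpe_input()
    phi <- runif(1, 0.05, 1.3)
    eps <- 1e-6
    dnum <- (fpe_residual(phi + eps, p) - fpe_residual(phi - eps, p)) / (2 * eps)
    expect_equal(stsbalance:::fpe_residual_deriv(phi, p), dnum,
                 tolerance = 1e-4)
  }
})

test_that("solver handles static input, the J = 0 closed form, and a frozen grid case", {
  sol0 <- solve_fpe(fpe_input(v_s1 = 0, v_z1 = 0, omega1 = 0),
                    r_G = c(0.2, 0.1, 0), s_hat = c(1, 0, 0))
  expect_equal(sol0$phi, 0)
  expect_equal(sol0$r_F, c(0.2, 0.1, 0))
  # J = 0, v_z = 0, w1 = 0: the balance equation collapses to the cubic
  # v^2 c^3 = 2 g h (1 - c) in c = cos(phi) (momentum-conserving contact,
  # then energy balance); solve it independently of the FPE solver
  for (v in c(0.2, 0.5, 1, 1.5, 2)) {
    p <- fpe_input(v_s1 = v, v_z1 = 0, omega1 = 0, J = 0, h = 1, m = 70)
    sol <- solve_fpe(p)
    croot <- stats::uniroot(function(cc) v^2 * cc^3 - 2 * p$g * p$h * (1 - cc),
                            c(1e-9, 1), tol = 1e-14)$root
    expect_equal(sol$phi, acos(croot), tolerance = 1e-10)
  }
  # the worked case: phi equals the dense grid argmin over the physical
  # bracket
  p <- fpe_input()
  sol <- solve_fpe(p)
  expect_equal(sol$phi, fpe_grid_oracle(p), tolerance = 1e-6)
  expect_true(sol$converged)
})

test_that("solutions satisfy the post-contact energy balance", {
  set.seed(303)
  for (rep in 1:100) {
    p <- random_fpe_input()
    sol <- solve_fpe(p)
    expect_true(sol$converged)
    lhs <- 0.5 * (p$J + p$m * sol$l^2) * sol$omega2^2
    rhs <- p$m * p$g * (sol$l - p$h)
    if (rhs > 1e-12) expect_lt(abs(lhs - rhs), 1e-9 * max(rhs, 1))
  }
})

test_that("phi grows with forward speed and mirrors for backward travel", {
  phis <- sapply(seq(0.1, 1.9, by = 0.2), function(v)
    solve_fpe(fpe_input(v_s1 = v))$phi)
  expect_true(all(diff(phis) > 0))
  p <- fpe_input(v_s1 = -0.6)
  pm <- fpe_input(v_s1 = 0.6, omega1 = -p$omega1)
  expect_equal(solve_fpe(p)$phi, -solve_fpe(pm)$phi, tolerance = 1e-12)
})

test_that("post-contact outcome is a trichotomy around the FPE", {
  set.seed(304)
  for (rep in 1:25) {
    p <- random_fpe_input()
    p$v_s1 <- runif(1, 0.3, 2)   # meaningfully moving forward
    sol <- solve_fpe(p)
    d_star <- p$h * tan(sol$phi)
    expect_identical(post_contact_outcome(p, d_star), "balances")
    expect_identical(post_contact_outcome(p, d_star - 0.05), "falls_forward")
    expect_identical(post_contact_outcome(p, d_star + 0.05), "falls_backward")
  }
})

test_that("dynamic metrics read the FPE against BOS and COP", {
  spec <- sts_cohort_spec(n_young = 2, n_old = 2, seed = 31,
                          noise_sd_marker = 0, noise_sd_force = 0)
  tr <- generate_sts_trial(spec, 1, 1)
  pt <- preprocess(tr)
  wbs <- whole_body_series(pt)
  tpl <- default_template_cached()
  bosr <- trial_bos(pt, tpl)
  i <- tr$ground_truth$i_seatoff
  dm <- dynamic_metrics(wbs, bosr$bos, pt$foot$cop, samples = i)
  truth <- trial_seatoff_truth(tr, tpl)
  expect_lt(abs(dm$d_bf[i] - truth["d_bf"]), 5e-3)
  expect_lt(abs(dm$fpe_cop_s[i] - truth["fpe_cop_s"]), 5e-3)
  expect_lt(abs(dm$wz[i]), 1e-3)
  # planar motion: the projection assumption holds everywhere
  b <- 0.01
  expect_true(all(applicability_check(dm$wz[i], b)))
  expect_false(applicability_check(2 * b, b))
})
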