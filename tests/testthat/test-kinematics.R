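# Whole-body aggregation: COM, inertia, angular momentum, average angular
# velocity, and the signal conditioning (zero-phase filtering and
# differentiation).

test_that("whole-body COM matches direct mass-weighted summation", {
  s1 <- segment_state(2, c(1, 0, 0))
  expect_equal(whole_body_com(list(s1))$r_C, c(1, 0, 0))
  # two equal masses at +/-1 on x: COM at the origin
  pair <- list(segment_state(3, c(1, 0, 0)), segment_state(3, c(-1, 0, 0)))
  expect_equal(whole_body_com(pair)$r_C, c(0, 0, 0))
  set.seed(101)
  for (rep in 1:5) {
    segs <- replicate(5, random_segment(), simplify = FALSE)
    com <- whole_body_com(segs)
    M <- sum(sapply(segs, `[[`, "m"))
    r_o <- colSums(t(sapply(segs, function(s) s$m * s$r))) / M
    v_o <- colSums(t(sapply(segs, function(s) s$m * s$v))) / M
    expect_equal(com$r_C, r_o, tolerance = 1e-12)
    expect_equal(com$v_C, v_o, tolerance = 1e-12)
  }
  expect_error(whole_body_com(list()), "at least one")
})

test_that("inertia about COM reproduces the parallel-axis summation", {
  # single segment at the COM: J_C is its own inertia
  s <- random_segment()
  s$r <- c(0, 0, 0)
  expect_equal(inertia_about_com(list(s)), s$J)
  # two unit point masses at (+/-1, 0, 0): diag(0, 2, 2)
  pm <- list(segment_state(1, c(1, 0, 0), J = diag(0, 3)),
             segment_state(1, c(-1, 0, 0), J = diag(0, 3)))
  expect_equal(inertia_about_com(pm), diag(c(0, 2, 2)))
  # random 4-segment body vs term-by-term oracle
  set.seed(102)
  for (rep in 1:5) {
    segs <- replicate(4, random_segment(), simplify = FALSE)
    r_C <- whole_body_com(segs)$r_C
    Jo <- matrix(0, 3, 3)
    for (s in segs) {
      rho <- s$r - r_C
      Jo <- Jo + s$J + s$m * (sum(rho^2) * diag(3) - rho %*% t(rho))
    }
    expect_equal(inertia_about_com(segs), Jo, tolerance = 1e-12)
  }
})

test_that("angular momentum about COM matches the summation oracle", {
  rest <- replicate(3, {
    s <- random_segment(); s$v <- c(0, 0, 0); s$omega <- c(0, 0, 0); s
  }, simplify = FALSE)
  expect_equal(angular_momentum_about_com(rest), c(0, 0, 0))
  # one rigid body spinning about its own COM: H = J omega
  s <- random_segment(); s$v <- c(0, 0, 0)
  expect_equal(angular_momentum_about_com(list(s)),
               as.numeric(s$J %*% s$omega))
  set.seed(103)
  for (rep in 1:5) {
    segs <- replicate(4, random_segment(), simplify = FALSE)
    com <- whole_body_com(segs)
    Ho <- c(0, 0, 0)
    for (s in segs) {
      rho <- s$r - com$r_C
      dv <- s$m * (s$v - com$v_C)
      Ho <- Ho + as.numeric(s$J %*% s$omega) +
        c(rho[2] * dv[3] - rho[3] * dv[2],
          rho[3] * dv[1] - rho[1] * dv[3],
          rho[1] * dv[2] - rho[2] * dv[1])
    }
    expect_equal(angular_momentum_about_com(segs), Ho, tolerance = 1e-12)
  }
})

test_that("average angular velocity solves J_C w = H_C and flags singularity", {
  # a single rigid body recovers its own angular velocity exactly
  s <- random_segment()
  st <- whole_body_state(list(s))
  expect_equal(st$omega_avg, s$omega, tolerance = 1e-12)
  expect_equal(average_angular_velocity(st$J_C, c(0, 0, 0)), c(0, 0, 0))
  set.seed(104)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3); J <- crossprod(A) + 0.1 * diag(3)
    H <- rnorm(3)
    w <- average_angular_velocity(J, H)
    expect_lt(sqrt(sum((J %*% w - H)^2)), 1e-10 * sqrt(sum(H^2)))
  }
  expect_true(all(is.na(average_angular_velocity(diag(0, 3), c(1, 0, 0)))))
})

test_that("frame equivariance: rotated bodies give rotated aggregates", {
  set.seed(105)
  segs <- replicate(4, random_segment(), simplify = FALSE)
  R <- random_rotation()
  segsR <- lapply(segs, rotate_segment, R = R)
  a <- whole_body_state(segs)
  b <- whole_body_state(segsR)
  expect_equal(b$r_C, as.numeric(R %*% a$r_C), tolerance = 1e-12)
  expect_equal(b$v_C, as.numeric(R %*% a$v_C), tolerance = 1e-12)
  expect_equal(b$H_C, as.numeric(R %*% a$H_C), tolerance = 1e-12)
  expect_equal(b$J_C, R %*% a$J_C %*% t(R), tolerance = 1e-12)
})

test_that("merging arm mass into the trunk preserves total mass", {
  # the chest-condition reduction: removing a segment and adding its mass
  # to another leaves the summed mass (and the COM, when collocated)
  # unchanged
  set.seed(106)
  segs <- replicate(4, random_segment(), simplify = FALSE)
  M0 <- sum(sapply(segs, `[[`, "m"))
  merged <- segs[-1]
  merged[[1]]$m <- merged[[1]]$m + segs[[1]]$m
  expect_equal(sum(sapply(merged, `[[`, "m")), M0)
})

test_that("bidirectional Butterworth filter has the designed magnitude and zero phase", {
  fs <- 150
  t <- seq(0, 10, by = 1 / fs)
  const <- rep(2.5, length(t))
  expect_equal(lowpass_filter(const, fs, 10), const, tolerance = 1e-9)
  # 1 Hz passes nearly untouched; 50 Hz is crushed (|H|^2 of a 4th-order
  # Butterworth at 10 Hz, applied twice)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_filter(s1, fs, 10)
  mid <- 300:1200
  amp1 <- max(abs(f1[mid]))
  expect_gt(amp1, 0.99)
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(max(abs(lowpass_filter(s50, fs, 10)[mid])), 0.05)
  # zero phase: away from the edges the filtered 1 Hz sinusoid overlays
  # the raw one (any phase lag would show as a large pointwise deviation)
  expect_lt(max(abs(f1[mid] - s1[mid])), 0.01)
})

test_that("central differences differentiate smooth signals accurately", {
  fs <- 150
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * t)
  d <- central_diff(x, 1 / fs)
  expect_equal(d[10:250], 2 * pi * cos(2 * pi * t[10:250]), tolerance = 1e-3)
})

test_that("preprocess aligns plates to the marker clock and rejects long gaps", {
  spec <- sts_cohort_spec(n_young = 2, n_old = 2, seed = 7)
  tr <- generate_sts_trial(spec, 1, 1)
  pt <- preprocess(tr)
  expect_equal(length(pt$seat$fz), length(pt$time))
  expect_equal(pt$fs_force, pt$fs_marker)
  expect_true(is.numeric(pt$seat$fz_raw))
  tr$markers$C7[100:150, ] <- NA   # 51-sample gap at 150 Hz (> 0.1 s)
  expect_error(preprocess(tr), class = "stsbalance_gap_error")
})
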