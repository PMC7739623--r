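# Two-stage segmentation: clustering, candidate rules, event refinement.

test_that("k-means++ clustering labels well-separated plateaus correctly", {
  x <- c(rep(0, 100), rep(0.5, 80), rep(1, 120))
  cl <- cluster_signal(x, seed = 1, role = "height")
  expect_identical(cl$labels, c(rep("seated", 100), rep("crouch", 80),
                                rep("standing", 120)))
  f <- c(rep(500, 100), rep(250, 80), rep(0, 120))
  clf <- cluster_signal(f, seed = 1, role = "force")
  expect_identical(clf$labels, c(rep("seated", 100), rep("transition", 80),
                                 rep("standing", 120)))
  # deterministic under the seed
  expect_identical(cluster_signal(x, seed = 7, role = "height"),
                   cluster_signal(x, seed = 7, role = "height"))
  expect_error(cluster_signal(c(1, 1, 2), role = "height"),
               "fewer distinct values")
})

test_that("noisy plateaus agree with the nearest-plateau assignment", {
  set.seed(401)
  centers <- c(0, 0.5, 1)
  truth <- rep(1:3, times = c(300, 200, 400))
  x <- centers[truth] + rnorm(900, sd = 0.03)
  cl <- cluster_signal(x, seed = 2, role = "height")
  oracle <- c("seated", "crouch", "standing")[apply(
    abs(outer(x, centers, "-")), 1, which.min)]
  expect_gt(mean(cl$labels == oracle), 0.99)
})

label_fixture <- function(fs = 150) {
  # 2 s seated, 1 s transition, 3 s standing
  hl <- c(rep("seated", 2 * fs), rep("crouch", fs), rep("standing", 3 * fs))
  fl <- c(rep("seated", 2 * fs), rep("transition", 0.6 * fs),
          rep("standing", 3.4 * fs))
  n <- length(hl)
  fz <- list(left = matrix(0, n, 6), right = matrix(0, n, 6))
  list(hl = hl, fl = fl, fz = fz, n = n)
}

test_that("candidate rules accept a clean sequence and reject designed violations", {
  fs <- 150
  fx <- label_fixture(fs)
  cands <- candidate_sequences(fx$hl, fx$fl, fx$fz, fs)
  expect_length(cands, 1)
  expect_true(cands[[1]]$accepted)

  # standing plateau of 0.4 s: short_standing
  hl2 <- c(rep("seated", 2 * fs), rep("crouch", fs),
           rep("standing", 0.4 * fs), rep("crouch", 2.6 * fs))
  c2 <- candidate_sequences(hl2, fx$fl, fx$fz, fs)
  expect_true(any(sapply(c2, function(x) x$reason == "short_standing")))

  # seated run of only 0.3 s: short_sitting
  fl3 <- c(rep("transition", 1.7 * fs), rep("seated", 0.3 * fs),
           rep("transition", 0.6 * fs), rep("standing", 3.4 * fs))
  c3 <- candidate_sequences(fx$hl, fl3, fx$fz, fs)
  expect_true(any(sapply(c3, function(x) x$reason == "short_sitting")))

  # bouncing force labels: more than one transition->standing switch
  fl4 <- c(rep("seated", 2 * fs), rep("transition", 0.2 * fs),
           rep("standing", 0.2 * fs), rep("transition", 0.2 * fs),
           rep("standing", 3.4 * fs))
  c4 <- candidate_sequences(fx$hl, fl4, fx$fz, fs)
  expect_true(any(sapply(c4, function(x) x$reason == "multiple_transitions")))

  # 4 of 6 left-foot markers rise 20 mm: foot_moved
  fz5 <- fx$fz
  fz5$left[350:420, 1:4] <- 0.020
  c5 <- candidate_sequences(fx$hl, fx$fl, fz5, fs)
  expect_true(any(sapply(c5, function(x) x$reason == "foot_moved")))
  # 3 of 6 stay put: acceptable
  fz6 <- fx$fz
  fz6$left[350:420, 1:3] <- 0.020
  c6 <- candidate_sequences(fx$hl, fx$fl, fz6, fs)
  expect_true(any(sapply(c6, function(x) isTRUE(x$accepted))))
})

test_that("event refinement hits the designed seat-off within one sample", {
  spec <- sts_cohort_spec(n_young = 2, n_old = 2, seed = 21)
  for (s in 1:2) {
    tr <- generate_sts_trial(spec, s, 1)
    res <- analyze_trial(tr, default_template_cached(), seed = 2)
    acc <- Filter(function(e) isTRUE(e$accepted), res$events)
    expect_length(acc, 1)
    err <- acc[[1]]$t_seatoff - tr$ground_truth$events$t_seatoff
    expect_lt(abs(err) * tr$fs_marker, 1 + 1e-9)
    expect_lt(acc[[1]]$t_init, acc[[1]]$t_seatoff)
    expect_lt(acc[[1]]$t_seatoff, acc[[1]]$t_stance)
  }
})

test_that("degenerate trials are rejected with a threshold reason", {
  fs <- 150
  fx <- label_fixture(fs)
  cand <- candidate_sequences(fx$hl, fx$fl, fx$fz, fs)[[1]]
  time <- (seq_len(fx$n) - 1) / fs
  # a seat force that oscillates around, but never comes within 1 N of,
  # the standing-cluster reference (its median)
  fz_far <- c(rep(500, 2 * fs), rep(c(90, 110), 2 * fs))
  ev <- refine_events(cand, com_speed = rep(1, fx$n), seat_fz_raw = fz_far,
                      com_height = rep(1, fx$n), com_vz = rep(0, fx$n),
                      height_labels = fx$hl, time = time)
  expect_false(ev$accepted)
  expect_identical(ev$reason, "no_seatoff")
  # constant COM speed: initiation threshold never crossed
  fz_ok <- c(rep(500, 2 * fs), seq(500, 0, length.out = 0.6 * fs),
             rep(0, 3.4 * fs))
  ev2 <- refine_events(cand, com_speed = rep(0.2, fx$n), seat_fz_raw = fz_ok,
                       com_height = rep(1, fx$n), com_vz = rep(0, fx$n),
                       height_labels = fx$hl, time = time)
  expect_false(ev2$accepted)
  expect_identical(ev2$reason, "no_initiation")
})

test_that("segmentation is deterministic and invariant to a uniform time shift", {
  spec <- sts_cohort_spec(n_young = 2, n_old = 2, seed = 23)
  tr <- generate_sts_trial(spec, 1, 1)
  pt <- preprocess(tr)
  e1 <- segment_sts(pt, seed = 5)
  e2 <- segment_sts(pt, seed = 5)
  expect_identical(e1, e2)
  # shift every clock by 10 s: event times shift by exactly 10 s
  tr2 <- tr
  tr2$time <- tr$time + 10
  tr2$seat$time <- tr$seat$time + 10
  tr2$foot$time <- tr$foot$time + 10
  pt2 <- preprocess(tr2)
  e3 <- segment_sts(pt2, seed = 5)
  a1 <- Filter(function(e) isTRUE(e$accepted), e1)[[1]]
  a3 <- Filter(function(e) isTRUE(e$accepted), e3)[[1]]
  expect_equal(a3$t_seatoff, a1$t_seatoff + 10, tolerance = 1e-9)
  expect_equal(a3$t_init, a1$t_init + 10, tolerance = 1e-9)
})

test_that("sit-back and foot-lift designs are rejected with their reasons", {
  spec <- sts_cohort_spec(n_young = 2, n_old = 2, seed = 25)
  sb <- analyze_trial(generate_sts_trial(spec, 1, 1, trial_type = "sit_back"),
                      default_template_cached(), seed = 3)
  expect_true(any(sapply(sb$events, function(e) e$reason == "sit_back")))
  expect_equal(sum(sapply(sb$events, function(e) isTRUE(e$accepted))), 1)
  fl <- analyze_trial(generate_sts_trial(spec, 2, 1, trial_type = "foot_lift"),
                      default_template_cached(), seed = 3)
  expect_true(any(sapply(fl$events, function(e) e$reason == "foot_moved")))
  expect_equal(sum(sapply(fl$events, function(e) isTRUE(e$accepted))), 0)
})
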