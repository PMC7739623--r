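# Shared fixtures: random segment generators and small cached objects.

# a random physically plausible segment state
random_segment <- function() {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  It <- runif(1, 0.01, 2); Il <- runif(1, 0.005, It)
  J <- It * (diag(3) - tcrossprod(u)) + Il * tcrossprod(u)
  segment_state(m = runif(1, 0.5, 30), r = rnorm(3), v = rnorm(3, sd = 0.5),
                J = J, omega = rnorm(3, sd = 1))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

rotate_segment <- function(s, R, about = c(0, 0, 0)) {
  segment_state(s$m, as.numeric(R %*% (s$r - about)) + about,
                as.numeric(R %*% s$v), R %*% s$J %*% t(R),
                as.numeric(R %*% s$omega))
}

# random physical planar FPE input (the acceptance-scale ranges)
random_fpe_input <- function() {
  structure(list(m = runif(1, 40, 100), h = runif(1, 0.7, 1.2),
                 v_s1 = runif(1, 0, 2), v_z1 = runif(1, -2, 2),
                 omega1 = runif(1, -3, 3), J = runif(1, 0, 15),
                 g = 9.81), class = "fpe_input")
}

# convex polygon with n random vertices (returns its bos_polygon)
random_polygon <- function(n = 8) {
  pts <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  bos_polygon(pts)
}

# brute-force signed distance oracle: winding-rule inside test plus
# min-over-edges point-segment distance (independent of the convexity
# shortcut in the implementation)
signed_distance_oracle <- function(p, poly) {
  V <- unclass(poly); m <- nrow(V)
  dmin <- Inf; wn <- 0
  for (j in seq_len(m)) {
    a <- V[j, ]; b <- V[if (j == m) 1 else j + 1, ]
    e <- b - a; w <- p - a
    tt <- max(0, min(1, sum(w * e) / sum(e^2)))
    dmin <- min(dmin, sqrt(sum((w - tt * e)^2)))
    if (a[2] <= p[2]) {
      if (b[2] > p[2] && (e[1] * w[2] - e[2] * w[1]) > 0) wn <- wn + 1
    } else {
      if (b[2] <= p[2] && (e[1] * w[2] - e[2] * w[1]) < 0) wn <- wn - 1
    }
  }
  if (wn != 0) dmin else -dmin
}

default_template_cached <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- default_bos_template()
    tpl
  }
})

# dense grid-scan oracle for the FPE angle: argmin of |residual| over the
# physical bracket, restricted to angles where the (independently
# recomputed) contact momentum is non-negative -- the residual squares
# that momentum, so it also vanishes at rotation-reversed angles that are
# not balance solutions
fpe_grid_oracle <- function(p, n_grid = 1e6) {
  grid <- seq(0, 0.95 * pi / 2, length.out = n_grid)
  cg <- cos(grid); sg <- sin(grid)
  momentum <- p$m * p$h * (p$v_s1 * cg + p$v_z1 * sg) * cg +
    p$J * p$omega1 * cg^2
  f <- fpe_residual(grid, p)
  ok <- momentum >= 0
  grid[ok][which.min(abs(f[ok]))]
}

mirror_fpe_input <- function(p) {
  p$v_s1 <- -p$v_s1
  p$omega1 <- -p$omega1
  p
}

withr_like_tempdir <- function() {
  d <- tempfile("stsb")
  dir.create(d)
  d
}
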