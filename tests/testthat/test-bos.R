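# Foot frames, foot dimensions, flat-foot test, template building,
# scaling and signed distances.

canonical_foot <- function() {
  # flat foot pointing +y: ankles on the x axis, toes at +y
  list(FAL = c(-0.04, 0, 0.065), TAM = c(0.04, 0, 0.065),
       FM1 = c(0.045, 0.16, 0.025), FM5 = c(-0.045, 0.16, 0.025),
       FM2 = c(0.005, 0.19, 0.028), FCC = c(0, -0.06, 0.045))
}

test_that("foot frame axes follow the marker construction and rotate with the foot", {
  mk <- canonical_foot()
  fr <- foot_frame(mk)
  expect_equal(fr$origin, c(0, 0, 0.065))
  expect_equal(as.numeric(crossprod(fr$x, fr$y)), 0, tolerance = 1e-12)
  expect_equal(fr$z, cross3(fr$x, fr$y), tolerance = 1e-12)
  # y points towards the metatarsals
  expect_gt(sum(fr$y * c(0, 1, 0)), 0.95)
  # equivariance under a yaw rotation of the whole marker set
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  mkR <- lapply(mk, function(p) as.numeric(Rz %*% p))
  frR <- foot_frame(mkR)
  expect_equal(frR$x, as.numeric(Rz %*% fr$x), tolerance = 1e-12)
  expect_equal(frR$y, as.numeric(Rz %*% fr$y), tolerance = 1e-12)
  mk$TAM <- mk$FAL
  expect_error(foot_frame(mk), "coincide")
})

test_that("foot dimensions recover the designed width and length, invariant to rotation", {
  mk <- canonical_foot()
  d <- foot_dimensions(mk)
  expect_equal(unname(d["w"]), 0.085, tolerance = 1e-9)
  # l = y . (FM2 - FCC); the y axis is slightly pitched by the marker
  # heights, so compare against the same construction
  fr <- foot_frame(mk)
  expect_equal(unname(d["l"]), sum(fr$y * (mk$FM2 - mk$FCC)), tolerance = 1e-12)
  R <- random_rotation()
  mkR <- lapply(mk, function(p) as.numeric(R %*% p))
  dR <- foot_dimensions(mkR)
  expect_equal(unname(dR), unname(d), tolerance = 1e-9)
  mk2 <- canonical_foot()
  mk2$FM2 <- mk2$FCC + c(0, -0.01, 0)   # toe marker behind the heel
  expect_error(foot_dimensions(mk2), "length")
})

test_that("flat-foot test applies the 1.5 cm allowance inclusively", {
  w <- 0.09; l <- 0.25
  expect_true(foot_is_flat(diag(3), w, l))
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  # w sin(psi) exactly at the bound: still flat (inclusive)
  a_eq <- asin(0.015 / w)
  expect_true(foot_is_flat(rx(a_eq), w, l))
  # 1.6 cm displacement: not flat
  a_over <- asin(0.016 / w)
  expect_false(foot_is_flat(rx(a_over), w, l))
})

test_that("signed distance agrees exactly with the edge-enumeration oracle", {
  sq <- bos_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(signed_distance(c(0.5, 0.5), sq), 0.5)
  expect_equal(signed_distance(c(1.5, 0.5), sq), -0.5)
  expect_equal(signed_distance(c(1, 0.5), sq), 0)
  set.seed(201)
  for (rep in 1:20) {
    poly <- random_polygon(10)
    pts <- cbind(runif(50, -1.5, 1.5), runif(50, -1.5, 1.5))
    d <- signed_distance(pts, poly)
    d_o <- apply(pts, 1, signed_distance_oracle, poly = poly)
    expect_equal(d, d_o, tolerance = 1e-12)
  }
})

test_that("signed distance is Lipschitz-1 and continuous across the boundary", {
  set.seed(202)
  poly <- random_polygon(8)
  p <- cbind(runif(200, -1.5, 1.5), runif(200, -1.5, 1.5))
  q <- p + matrix(rnorm(400, sd = 0.01), ncol = 2)
  dd <- abs(signed_distance(p, poly) - signed_distance(q, poly))
  step <- sqrt(rowSums((p - q)^2))
  expect_true(all(dd <= step + 1e-12))
})

test_that("ray-averaged template of two concentric squares has the mean radius", {
  sqr <- function(a) cbind(c(-a, a, a, -a), c(-a, -a, a, a))
  # profiles in physical units with w = l = 1 so normalization is identity
  prof <- function(a) list(cop = sqr(a), force = rep(1000, 4),
                           flat = rep(TRUE, 4), w = 1, l = 1, side = "left")
  tpl <- build_template(list(prof(0.2), prof(0.4)), body_weight = 100,
                        center = c(0, 0), n_rays = 3600)
  # oracle: mean of the two squares' radii along dense rays
  ang <- seq(0, 2 * pi, length.out = 3601)[-3601]
  r1 <- polygon_ray_radii(bos_polygon(sqr(0.2)), c(0, 0), ang)
  r2 <- polygon_ray_radii(bos_polygon(sqr(0.4)), c(0, 0), ang)
  r_o <- (r1 + r2) / 2
  r_t <- polygon_ray_radii(bos_polygon(tpl$vertices), c(0, 0), ang)
  # the template is the convex hull of the ray average, so compare hulls
  pts_o <- cbind(r_o * cos(ang), r_o * sin(ang))
  area_o <- abs(stsbalance:::polygon_area(stsbalance:::convex_hull_ccw(pts_o)))
  area_t <- abs(stsbalance:::polygon_area(tpl$vertices))
  expect_equal(area_t, area_o, tolerance = 1e-4)
  expect_equal(max(abs(r_t - pmax(r_o, r_t))), 0, tolerance = 1e-6)
})

test_that("a single square profile yields that square and mirrored pairs are symmetric", {
  sq <- cbind(c(-0.3, 0.5, 0.5, -0.3), c(-0.2, -0.2, 0.8, 0.8))
  prof <- list(cop = sq, force = rep(1000, 4), flat = rep(TRUE, 4),
               w = 1, l = 1, side = "left")
  tpl <- build_template(list(prof), body_weight = 100, center = c(0, 0.2),
                        n_rays = 720)
  expect_equal(abs(stsbalance:::polygon_area(tpl$vertices)), 0.8, tolerance = 1e-3)
  # left profile plus its mirrored right copy: since both foot frames
  # point their x axes medially, the physical mirror of the left foot has
  # identical coordinates in the right-foot frame; the builder reflects
  # it into left-foot space, making the averaged template symmetric
  profR <- prof
  profR$side <- "right"
  tpl2 <- build_template(list(prof, profR), body_weight = 100,
                         center = c(0, 0.2), n_rays = 360)
  v <- tpl2$vertices
  mirrored <- cbind(-v[, 1], v[, 2])
  d <- signed_distance(mirrored, bos_polygon(v))
  expect_lt(max(abs(d)), 1e-12)
})

test_that("template filtering errors on too few valid points", {
  sq <- cbind(c(-0.3, 0.5, 0.5, -0.3), c(-0.2, -0.2, 0.8, 0.8))
  low <- list(cop = sq, force = rep(10, 4), flat = rep(TRUE, 4),
              w = 1, l = 1, side = "left")
  expect_error(build_template(list(low), body_weight = 700), "too few valid")
  tilted <- list(cop = sq, force = rep(1000, 4), flat = rep(FALSE, 4),
                 w = 1, l = 1, side = "left")
  expect_error(build_template(list(tilted), body_weight = 700), "too few valid")
})

test_that("template scaling is exact and invertible", {
  tpl <- default_template_cached()
  id_frame <- structure(list(origin = c(0, 0, 0), x = c(1, 0, 0),
                             y = c(0, 1, 0), z = c(0, 0, 1)),
                        class = "foot_frame")
  p1 <- scale_template(tpl, 1, 1, id_frame, "left")
  expect_equal(unclass(p1), stsbalance:::convex_hull_ccw(tpl$vertices),
               tolerance = 1e-12, ignore_attr = TRUE)
  # doubling w doubles only the x extent
  p2 <- scale_template(tpl, 2, 1, id_frame, "left")
  expect_equal(diff(range(p2[, 1])), 2 * diff(range(p1[, 1])), tolerance = 1e-12)
  expect_equal(diff(range(p2[, 2])), diff(range(p1[, 2])), tolerance = 1e-12)
  # translation equivariance
  tr_frame <- id_frame; tr_frame$origin <- c(0.3, -0.2, 0)
  p3 <- scale_template(tpl, 1, 1, tr_frame, "left")
  expect_equal(unclass(p3), sweep(unclass(p1), 2, c(-0.3, 0.2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("whole-body BOS is the hull of both feet and contains every vertex", {
  a <- bos_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(abs(stsbalance:::polygon_area(whole_body_bos(a, a))), 1)
  b <- bos_polygon(cbind(c(2, 3, 3, 2), c(0, 0, 1, 1)))
  hull <- whole_body_bos(a, b)
  expect_equal(abs(stsbalance:::polygon_area(hull)), 3)
  set.seed(203)
  for (rep in 1:10) {
    p1 <- random_polygon(6); p2 <- random_polygon(6)
    h <- whole_body_bos(p1, p2)
    d <- signed_distance(rbind(unclass(p1), unclass(p2)), h)
    expect_true(all(d >= -1e-12))
  }
})
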