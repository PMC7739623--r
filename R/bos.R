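# Functional base-of-support (BOS) model: foot-fixed frames, foot
# dimensions, flat-foot test, COP-derived template polygon (normalized,
# ray-averaged, convex), per-foot scaling back to the world ground plane,
# the whole-body BOS hull and signed distances to it.

# ---- polygon primitives ---------------------------------------------------

polygon_area <- function(P) {
  x <- P[, 1L]; y <- P[, 2L]
  j <- c(seq_len(nrow(P))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# convex hull, counter-clockwise, no repeated closing vertex
convex_hull_ccw <- function(P) {
  idx <- grDevices::chull(P[, 1L], P[, 2L])
  H <- P[idx, , drop = FALSE]
  if (polygon_area(H) < 0) H <- H[rev(seq_len(nrow(H))), , drop = FALSE]
  H
}

#' Construct a convex BOS polygon
#'
#' Takes the convex hull of the supplied ground-plane points and stores it
#' counter-clockwise. Degenerate (zero-area) hulls are an error.
#'
#' @param vertices numeric matrix (n x 2) of ground-plane points (m).
#' @return object of class `bos_polygon` (a CCW convex vertex matrix).
#' @export
bos_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  H <- convex_hull_ccw(vertices)
  if (nrow(H) < 3L || polygon_area(H) <= 0)
    stop("degenerate BOS polygon (zero area)")
  structure(H, class = c("bos_polygon", "matrix", "array"))
}

#' Signed distance from points to a convex polygon boundary
#'
#' Positive inside, negative outside, zero on the boundary: the sign
#' convention used for both the static margin (COM ground projection) and
#' the dynamic balance margin (FPE point).
#'
#' @param points numeric vector of length 2 or an (n x 2) matrix.
#' @param polygon a [bos_polygon()] (CCW convex vertex matrix).
#' @return numeric vector of signed distances (m).
#' @export
signed_distance <- function(points, polygon) {
  P <- if (is.matrix(points)) points else matrix(points, ncol = 2L)
  V <- unclass(polygon)
  m <- nrow(V)
  n <- nrow(P)
  inside <- rep(TRUE, n)
  dmin <- rep(Inf, n)
  for (j in seq_len(m)) {
    a <- V[j, ]
    b <- V[if (j == m) 1L else j + 1L, ]
    e <- b - a
    wx <- P[, 1L] - a[1L]; wy <- P[, 2L] - a[2L]
    cr <- e[1L] * wy - e[2L] * wx
    inside <- inside & (cr >= -1e-15)
    tt <- pmin(1, pmax(0, (wx * e[1L] + wy * e[2L]) / sum(e^2)))
    dx <- wx - tt * e[1L]; dy <- wy - tt * e[2L]
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  ifelse(inside, dmin, -dmin)
}

# radius of a convex polygon boundary from an interior point, along each of
# `angles` (rad); vectorized over angles
polygon_ray_radii <- function(P, center, angles) {
  V <- unclass(P)
  m <- nrow(V)
  dx <- cos(angles); dy <- sin(angles)
  r <- rep(Inf, length(angles))
  for (j in seq_len(m)) {
    a <- V[j, ] - center
    b <- V[if (j == m) 1L else j + 1L, ] - center
    e <- b - a
    den <- dx * (-e[2L]) + dy * e[1L]     # cross(d, e) with sign flip
    tt <- (a[1L] * (-e[2L]) + a[2L] * e[1L]) / den   # ray parameter
    # intersection point must lie within the edge segment
    s <- if (abs(e[1L]) > abs(e[2L])) (tt * dx - a[1L]) / e[1L]
         else (tt * dy - a[2L]) / e[2L]
    ok <- is.finite(tt) & tt > 0 & s >= -1e-12 & s <= 1 + 1e-12
    r[ok] <- pmin(r[ok], tt[ok])
  }
  if (any(!is.finite(r)))
    stop("ray sampling failed: center not interior to the polygon")
  r
}

# ---- foot frame -----------------------------------------------------------

#' Foot-fixed coordinate frame from the six foot markers
#'
#' The origin sits midway between the ankle markers FAL and TAM; the y-axis
#' points from there towards the midpoint of the first and fifth metatarsal
#' markers (FM1, FM5); the x-axis is the component of (TAM - FAL)
#' perpendicular to y; z completes the right-handed triad. With
#' `flatten = TRUE` the frame is re-anchored to the ground plane as done
#' after quiet-standing calibration: the origin is dropped to z = 0, z-hat
#' is set vertical and y-hat to the horizontal component of the raw y axis.
#'
#' @param markers named list with 3-vectors (or n x 3 matrices averaged
#'   over rows) `FAL`, `TAM`, `FM1`, `FM2`, `FM5`, `FCC`.
#' @param flatten logical; return the ground-plane calibrated frame.
#' @return list with `origin` and unit axes `x`, `y`, `z` (class
#'   `foot_frame`).
#' @export
foot_frame <- function(markers, flatten = FALSE) {
  need <- c("FAL", "TAM", "FM1", "FM2", "FM5", "FCC")
  stopifnot(all(need %in% names(markers)))
  g <- function(nm) {
    v <- markers[[nm]]
    if (is.matrix(v)) colMeans(v) else as.numeric(v)
  }
  FAL <- g("FAL"); TAM <- g("TAM"); FM1 <- g("FM1"); FM5 <- g("FM5")
  origin <- (FAL + TAM) / 2
  yraw <- (FM1 + FM5) / 2 - origin
  if (sqrt(sum(yraw^2)) < 1e-9) stop("degenerate foot markers (ankle/toe coincide)")
  y <- unitv(yraw)
  xr <- TAM - FAL
  if (sqrt(sum(xr^2)) < 1e-9) stop("degenerate foot markers (FAL and TAM coincide)")
  x <- xr - sum(xr * y) * y
  if (sqrt(sum(x^2)) < 1e-9) stop("degenerate foot markers (colinear)")
  x <- unitv(x)
  z <- cross3(x, y)
  if (flatten) {
    z <- c(0, 0, 1)
    yh <- c(y[1L], y[2L], 0)
    if (sqrt(sum(yh^2)) < 1e-9) stop("foot y axis is vertical; cannot flatten")
    y <- unitv(yh)
    x <- cross3(y, z)
    origin <- c(origin[1L], origin[2L], 0)
  }
  structure(list(origin = origin, x = x, y = y, z = z), class = "foot_frame")
}

#' Foot width and length from the markers
#'
#' Width `w = x . (0.5 (TAM - FAL) + 0.5 (FM1 - FM5))` and length
#' `l = y . (FM2 - FCC)`, both in the foot frame axes.
#'
#' @inheritParams foot_frame
#' @param frame optional precomputed [foot_frame()].
#' @return named numeric `c(w = , l = )` in metres.
#' @export
foot_dimensions <- function(markers, frame = NULL) {
  if (is.null(frame)) frame <- foot_frame(markers)
  g <- function(nm) {
    v <- markers[[nm]]
    if (is.matrix(v)) colMeans(v) else as.numeric(v)
  }
  w <- sum(frame$x * (0.5 * (g("TAM") - g("FAL")) + 0.5 * (g("FM1") - g("FM5"))))
  l <- sum(frame$y * (g("FM2") - g("FCC")))
  if (w <= 0) stop("non-positive foot width")
  if (l <= 0) stop("non-positive foot length (FM2 behind FCC?)")
  c(w = w, l = l)
}

# rotation of the instantaneous foot frame relative to a (flattened)
# reference frame, expressed in reference axes
foot_rotation <- function(frame_now, frame_ref) {
  Fn <- cbind(frame_now$x, frame_now$y, frame_now$z)
  Fr <- cbind(frame_ref$x, frame_ref$y, frame_ref$z)
  t(Fr) %*% Fn
}

#' Is the foot flat on the ground?
#'
#' Uses the X-Y'-Z'' Euler decomposition of the foot rotation relative to
#' its ground-calibrated reference: the foot counts as flat while the edge
#' drop on either axis, `w |sin psi_x|` and `l |sin theta_y|`, stays within
#' the compression allowance of the foot pad plus shoe sole (1.5 cm by
#' default, inclusive bound).
#'
#' @param rotation 3x3 rotation matrix of the foot frame relative to its
#'   flattened reference (see `foot_rotation`).
#' @param w,l foot width and length (m).
#' @param tol allowance (m), default 0.015.
#' @return logical.
#' @export
foot_is_flat <- function(rotation, w, l, tol = 0.015) {
  th_y <- asin(max(-1, min(1, rotation[1L, 3L])))
  psi_x <- atan2(-rotation[2L, 3L], rotation[3L, 3L])
  (w * abs(sin(psi_x)) <= tol) && (l * abs(sin(th_y)) <= tol)
}

# ---- template -------------------------------------------------------------

#' Build the normalized functional BOS template
#'
#' Each foot profile contributes the convex hull of its valid COP samples
#' (foot flat and normal force above half body weight), normalized by that
#' foot's width and length. Right-foot hulls are reflected about the y-axis
#' into left-foot space. The profiles are then averaged by sampling the
#' boundary radius of every hull along a common dense fan of rays from the
#' template center and taking the mean radius per ray; the ray-average is
#' convexified by a final hull.
#'
#' @param profiles list of per-foot profiles, each a list with `cop`
#'   (n x 2 COP in the flattened foot frame, m), `force` (n, normal force
#'   N), `flat` (logical n), `w`, `l` (m) and `side` ("left"/"right").
#' @param body_weight participant body weight (N).
#' @param center template center in left-foot normalized space; a point
#'   that must be interior to every profile hull.
#' @param n_rays number of ray angles used for the radius averaging.
#' @param min_force_frac valid-sample force threshold as a fraction of body
#'   weight (default one half).
#' @return object of class `bos_template`: list with `vertices` (CCW,
#'   normalized units) and `center`.
#' @export
build_template <- function(profiles, body_weight, center = c(-0.15, 0.3),
                           n_rays = 360L, min_force_frac = 0.5) {
  stopifnot(length(profiles) >= 1L, body_weight > 0)
  hulls <- lapply(profiles, function(p) {
    ok <- p$flat & (p$force > min_force_frac * body_weight)
    if (sum(ok) < 3L)
      stop("too few valid COP samples (flat foot with force > ",
           min_force_frac, " body weight) to build a BOS profile")
    cop <- p$cop[ok, , drop = FALSE]
    cop <- cbind(cop[, 1L] / p$w, cop[, 2L] / p$l)
    if (identical(p$side, "right")) cop[, 1L] <- -cop[, 1L]
    H <- convex_hull_ccw(cop)
    if (signed_distance(center, bos_polygon(H)) <= 0)
      stop("template center lies outside a profile hull")
    H
  })
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  R <- vapply(hulls, function(H) polygon_ray_radii(bos_polygon(H), center, angles),
              numeric(length(angles)))
  rbar <- if (is.matrix(R)) rowMeans(R) else R
  pts <- cbind(center[1L] + rbar * cos(angles), center[2L] + rbar * sin(angles))
  structure(list(vertices = convex_hull_ccw(pts), center = center),
            class = "bos_template")
}

#' Scale the BOS template to a participant's foot
#'
#' Un-normalizes the template by the foot's width and length and places it
#' in the world ground plane through the flattened foot frame. Right feet
#' use the template reflected about the y-axis.
#'
#' @param template a [build_template()] result.
#' @param w,l foot width and length (m).
#' @param frame flattened [foot_frame()] of this foot.
#' @param side "left" or "right".
#' @return a [bos_polygon()] in world ground-plane coordinates.
#' @export
scale_template <- function(template, w, l, frame, side = "left") {
  v <- template$vertices
  if (identical(side, "right")) v <- cbind(-v[, 1L], v[, 2L])
  xy <- cbind(v[, 1L] * w, v[, 2L] * l)
  o <- frame$origin[1:2]
  ex <- frame$x[1:2]; ey <- frame$y[1:2]
  world <- cbind(o[1L] + xy[, 1L] * ex[1L] + xy[, 2L] * ey[1L],
                 o[2L] + xy[, 1L] * ex[2L] + xy[, 2L] * ey[2L])
  bos_polygon(world)
}

#' Whole-body BOS from the two foot polygons
#'
#' The convex hull of the union of the left and right foot BOS polygon
#' vertices (both feet stay grounded throughout an STS).
#'
#' @param left,right [bos_polygon()] objects.
#' @return a [bos_polygon()].
#' @export
whole_body_bos <- function(left, right) {
  bos_polygon(rbind(unclass(left), unclass(right)))
}

# ---- template persistence -------------------------------------------------

#' Read / write a BOS template as JSON
#'
#' @param path file path.
#' @return `read_bos_template` returns a `bos_template`.
#' @export
read_bos_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(vertices = as.matrix(obj$vertices), center = as.numeric(obj$center)),
            class = "bos_template")
}

#' @rdname read_bos_template
#' @param template a `bos_template`.
#' @export
write_bos_template <- function(template, path) {
  jsonlite::write_json(list(vertices = unname(template$vertices),
                            center = template$center),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Packaged default BOS template
#'
#' A normalized functional BOS template shipped with the package, built
#' from the synthetic COP-excursion generator (see
#' `scripts/make_template.R` in the source repository). Labelled synthetic:
#' it stands in for a laboratory-calibrated template.
#'
#' @return a `bos_template`.
#' @export
default_bos_template <- function() {
  read_bos_template(system.file("extdata", "bos_template_synthetic.json",
                                package = "stsbalance", mustWork = TRUE))
}
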