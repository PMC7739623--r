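# Static balance: the four metrics whose smallness (relative to
# still-standing envelopes) defines a statically balanced state, plus the
# bounds machinery and the per-sample classification.

#' Static balance metric series
#'
#' Per sample: signed distance from the COM ground projection to the BOS
#' boundary (`d_bg`, positive inside), the horizontal COM-to-COP distance
#' (`com_cop_dist`), the COM speed (`com_speed`) and the average angular
#' speed (`avg_ang_speed`).
#'
#' @param wbs a [whole_body_series()].
#' @param cop n x 2 COP positions on the ground plane (m); `NA` rows give
#'   `NA` distances.
#' @param bos the whole-body [bos_polygon()].
#' @return data.frame of class `sts_static_metrics` with columns `time`,
#'   `d_bg`, `com_cop_dist`, `com_speed`, `avg_ang_speed`.
#' @export
static_metrics <- function(wbs, cop, bos) {
  G <- wbs$r_C[, 1:2, drop = FALSE]
  if (!is.matrix(cop) || nrow(cop) != wbs$n)
    stop("cop must be an n x 2 matrix aligned with the state series")
  out <- data.frame(
    time = wbs$time,
    d_bg = signed_distance(G, bos),
    com_cop_dist = sqrt(rowSums((G - cop)^2)),
    com_speed = wbs$com_speed,
    avg_ang_speed = sqrt(rowSums(wbs$omega_avg^2)))
  class(out) <- c("sts_static_metrics", "data.frame")
  out
}

#' Still-standing bounds for the balance metrics
#'
#' For each metric, takes the minimum and maximum over every subject's
#' quiet-standing window and averages those extremes across subjects.
#' Signed metrics are symmetrized using the larger of the two averaged
#' bounds, giving a region symmetric about zero.
#'
#' @param quiet_metrics list (one element per subject) of data.frames of
#'   metric series; all numeric columns except `time` are bounded.
#' @param signed_metrics names of columns treated as signed (symmetrized);
#'   by default `wz`, the vertical average angular velocity.
#' @return object of class `still_standing_bounds`: named list of
#'   `c(lower, upper)` pairs.
#' @export
still_standing_bounds <- function(quiet_metrics, signed_metrics = "wz") {
  if (length(quiet_metrics) == 0L) stop("need at least one quiet-standing trial")
  cols <- setdiff(names(quiet_metrics[[1L]]), "time")
  cols <- cols[vapply(quiet_metrics[[1L]][cols], is.numeric, logical(1))]
  bounds <- list()
  for (cl in cols) {
    lo <- mean(vapply(quiet_metrics, function(d) min(d[[cl]], na.rm = TRUE), numeric(1)))
    hi <- mean(vapply(quiet_metrics, function(d) max(d[[cl]], na.rm = TRUE), numeric(1)))
    if (cl %in% signed_metrics) {
      b <- max(abs(lo), abs(hi))
      lo <- -b; hi <- b
    }
    bounds[[cl]] <- c(lower = lo, upper = hi)
  }
  structure(bounds, class = "still_standing_bounds")
}

#' Classify samples as statically balanced
#'
#' A sample is statically balanced when the COM ground projection lies
#' inside the BOS (`d_bg >= 0`) and the COM-COP distance, COM speed and
#' average angular speed each stay within their still-standing bounds.
#'
#' @param metrics an [static_metrics()] data.frame (or any data.frame with
#'   the four metric columns).
#' @param bounds a [still_standing_bounds()] object containing entries for
#'   `com_cop_dist`, `com_speed` and `avg_ang_speed`.
#' @return logical vector, one element per row of `metrics`.
#' @export
is_statically_balanced <- function(metrics, bounds) {
  within <- function(x, b) x >= b["lower"] & x <= b["upper"]
  metrics$d_bg >= 0 &
    within(metrics$com_cop_dist, bounds$com_cop_dist) &
    within(metrics$com_speed, bounds$com_speed) &
    within(metrics$avg_ang_speed, bounds$avg_ang_speed)
}
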