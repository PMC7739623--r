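# Two-stage automatic STS segmentation: k-means++ clustering of the COM
# height and seat-plate vertical force labels candidate repetitions, which
# are then screened by sequence rules (run lengths, single force
# transition, stationary feet) and refined into initiation / seat-off /
# stance event times by adaptive thresholds.

#' Cluster a phase signal with k-means++
#'
#' k-means with k-means++ seeding and a configurable number of restarts
#' (best within-cluster sum of squares wins), deterministic for a given
#' seed. Cluster labels are assigned from the ordering of the cluster
#' means: for a COM-height signal the lowest mean is `seated`, the highest
#' `standing`, the rest `crouch`; for a seat-force signal the largest mean
#' is `seated`, the lowest `standing`, the rest `transition`.
#'
#' @param x numeric signal.
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the probabilistic seeding.
#' @param role `"height"` or `"force"`: which labelling convention to use.
#' @param nstart number of seeded restarts.
#' @return list with `labels` (character vector), `means` (named cluster
#'   means) and `cluster` (integer assignments).
#' @export
cluster_signal <- function(x, k = 3L, seed = 1L, role = c("height", "force"),
                           nstart = 10L) {
  role <- match.arg(role)
  if (length(unique(x)) < k)
    stop("signal has fewer distinct values than clusters")
  fit <- with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- .kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = matrix(centers, ncol = 1L),
                      iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  mu <- as.numeric(fit$centers)
  lab <- character(k)
  if (role == "height") {
    lab[which.min(mu)] <- "seated"
    lab[which.max(mu)] <- "standing"
    lab[lab == ""] <- "crouch"
  } else {
    lab[which.max(mu)] <- "seated"
    lab[which.min(mu)] <- "standing"
    lab[lab == ""] <- "transition"
  }
  list(labels = lab[fit$cluster], means = stats::setNames(mu, lab),
       cluster = fit$cluster)
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to the squared distance to the nearest center
.kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers[1L])^2
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j] <- x[sample.int(length(x), 1L)]
    } else {
      centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
    }
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

.label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Identify candidate STS intervals from the cluster labels
#'
#' A candidate is a standing-height run (at least `min_run_s` long)
#' connected backwards in time, through force labels, to a seated-force
#' run (also at least `min_run_s`), with exactly one transition from the
#' transition-force cluster to the standing-force cluster in between.
#' Candidates whose feet break contact (fewer than `foot_min_ok` of the 6
#' markers of either foot staying within `foot_thresh` vertical excursion
#' over the interval) are rejected. Aborted rises that return to the
#' seated-force cluster without a standing-height run are reported as
#' `sit_back` rejections.
#'
#' @param height_labels,force_labels character label vectors on the common
#'   marker clock (from [cluster_signal()]).
#' @param foot_z named list `left`/`right` of n x 6 matrices of vertical
#'   foot-marker positions (m).
#' @param fs sampling rate (Hz).
#' @param min_run_s minimum run length (s), default 0.5.
#' @param foot_thresh vertical excursion threshold (m), default 0.015.
#' @param foot_min_ok minimum number of stationary markers per foot.
#' @return list of candidate records: `start`, `end` (sample indices),
#'   `seated_run`, `standing_run`, `accepted`, `reason`.
#' @export
candidate_sequences <- function(height_labels, force_labels, foot_z, fs,
                                min_run_s = 0.5, foot_thresh = 0.015,
                                foot_min_ok = 3L) {
  n <- length(height_labels)
  stopifnot(length(force_labels) == n)
  min_run <- as.integer(round(min_run_s * fs))
  hr <- .label_runs(height_labels)
  fr <- .label_runs(force_labels)

  feet_ok <- function(i1, i2) {
    for (side in names(foot_z)) {
      exc <- apply(foot_z[[side]][i1:i2, , drop = FALSE], 2L,
                   function(z) max(z) - min(z))
      if (sum(exc < foot_thresh) < foot_min_ok) return(FALSE)
    }
    TRUE
  }

  cands <- list()
  stand_runs <- which(hr$value == "standing")
  for (si in stand_runs) {
    srun <- hr[si, ]
    rec <- list(standing_run = c(srun$start, srun$end), accepted = FALSE,
                reason = "none")
    # nearest seated-force run backwards in time from the standing run
    fi <- max(which(fr$start <= srun$start))
    seated_cands <- which(fr$value == "seated" & seq_len(nrow(fr)) <= fi)
    if (length(seated_cands) == 0L) next  # no seated period behind: not a candidate
    seated_fi <- max(seated_cands)
    # count transition-force -> standing-force switches between the seated
    # run and the end of the standing-height run
    fe <- max(which(fr$start <= srun$end))
    trans_to_stand <- 0L
    if (fe > seated_fi) {
      for (j in (seated_fi + 1L):fe) {
        if (j > 1L && fr$value[j] == "standing" && fr$value[j - 1L] == "transition")
          trans_to_stand <- trans_to_stand + 1L
      }
    }
    rec$seated_run <- c(fr$start[seated_fi], fr$end[seated_fi])
    rec$start <- fr$start[seated_fi]
    rec$end <- srun$end
    if (srun$length < min_run) {
      rec$reason <- "short_standing"
    } else if (fr$length[seated_fi] < min_run) {
      rec$reason <- "short_sitting"
    } else if (trans_to_stand != 1L) {
      rec$reason <- "multiple_transitions"
    } else if (!feet_ok(fr$end[seated_fi], srun$end)) {
      rec$reason <- "foot_moved"
    } else {
      rec$accepted <- TRUE
    }
    cands[[length(cands) + 1L]] <- rec
  }

  # sit-back attempts: seated-force -> off-seat excursion -> seated-force
  # with the COM leaving the seated-height cluster but no standing-height
  # run inside the span
  seated_fis <- which(fr$value == "seated")
  if (length(seated_fis) >= 2L) {
    for (k in seq_len(length(seated_fis) - 1L)) {
      a <- fr$end[seated_fis[k]]
      b <- fr$start[seated_fis[k + 1L]]
      if (b - a < as.integer(round(0.25 * fs))) next  # label flicker
      span <- (a + 1L):(b - 1L)
      if (!any(height_labels[span] != "seated")) next
      has_standing <- any(hr$value == "standing" &
                            hr$start <= b & hr$end >= a &
                            hr$length >= min_run)
      if (has_standing) next
      cands[[length(cands) + 1L]] <- list(
        standing_run = NULL, seated_run = c(fr$start[seated_fis[k]], a),
        start = a, end = b, accepted = FALSE, reason = "sit_back")
    }
  }
  cands
}

#' Refine candidate intervals into STS event times
#'
#' Adaptive thresholds, all relative to quantities the trial itself
#' defines: initiation is the last time before seat-off at which the COM
#' speed was within 1 cm/s of the minimum observed in the seated-force
#' run; seat-off is the first time the (raw, decimated) seat-plate
#' vertical force comes within 1 N of the value it registers during the
#' standing-height cluster; stance is the first time after seat-off at
#' which the COM is within 1 cm of the median standing-cluster height and
#' its upward speed has dropped below 1 cm/s.
#'
#' @param cand one candidate record from [candidate_sequences()].
#' @param com_speed COM speed series (m/s).
#' @param seat_fz_raw raw decimated seat-plate vertical force (N).
#' @param com_height,com_vz COM height (m) and vertical velocity (m/s).
#' @param height_labels height cluster labels.
#' @param time time vector (s).
#' @param speed_margin initiation margin above the seated minimum (m/s).
#' @param force_tol seat-off force tolerance (N).
#' @param height_tol,stance_vz stance height tolerance (m) and upward
#'   speed bound (m/s).
#' @return object of class `sts_events`: `t_init`, `t_seatoff`,
#'   `t_stance`, sample indices, `accepted`, `reason`.
#' @export
refine_events <- function(cand, com_speed, seat_fz_raw, com_height, com_vz,
                          height_labels, time, speed_margin = 0.01,
                          force_tol = 1, height_tol = 0.01, stance_vz = 0.01) {
  fail <- function(reason) {
    structure(list(t_init = NA_real_, t_seatoff = NA_real_, t_stance = NA_real_,
                   i_init = NA_integer_, i_seatoff = NA_integer_,
                   i_stance = NA_integer_, accepted = FALSE, reason = reason),
              class = "sts_events")
  }
  if (!isTRUE(cand$accepted)) return(fail(cand$reason))

  stand_idx <- which(height_labels == "standing")
  if (length(stand_idx) == 0L) return(fail("no_stance"))
  ref_force <- stats::median(seat_fz_raw[stand_idx])

  seated <- cand$seated_run[1L]:cand$seated_run[2L]
  search <- (cand$seated_run[2L] + 1L):cand$end
  i_so <- search[which(abs(seat_fz_raw[search] - ref_force) <= force_tol)[1L]]
  if (is.na(i_so)) return(fail("no_seatoff"))

  thr <- min(com_speed[seated]) + speed_margin
  pre <- cand$start:i_so
  below <- pre[com_speed[pre] <= thr]
  if (length(below) == 0L || max(below) == i_so) return(fail("no_initiation"))
  i_init <- max(below)

  h_med <- stats::median(com_height[stand_idx])
  post <- i_so:cand$end
  ok <- abs(com_height[post] - h_med) <= height_tol & com_vz[post] < stance_vz
  if (!any(ok)) return(fail("no_stance"))
  i_st <- post[which(ok)[1L]]
  if (!(i_init < i_so && i_so < i_st)) return(fail("event_order"))

  structure(list(t_init = time[i_init], t_seatoff = time[i_so],
                 t_stance = time[i_st], i_init = i_init, i_seatoff = i_so,
                 i_stance = i_st, accepted = TRUE, reason = "none"),
            class = "sts_events")
}

#' Segment a preprocessed trial into STS repetitions
#'
#' Runs the full two-stage segmentation: clusters the COM height and the
#' seat-plate vertical force into three phases each, screens candidate
#' sequences, and refines event times for the accepted ones.
#'
#' @param trial a preprocessed `sts_trial`.
#' @param wbs optional precomputed [whole_body_series()] for the trial.
#' @param seed clustering seed.
#' @param ... further arguments passed to [candidate_sequences()] and
#'   [refine_events()] thresholds via `config`.
#' @param config list of thresholds overriding the defaults (`min_run_s`,
#'   `foot_thresh`, `foot_min_ok`, `speed_margin`, `force_tol`,
#'   `height_tol`, `stance_vz`).
#' @return list of `sts_events` (accepted and rejected candidates, in
#'   temporal order of their interval starts).
#' @export
segment_sts <- function(trial, wbs = NULL, seed = 1L, config = list(), ...) {
  stopifnot(isTRUE(trial$preprocessed))
  if (is.null(wbs)) wbs <- whole_body_series(trial)
  cfg <- utils::modifyList(list(min_run_s = 0.5, foot_thresh = 0.015,
                                foot_min_ok = 3L, speed_margin = 0.01,
                                force_tol = 1, height_tol = 0.01,
                                stance_vz = 0.01), config)
  hcl <- cluster_signal(wbs$h, seed = seed, role = "height")
  fcl <- cluster_signal(trial$seat$fz, seed = seed + 1L, role = "force")
  foot_z <- list(
    left = do.call(cbind, lapply(c("LFAL", "LTAM", "LFM1", "LFM2", "LFM5", "LFCC"),
                                 function(nm) trial$markers[[nm]][, 3L])),
    right = do.call(cbind, lapply(c("RFAL", "RTAM", "RFM1", "RFM2", "RFM5", "RFCC"),
                                  function(nm) trial$markers[[nm]][, 3L])))
  cands <- candidate_sequences(hcl$labels, fcl$labels, foot_z, trial$fs_marker,
                               min_run_s = cfg$min_run_s,
                               foot_thresh = cfg$foot_thresh,
                               foot_min_ok = cfg$foot_min_ok)
  dt <- 1 / trial$fs_marker
  vz <- central_diff(wbs$h, dt)
  ev <- lapply(cands, refine_events, com_speed = wbs$com_speed,
               seat_fz_raw = trial$seat$fz_raw, com_height = wbs$h,
               com_vz = vz, height_labels = hcl$labels, time = trial$time,
               speed_margin = cfg$speed_margin, force_tol = cfg$force_tol,
               height_tol = cfg$height_tol, stance_vz = cfg$stance_vz)
  ord <- order(vapply(cands, function(cc) cc$start, numeric(1)))
  ev[ord]
}
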