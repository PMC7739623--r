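# Per-trial orchestration and cohort-level runs: preprocess, whole-body
# state, segmentation, per-subject BOS construction, metric series, and
# seat-off extraction across a cohort.

#' Per-subject whole-body BOS for a trial
#'
#' Calibrates both foot frames from the marker positions averaged over an
#' initial quiet window (feet are stationary throughout an STS recording),
#' scales the normalized template by each foot's measured width and
#' length, and hulls the two polygons.
#'
#' @param trial a preprocessed `sts_trial`.
#' @param template a `bos_template` (default: the packaged synthetic one).
#' @param calib_window seconds of data used for frame calibration.
#' @return list with `bos` (whole-body [bos_polygon()]), per-side `frames`
#'   and `dims`.
#' @export
trial_bos <- function(trial, template = default_bos_template(),
                      calib_window = 1.0) {
  idx <- which(trial$time <= trial$time[1L] + calib_window)
  polys <- list(); frames <- list(); dims <- list()
  for (side in c("left", "right")) {
    pre <- if (side == "left") "L" else "R"
    nms <- paste0(pre, c("FAL", "TAM", "FM1", "FM2", "FM5", "FCC"))
    mk <- lapply(stats::setNames(nms, sub(pre, "", nms)), function(nm)
      colMeans(trial$markers[[nm]][idx, , drop = FALSE]))
    fr <- foot_frame(mk, flatten = TRUE)
    dm <- foot_dimensions(mk, foot_frame(mk))
    polys[[side]] <- scale_template(template, dm["w"], dm["l"], fr, side)
    frames[[side]] <- fr
    dims[[side]] <- dm
  }
  list(bos = whole_body_bos(polys$left, polys$right), frames = frames,
       dims = dims, polygons = polys)
}

#' Analyze one STS trial end to end
#'
#' Preprocesses the recording, reconstructs the whole-body state series,
#' segments it into STS repetitions, builds the subject's BOS, and
#' computes the static and dynamic balance metric series. With
#' `fpe_window = "seatoff"` the FPE is solved only at the accepted
#' seat-off samples (the moment the group statistics use), which keeps
#' cohort-scale runs cheap; `"full"` solves every sample.
#'
#' @param trial an `sts_trial` (raw).
#' @param template BOS template.
#' @param seed clustering seed.
#' @param fpe_window `"seatoff"` or `"full"`.
#' @param config segmentation threshold overrides (see [segment_sts()]).
#' @return list with `trial` (preprocessed), `wbs`, `bos`, `events`
#'   (list of `sts_events`), `static`, `dynamic`.
#' @export
analyze_trial <- function(trial, template = default_bos_template(),
                          seed = 1L, fpe_window = c("seatoff", "full"),
                          config = list()) {
  fpe_window <- match.arg(fpe_window)
  pt <- preprocess(trial)
  wbs <- whole_body_series(pt)
  events <- segment_sts(pt, wbs, seed = seed, config = config)
  bosr <- trial_bos(pt, template)
  static <- static_metrics(wbs, pt$foot$cop, bosr$bos)
  samples <- if (fpe_window == "full") NULL else {
    acc <- Filter(function(e) isTRUE(e$accepted), events)
    if (length(acc) == 0L) integer(0) else
      unique(unlist(lapply(acc, function(e)
        max(1L, e$i_seatoff - 1L):min(wbs$n, e$i_seatoff + 1L))))
  }
  dynamic <- dynamic_metrics(wbs, bosr$bos, pt$foot$cop, samples = samples)
  list(trial = pt, wbs = wbs, bos = bosr$bos, events = events,
       static = static, dynamic = dynamic)
}

#' Quiet-standing metric series for bounds estimation
#'
#' Runs the balance metrics over a quiet-standing trial (static metrics
#' plus the vertical average angular velocity `wz`), the input to
#' [still_standing_bounds()].
#'
#' @param trial a quiet-standing `sts_trial`.
#' @param template BOS template.
#' @return data.frame with `time`, the four static metrics and `wz`.
#' @export
quiet_metrics <- function(trial, template = default_bos_template()) {
  pt <- preprocess(trial)
  wbs <- whole_body_series(pt)
  bosr <- trial_bos(pt, template)
  sm <- static_metrics(wbs, pt$foot$cop, bosr$bos)
  sm$wz <- wbs$omega_avg[, 3L]
  sm
}

#' Run the full pipeline over a synthetic cohort
#'
#' Generates every repetition of every subject, analyzes each trial, and
#' collects the seat-off metric rows, the per-participant aggregation and
#' the young-vs-old group comparisons.
#'
#' @param spec an [sts_cohort_spec()].
#' @param template BOS template.
#' @param fpe_window passed to [analyze_trial()].
#' @param progress print one line per subject.
#' @return list with `rows` (per-repetition seat-off values), `table`
#'   (per-participant means and ranges), `comparison_mean`,
#'   `comparison_range` (group tests), and bookkeeping in `trials`
#'   (acceptance counts and seat-off timing errors).
#' @export
run_cohort <- function(spec, template = default_bos_template(),
                       fpe_window = "seatoff", progress = FALSE) {
  rows <- list()
  book <- list()
  n_sub <- spec$n_young + spec$n_old
  for (s in seq_len(n_sub)) {
    if (progress) message("subject ", s, "/", n_sub)
    for (r in seq_len(spec$reps_per_subject)) {
      trial <- generate_sts_trial(spec, s, r)
      res <- analyze_trial(trial, template,
                           seed = derive_seed(spec$seed, 6L, s, r),
                           fpe_window = fpe_window)
      acc <- Filter(function(e) isTRUE(e$accepted), res$events)
      truth <- trial$ground_truth$events
      book[[length(book) + 1L]] <- data.frame(
        subject = s, rep = r, group = trial$meta$group,
        n_accepted = length(acc),
        seatoff_err_s = if (length(acc) == 1L)
          acc[[1L]]$t_seatoff - truth$t_seatoff else NA_real_)
      if (length(acc) >= 1L) {
        rows[[length(rows) + 1L]] <- extract_seatoff_values(
          res$static, res$dynamic, acc[[1L]],
          participant = paste0("S", s), group = trial$meta$group,
          repetition = r)
      }
    }
  }
  rows <- do.call(rbind, rows)
  tab <- seatoff_table(rows)
  list(rows = rows, table = tab,
       comparison_mean = compare_groups(tab, "unpaired", "mean"),
       comparison_range = compare_groups(tab, "unpaired", "range"),
       trials = do.call(rbind, book))
}

#' Ground-truth seat-off balance metrics of a synthetic trial
#'
#' Computes the eight balance metrics at the designed seat-off instant
#' from the generator's analytic segment states (no filtering or
#' numerical differentiation), using the same BOS template as the
#' analysis. Serves as the oracle for pipeline-recovery tests.
#'
#' @param trial a [generate_sts_trial()] recording.
#' @param template BOS template.
#' @return named numeric vector of seat-off metrics.
#' @export
trial_seatoff_truth <- function(trial, template = default_bos_template()) {
  gt <- trial$ground_truth
  segs <- gt$seatoff_segments
  st <- whole_body_state(segs)
  # BOS from the noiseless marker layout
  sub <- gt$subject
  mkL <- .foot_markers("left", 0, sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  mkR <- .foot_markers("right", 0, -sub$hip_half, sub$ankle_h, sub$foot_l, sub$foot_w)
  polys <- list()
  for (side in c("left", "right")) {
    mk <- if (side == "left") mkL else mkR
    fr <- foot_frame(mk, flatten = TRUE)
    dm <- foot_dimensions(mk, foot_frame(mk))
    polys[[side]] <- scale_template(template, dm["w"], dm["l"], fr, side)
  }
  bos <- whole_body_bos(polys$left, polys$right)
  i <- gt$i_seatoff
  cop <- gt$cop_foot_150[i, ]
  G <- st$r_C[1:2]
  fr <- travel_frame(st$H_G, v_C = st$v_C)
  inp <- project_state(st, fr)
  sol <- solve_fpe(inp, r_G = c(G, 0), s_hat = fr$s)
  pf <- c(sol$r_F[1:2] - cop, 0)
  c(d_bg = signed_distance(G, bos),
    com_cop_dist = sqrt(sum((G - cop)^2)),
    com_speed = sqrt(sum(st$v_C^2)),
    avg_ang_speed = sqrt(sum(st$omega_avg^2)),
    wz = st$omega_avg[3L],
    d_bf = signed_distance(sol$r_F[1:2], bos),
    fpe_cop_t = sum(pf * fr$t), fpe_cop_s = sum(pf * fr$s))
}

#' Export metric series as tidy CSV
#'
#' Long format (`trial`, `time`, `metric`, `value`), one row per sample
#' and metric, ready for plotting.
#'
#' @param series named list of metric data.frames (static and/or dynamic).
#' @param path output CSV path.
#' @param trial_id identifier written in the `trial` column.
#' @return the path, invisibly.
#' @export
write_metric_series_csv <- function(series, path, trial_id = "trial") {
  rows <- list()
  for (nm in names(series)) {
    d <- series[[nm]]
    for (cl in setdiff(names(d), c("time", "converged"))) {
      rows[[paste(nm, cl)]] <- data.frame(trial = trial_id, time = d$time,
                                          metric = cl, value = d[[cl]],
                                          stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
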