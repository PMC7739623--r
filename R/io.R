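# Plain-text interchange: the package's TSV dialect for trial recordings.
#
# One marker table file (`<stem>_markers.tsv`: time plus <name>_x/_y/_z
# columns, metres, 0-based sample indexing implied by the time column in
# seconds), one force file per plate (`<stem>_seat.tsv`,
# `<stem>_foot.tsv`: time, fz in newtons, cop_x/cop_y in metres, lab
# frame, z up), and a JSON sidecar (`<stem>_meta.json`) carrying sampling
# rates, the body parameter table, body mass and any ground-truth event
# times.

#' Write a trial recording in the TSV dialect
#'
#' @param trial an `sts_trial`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return the stem path, invisibly.
#' @export
write_trial_tsv <- function(trial, dir, stem = "trial") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtab <- data.frame(time = trial$time)
  for (nm in names(trial$markers)) {
    m <- trial$markers[[nm]]
    mtab[[paste0(nm, "_x")]] <- m[, 1L]
    mtab[[paste0(nm, "_y")]] <- m[, 2L]
    mtab[[paste0(nm, "_z")]] <- m[, 3L]
  }
  utils::write.table(mtab, file.path(dir, paste0(stem, "_markers.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (pl in c("seat", "foot")) {
    p <- trial[[pl]]
    ptab <- data.frame(time = p$time, fz = p$fz,
                       cop_x = p$cop[, 1L], cop_y = p$cop[, 2L])
    utils::write.table(ptab, file.path(dir, paste0(stem, "_", pl, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  side <- list(fs_marker = trial$fs_marker, fs_force = trial$fs_force,
               body_mass = trial$body_mass,
               body_params = trial$body_params, meta = trial$meta)
  if (!is.null(trial$ground_truth$events))
    side$ground_truth_events <- trial$ground_truth$events
  jsonlite::write_json(side, file.path(dir, paste0(stem, "_meta.json")),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(file.path(dir, stem))
}

#' Read a trial recording from the TSV dialect
#'
#' @param dir directory containing the files.
#' @param stem file-name stem used at write time.
#' @return an `sts_trial` (without analytic ground-truth series; designed
#'   event times are restored when present in the sidecar).
#' @export
read_trial_tsv <- function(dir, stem = "trial") {
  mtab <- utils::read.table(file.path(dir, paste0(stem, "_markers.tsv")),
                            sep = "\t", header = TRUE)
  nms <- unique(sub("_(x|y|z)$", "", setdiff(names(mtab), "time")))
  markers <- lapply(stats::setNames(nms, nms), function(nm)
    unname(as.matrix(mtab[paste0(nm, c("_x", "_y", "_z"))])))
  plates <- lapply(c(seat = "seat", foot = "foot"), function(pl) {
    p <- utils::read.table(file.path(dir, paste0(stem, "_", pl, ".tsv")),
                           sep = "\t", header = TRUE)
    list(time = p$time, fz = p$fz, cop = unname(cbind(p$cop_x, p$cop_y)))
  })
  side <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  gt <- if (!is.null(side$ground_truth_events))
    list(events = side$ground_truth_events) else NULL
  .new_trial(mtab$time, side$fs_marker, side$fs_force, markers,
             plates$seat, plates$foot,
             as.data.frame(side$body_params), side$body_mass, gt,
             as.list(side$meta))
}
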