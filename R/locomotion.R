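#' Worm-track locomotion metrics
#'
#' Centroid tracks at 8 frames/s over 5 minute assays. Tracks are filtered
#' (animals leaving the field of view in the first 3 minutes, or slower than
#' 100 um/s on average, are excluded), reversals are maximal backward runs
#' longer than 4 frames (> 500 ms), and the reported metrics are total path
#' distance, mean speed excluding pauses, forward run distance/duration
#' between reversals, reversals per minute, and per-bout reverse
#' distance/duration.
#'
#' @name locomotion
NULL

.track_steps <- function(track) {
  n <- nrow(track)
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  dt <- diff(track$t_s)
  data.frame(dist_um = sqrt(dx^2 + dy^2),
             speed_um_s = sqrt(dx^2 + dy^2) / dt,
             direction = track$direction[-n],
             t_s = track$t_s[-n])
}

# a frame counts as paused if labelled so by the tracker, or (fallback when
# no labels exist) if its speed is below the pause threshold
.is_pause <- function(steps, pause_speed = 20) {
  if (!is.null(steps$direction) && !all(is.na(steps$direction)))
    steps$direction == "pause"
  else steps$speed_um_s < pause_speed
}

#' Filter a cohort of tracks
#'
#' Excludes tracks that leave the field of view before 180 s (when bounds are
#' given) and tracks whose assay-mean speed excluding pauses is below
#' `min_speed`. Exclusion counts are attached as attribute `exclusions`.
#'
#' @param tracks list of track data frames (`worm_id`, `t_s`, `x_um`,
#'   `y_um`, optional `direction`).
#' @param fov optional field-of-view bounds `c(xmin, xmax, ymin, ymax)` um.
#' @param min_speed um/s, default 100.
#' @param fov_grace_s leave-FOV grace period, default 180 (first 3 min).
#' @param pause_speed um/s threshold used when no direction labels exist.
#' @return the retained list of tracks, with attribute `exclusions`
#'   (list: `fov`, `slow`).
#' @export
filter_tracks <- function(tracks, fov = NULL, min_speed = 100,
                          fov_grace_s = 180, pause_speed = 20) {
  left_fov <- vapply(tracks, function(tr) {
    if (is.null(fov)) return(FALSE)
    out <- tr$x_um < fov[1] | tr$x_um > fov[2] |
      tr$y_um < fov[3] | tr$y_um > fov[4]
    any(out & tr$t_s < fov_grace_s)
  }, logical(1))
  slow <- vapply(tracks, function(tr) {
    st <- .track_steps(tr)
    moving <- !.is_pause(st, pause_speed)
    if (!any(moving)) return(TRUE)
    mean(st$speed_um_s[moving]) < min_speed
  }, logical(1))
  keep <- !left_fov & !slow
  structure(tracks[keep],
            exclusions = list(fov = sum(left_fov), slow = sum(slow & !left_fov)))
}

#' Detect reversal bouts
#'
#' Maximal runs of backward locomotion; a run qualifies as a reversal iff it
#' lasts strictly more than 4 frames (i.e. at least 5 frames, > 500 ms at
#' 8 frames/s).
#'
#' @param track a track data frame with a per-frame `direction` column
#'   (forward / reverse / pause) from the tracker or generator.
#' @param min_frames strict lower bound in frames, default 4.
#' @return data frame of reversal bouts: `start_frame`, `end_frame`,
#'   `n_frames`.
#' @export
detect_reversals <- function(track, min_frames = 4) {
  if (is.null(track$direction))
    stop("reversal detection needs per-frame directions; supply the ",
         "tracker's direction column", call. = FALSE)
  r <- rle(track$direction == "reverse")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths > min_frames
  data.frame(start_frame = starts[sel], end_frame = ends[sel],
             n_frames = r$lengths[sel])
}

#' Locomotion metrics for one track
#'
#' @param track a track data frame.
#' @param bouts reversal bouts from [detect_reversals()]; computed when
#'   missing.
#' @param pause_speed um/s threshold used when no direction labels exist.
#' @return one-row data frame: `worm_id`, `duration_s`, `distance_mm` (total
#'   path), `speed_um_s` (mean over non-pause frames), `reversals_per_min`,
#'   `forward_run_dist_mm` and `forward_run_dur_s` (mean forward-run distance
#'   and duration between consecutive reversals), `reverse_dist_um` and
#'   `reverse_dur_s` (means per reversal bout; `NA` with no reversals).
#' @export
track_metrics <- function(track, bouts = NULL, pause_speed = 20) {
  st <- .track_steps(track)
  if (is.null(bouts)) bouts <- detect_reversals(track)
  dur <- max(track$t_s) - min(track$t_s)
  paused <- .is_pause(st, pause_speed)
  # step i joins frames i and i+1; a bout over frames s..e owns steps s..e-1
  in_rev <- rep(FALSE, nrow(st))
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start_frame[b]:min(bouts$end_frame[b] - 1L, nrow(st))
    in_rev[idx] <- TRUE
  }
  # forward runs = segments between consecutive reversals
  run_id <- cumsum(c(FALSE, diff(in_rev) != 0))
  fwd <- !in_rev & !paused
  runs <- split(seq_len(nrow(st))[fwd], run_id[fwd])
  run_dist <- vapply(runs, function(i) sum(st$dist_um[i]), numeric(1))
  run_dur <- vapply(runs, length, numeric(1)) * stats::median(diff(track$t_s))
  rev_dist <- if (nrow(bouts)) vapply(seq_len(nrow(bouts)), function(b) {
    idx <- bouts$start_frame[b]:min(bouts$end_frame[b] - 1L, nrow(st))
    sum(st$dist_um[idx])
  }, numeric(1)) else numeric()
  data.frame(
    worm_id = track$worm_id[1],
    duration_s = dur,
    distance_mm = sum(st$dist_um) / 1000,
    speed_um_s = if (any(!paused)) mean(st$speed_um_s[!paused]) else NA_real_,
    reversals_per_min = nrow(bouts) / (dur / 60),
    forward_run_dist_mm = if (length(run_dist)) mean(run_dist) / 1000 else NA_real_,
    forward_run_dur_s = if (length(run_dur)) mean(run_dur) else NA_real_,
    reverse_dist_um = if (length(rev_dist)) mean(rev_dist) else NA_real_,
    reverse_dur_s = if (nrow(bouts))
      mean(bouts$n_frames) * stats::median(diff(track$t_s)) else NA_real_)
}

#' Cohort summary of locomotion metrics
#'
#' @param tracks list of (filtered) tracks.
#' @param pause_speed um/s threshold used when no direction labels exist.
#' @return data frame with one row per worm (see [track_metrics()]).
#' @export
cohort_metrics <- function(tracks, pause_speed = 20) {
  do.call(rbind, lapply(tracks, track_metrics, pause_speed = pause_speed))
}
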