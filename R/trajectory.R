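#' Frame and trajectory containers
#'
#' A frame holds time (ps), an N x 3 position matrix (nm), optional
#' velocities (nm/ps) and a [simulation_box()].  A trajectory is an ordered
#' list of frames with strictly increasing times and constant atom count.
#'
#' @param time time stamp in ps
#' @param positions N x 3 numeric matrix, nm
#' @param box a `simulation_box` (or `NULL` when the source format carries
#'   no box; most operations then require one to be supplied)
#' @param velocities optional N x 3 matrix, nm/ps
#' @return `md_frame` / `md_trajectory` objects.
#' @export
md_frame <- function(positions, box = NULL, time = 0, velocities = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(all(dim(velocities) == dim(positions)))
  }
  structure(list(time = time, positions = unname(positions),
                 velocities = velocities, box = box),
            class = "md_frame")
}

#' @rdname md_frame
#' @param frames list of `md_frame`
#' @export
md_trajectory <- function(frames) {
  if (!length(frames)) stop("trajectory must contain at least one frame")
  n <- nrow(frames[[1]]$positions)
  times <- vapply(frames, `[[`, numeric(1), "time")
  for (f in frames)
    if (nrow(f$positions) != n) stop("inconsistent atom count across frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  interval <- if (length(times) > 1) times[2] - times[1] else NA_real_
  structure(list(frames = frames, frame_interval = interval),
            class = "md_trajectory")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> t=%.3f ps, %d atoms%s%s\n", x$time,
              nrow(x$positions),
              if (is.null(x$velocities)) "" else ", with velocities",
              if (is.null(x$box)) ", no box" else ""))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  tt <- trajectory_times(x)
  cat(sprintf("<md_trajectory> %d frames, %d atoms, t = %.3f..%.3f ps\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              tt[1], tt[length(tt)]))
  invisible(x)
}

#' @rdname md_frame
#' @param traj an `md_trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname md_frame
#' @export
trajectory_times <- function(traj)
  vapply(traj$frames, `[[`, numeric(1), "time")

#' Subset a trajectory to a time window
#' @param traj an `md_trajectory`
#' @param t_start,t_end window bounds in ps (inclusive)
#' @export
trajectory_window <- function(traj, t_start = -Inf, t_end = Inf) {
  tt <- trajectory_times(traj)
  keep <- tt >= t_start & tt <= t_end
  if (!any(keep)) stop("empty analysis window [", t_start, ", ", t_end, "] ps")
  md_trajectory(traj$frames[keep])
}
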