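#' Construct a trajectory frame
#'
#' @param time Simulation time (ns).
#' @param box Orthorhombic box edge lengths (nm), length 3.
#' @param positions n x 3 matrix of bead positions (nm), row order aligned
#'   with the bead topology (`bead_id` 0 is row 1).
#' @return A `cg_frame` object.
#' @export
cg_frame <- function(time, box, positions) {
  check_box(box)
  positions <- to_xyz(positions)
  dimnames(positions) <- NULL
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time))
    abort("time must be a finite scalar (ns)")
  structure(list(time = as.numeric(time), box = as.numeric(box),
                 positions = positions),
            class = "cg_frame")
}

#' Construct a trajectory from frames
#'
#' Validates that frame times are strictly increasing with constant spacing
#' (tolerance 1e-6 ns) and that all frames carry the same bead count.
#'
#' @param frames A list of [cg_frame()] objects.
#' @return A `cg_trajectory` object (list of frames).
#' @export
cg_trajectory <- function(frames) {
  if (!length(frames)) abort("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "cg_frame")))
    abort("all elements must be cg_frame objects")
  n <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(n)) != 1L)
    abort("all frames must have the same bead count")
  tt <- frame_times_of(frames)
  if (length(tt) > 1L) {
    dt <- diff(tt)
    if (any(dt <= 0))
      abort("frame times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      abort("frame spacing must be constant (tolerance 1e-6 ns)")
  }
  structure(frames, class = "cg_trajectory")
}

frame_times_of <- function(traj) {
  vapply(traj, function(f) f$time, numeric(1))
}

#' Frame times of a trajectory
#' @param traj A `cg_trajectory`.
#' @return Numeric vector of times (ns).
#' @export
frame_times <- function(traj) frame_times_of(traj)

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame> t = %g ns, %d beads, box %.2f x %.2f x %.2f nm\n",
              x$time, nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  tt <- frame_times_of(x)
  cat(sprintf("<cg_trajectory> %d frames, t = %g..%g ns, %d beads\n",
              length(x), min(tt), max(tt), nrow(x[[1]]$positions)))
  invisible(x)
}

#' Subset a trajectory to an analysis time window
#'
#' Keeps frames with `t_start <= time <= t_end`. Both endpoints must align
#' with frame times actually present (tolerance 1e-6 ns), mirroring how
#' analysis windows are defined on saved frames.
#'
#' @param traj A `cg_trajectory`.
#' @param t_start,t_end Window bounds (ns), `t_start < t_end`.
#' @return A `cg_trajectory` restricted to the window.
#' @export
trajectory_window <- function(traj, t_start, t_end) {
  if (t_start >= t_end) abort("t_start must be < t_end")
  tt <- frame_times_of(traj)
  if (min(abs(tt - t_start)) > 1e-6 || min(abs(tt - t_end)) > 1e-6)
    abort("window bounds must align with frame times present in the trajectory",
          class = "cgagg_window_error")
  keep <- tt >= t_start - 1e-6 & tt <= t_end + 1e-6
  structure(traj[keep], class = "cg_trajectory")
}
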