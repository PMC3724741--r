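#' Unwrap molecule center-of-mass tracks from a wrapped trajectory
#'
#' Computes a lateral (xy) center-of-mass track per selected molecule and
#' removes periodic jumps by accumulating minimum-image inter-frame
#' displacements. Within a frame, the center of mass is taken relative to
#' the molecule's first bead (minimum-image offsets), so molecules
#' straddling the box boundary are handled correctly.
#'
#' The method assumes each molecule moves less than half a box edge
#' between consecutive frames; frames saved too sparsely for that cannot
#' be unwrapped unambiguously.
#'
#' @param traj A `cg_trajectory`.
#' @param topo A `bead_topology`.
#' @param selection Molecule type to track (default `"PROTEIN"`).
#' @return A `com_tracks` tibble with columns `molecule_id`, `time_ns`,
#'   `x`, `y` (unwrapped, nm).
#' @export
unwrap_trajectory <- function(traj, topo, selection = "PROTEIN") {
  sel <- topo$molecule_type == selection
  if (!any(sel)) abort(paste0("no molecules of type ", selection))
  mols <- sort(unique(topo$molecule_id[sel]))
  bead_rows <- lapply(mols, function(m) which(sel & topo$molecule_id == m))
  n_f <- length(traj)
  tt <- frame_times_of(traj)

  com_frame <- function(f) {
    t(vapply(bead_rows, function(rows) {
      p <- f$positions[rows, , drop = FALSE]
      if (nrow(p) == 1L) return(p[1, 1:2])
      ref <- p[1, ]
      offs <- wrap_half_open(sweep(p, 2L, ref), f$box)
      (ref + colMeans(offs))[1:2]
    }, numeric(2)))
  }

  x <- matrix(NA_real_, n_f, length(mols))
  y <- matrix(NA_real_, n_f, length(mols))
  prev <- com_frame(traj[[1]])
  x[1, ] <- prev[, 1]; y[1, ] <- prev[, 2]
  for (k in seq_len(n_f - 1L)) {
    cur <- com_frame(traj[[k + 1L]])
    box <- traj[[k + 1L]]$box
    d <- wrap_half_open(cbind(cur[, 1] - prev[, 1], cur[, 2] - prev[, 2], 0),
                        box)
    big <- abs(d[, 1]) >= box[1] / 2 | abs(d[, 2]) >= box[2] / 2
    if (any(big))
      abort(sprintf(
        "undersampled trajectory: molecule %d moved >= half a box edge between frames %d and %d",
        mols[which(big)[1]], k, k + 1L), class = "cgagg_undersampling_error")
    x[k + 1L, ] <- x[k, ] + d[, 1]
    y[k + 1L, ] <- y[k, ] + d[, 2]
    prev <- cur
  }
  out <- tibble::tibble(
    molecule_id = rep(mols, each = n_f),
    time_ns = rep(tt, length(mols)),
    x = as.vector(x), y = as.vector(y))
  class(out) <- c("com_tracks", class(out))
  out
}

# tracks tibble -> list(times, X, Y) with frames x molecules matrices
tracks_matrices <- function(tracks) {
  mols <- sort(unique(tracks$molecule_id))
  tt <- sort(unique(tracks$time_ns))
  X <- matrix(NA_real_, length(tt), length(mols))
  Y <- matrix(NA_real_, length(tt), length(mols))
  fi <- match(tracks$time_ns, tt)
  mi <- match(tracks$molecule_id, mols)
  X[cbind(fi, mi)] <- tracks$x
  Y[cbind(fi, mi)] <- tracks$y
  list(times = tt, X = X, Y = Y, mols = mols)
}

#' Time-origin-averaged mean-square displacement
#'
#' `MSD(t) = <|r_i(tau0 + t) - r_i(tau0)|^2>` averaged over every
#' molecule `i` and every valid origin `tau0` in the window; lateral (xy)
#' components only (`d = 2`).
#'
#' @param tracks A `com_tracks` tibble (from [unwrap_trajectory()] or the
#'   generator's ground-truth record).
#' @param window Optional length-2 time window (ns) restricting origins
#'   and endpoints.
#' @param max_lag Largest lag time (ns); must be smaller than the window
#'   length. Default: half the window.
#' @return An `msd_profile` tibble with `lag_ns`, `msd_nm2`, `n_origins`
#'   (origin-molecule pairs averaged per lag). Lag 0 is included.
#' @export
msd_profile <- function(tracks, window = NULL, max_lag = NULL) {
  tm <- tracks_matrices(tracks)
  if (!is.null(window)) {
    keep <- tm$times >= window[1] - 1e-6 & tm$times <= window[2] + 1e-6
    if (sum(keep) < 2L) abort("window must contain at least 2 frames")
    tm$times <- tm$times[keep]
    tm$X <- tm$X[keep, , drop = FALSE]
    tm$Y <- tm$Y[keep, , drop = FALSE]
  }
  n_f <- length(tm$times)
  if (n_f < 2L) abort("need at least 2 frames")
  dt <- tm$times[2] - tm$times[1]
  span <- tm$times[n_f] - tm$times[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span + 1e-9)
    abort("max_lag must be smaller than the window length")
  k_max <- min(n_f - 1L, floor(max_lag / dt + 1e-9))
  msd <- numeric(k_max + 1L)
  n_or <- integer(k_max + 1L)
  n_mol <- ncol(tm$X)
  n_or[1] <- n_f * n_mol
  for (k in seq_len(k_max)) {
    dx <- tm$X[(1L + k):n_f, , drop = FALSE] - tm$X[1L:(n_f - k), , drop = FALSE]
    dy <- tm$Y[(1L + k):n_f, , drop = FALSE] - tm$Y[1L:(n_f - k), , drop = FALSE]
    msd[k + 1L] <- mean(dx^2 + dy^2)
    n_or[k + 1L] <- (n_f - k) * n_mol
  }
  out <- tibble::tibble(lag_ns = (0:k_max) * dt, msd_nm2 = msd,
                        n_origins = n_or)
  class(out) <- c("msd_profile", class(out))
  attr(out, "tracks") <- tm
  attr(out, "d") <- 2L
  out
}

#' @rdname msd_profile
#' @param object An `msd_profile`.
#' @param ... Ignored.
#' @export
autoplot.msd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ns, y = .data$msd_nm2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag time (ns)", y = expression(MSD ~ (nm^2))) +
    ggplot2::theme_minimal()
}

ols_slope <- function(lag, msd) {
  fit <- lm(msd ~ lag)
  unname(coef(fit)[2])
}

#' Fit a lateral diffusion coefficient from an MSD profile
#'
#' Ordinary least-squares slope `s` of the MSD curve over the fit window;
#' `D = s / (2 d)` with `d = 2` for lateral diffusion, reported in units
#' of 1e-8 cm^2/s (1e-8 cm^2/s = 1e-3 nm^2/ns). The default fit window,
#' lag in `[10%, 50%]` of the largest lag, avoids both the short-lag
#' ballistic/noise regime and the poorly averaged tail.
#'
#' The uncertainty comes from block averaging over molecules: molecules
#' are split into `n_blocks` groups, the MSD is rebuilt and refit per
#' block, and the standard deviation of the block estimates is reported.
#'
#' @param profile An `msd_profile`.
#' @param fit_window Optional length-2 lag window (ns).
#' @param d Dimensionality (2 for lateral diffusion).
#' @param n_blocks Number of molecule blocks for the error estimate.
#' @return A `diffusion_estimate`: list with `D` (1e-8 cm^2/s), `stderr`,
#'   `slope` (nm^2/ns), `intercept`, `fit_window`, `d`, `n_lags`,
#'   `n_molecules`, `block_Ds`.
#' @export
fit_diffusion <- function(profile, fit_window = NULL, d = 2L,
                          n_blocks = 5L) {
  stopifnot(inherits(profile, "msd_profile"))
  max_lag <- max(profile$lag_ns)
  if (is.null(fit_window)) {
    fit_window <- c(0.1, 0.5) * max_lag
    if (sum(profile$lag_ns >= fit_window[1] &
              profile$lag_ns <= fit_window[2]) < 3L)
      fit_window <- c(0, max_lag)   # short profiles: fall back to all lags
  }
  if (fit_window[1] < 0 || fit_window[2] > max_lag + 1e-9 ||
      fit_window[1] >= fit_window[2])
    abort("fit_window must lie within the profile's lag range")
  in_win <- profile$lag_ns >= fit_window[1] - 1e-9 &
    profile$lag_ns <= fit_window[2] + 1e-9
  if (sum(in_win) < 3L)
    abort("need at least 3 lag points in the fit window")
  fit <- lm(msd_nm2 ~ lag_ns, data = profile[in_win, ])
  slope <- unname(coef(fit)[2])
  D_nm <- slope / (2 * d)
  D <- D_nm / D_UNIT_NM2_NS

  tm <- attr(profile, "tracks")
  block_Ds <- NULL
  if (!is.null(tm) && ncol(tm$X) >= 2L) {
    n_mol <- ncol(tm$X)
    nb <- min(n_blocks, n_mol)
    grp <- cut(seq_len(n_mol), breaks = nb, labels = FALSE)
    block_Ds <- vapply(seq_len(nb), function(b) {
      ix <- grp == b
      sub <- tibble::tibble(
        molecule_id = rep(tm$mols[ix], each = length(tm$times)),
        time_ns = rep(tm$times, sum(ix)),
        x = as.vector(tm$X[, ix, drop = FALSE]),
        y = as.vector(tm$Y[, ix, drop = FALSE]))
      p <- msd_profile(sub, max_lag = max_lag)
      iw <- p$lag_ns >= fit_window[1] - 1e-9 & p$lag_ns <= fit_window[2] + 1e-9
      ols_slope(p$lag_ns[iw], p$msd_nm2[iw]) / (2 * d) / D_UNIT_NM2_NS
    }, numeric(1))
  }
  se <- if (!is.null(block_Ds) && length(block_Ds) >= 2L) sd(block_Ds)
        else NA_real_
  structure(list(D = D, stderr = se, slope = slope,
                 intercept = unname(coef(fit)[1]), fit_window = fit_window,
                 d = d, n_lags = sum(in_win),
                 n_molecules = if (is.null(tm)) NA_integer_ else ncol(tm$X),
                 block_Ds = block_Ds),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "<diffusion_estimate> D = %.4g x 1e-8 cm^2/s (block stderr %.2g), fit lags %.3g-%.3g ns\n",
    x$D, x$stderr, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Tidy a diffusion estimate
#'
#' @param x A `diffusion_estimate`.
#' @param ... Ignored.
#' @return One-row tibble with `term`, `estimate`, `std.error`, `unit`.
#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble::tibble(term = c("D", "slope", "intercept"),
                 estimate = c(x$D, x$slope, x$intercept),
                 std.error = c(x$stderr, NA_real_, NA_real_),
                 unit = c("1e-8 cm^2/s", "nm^2/ns", "nm^2"))
}

#' @rdname tidy.diffusion_estimate
#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble::tibble(D = x$D, stderr = x$stderr,
                 fit_lag_min_ns = x$fit_window[1],
                 fit_lag_max_ns = x$fit_window[2], d = x$d,
                 n_lags = x$n_lags, n_molecules = x$n_molecules)
}

#' Convenience: tracks from a sticky-simulation ground-truth record
#'
#' @param truth The `truth` element returned by
#'   [simulate_sticky_brownian()].
#' @return A `com_tracks` tibble of the unwrapped center positions.
#' @export
truth_tracks <- function(truth) {
  cu <- truth$centers_unwrapped
  n_f <- dim(cu)[1]; n <- dim(cu)[2]
  out <- tibble::tibble(
    molecule_id = rep(seq_len(n), each = n_f),
    time_ns = rep(truth$times, n),
    x = as.vector(cu[, , 1]),
    y = as.vector(cu[, , 2]))
  class(out) <- c("com_tracks", class(out))
  out
}
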