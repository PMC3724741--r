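#' Per-bead solvent-accessible surface area (Shrake-Rupley)
#'
#' Distributes `n_sphere_points` quasi-uniform points (deterministic
#' Fibonacci spiral, no RNG) on each bead's expanded sphere of radius
#' `bead_radius + probe`; a point is accessible when it lies outside
#' every occluding neighbor's expanded sphere. The area is the accessible
#' fraction times `4*pi*(r+probe)^2`. Neighbor distances use the
#' minimum-image convention, so periodic images occlude correctly.
#'
#' The default probe of 0.56 nm is the coarse-grained convention: about
#' four times the atomistic 0.14 nm water probe, matching the larger
#' radius of beads that map four heavy atoms.
#'
#' @param frame A `cg_frame`.
#' @param topo A `bead_topology` (per-bead radii are taken from it).
#' @param probe Probe radius (nm), default 0.56.
#' @param n_sphere_points Test points per sphere (>= 64), default 960.
#' @param compute_types Molecule types whose beads get an area (default
#'   `"PROTEIN"`).
#' @param occluder_types Molecule types that block solvent. Defaults to
#'   every type except `OTHER` (solvent/ion stand-ins do not occlude;
#'   lipid beads do, since a membrane-facing residue is genuinely
#'   inaccessible).
#' @return Numeric vector, one area (nm^2) per topology bead; beads
#'   outside `compute_types` get `NA`.
#' @export
bead_sasa <- function(frame, topo, probe = 0.56, n_sphere_points = 960L,
                      compute_types = "PROTEIN",
                      occluder_types = c("PROTEIN", "DPPC", "DLIPC", "CHOL")) {
  if (any(!is.finite(topo$bead_radius)) || any(topo$bead_radius <= 0))
    abort("every bead needs a positive radius for SASA")
  compute <- topo$molecule_type %in% compute_types
  if (!any(compute)) abort("no beads selected for SASA computation")
  occl <- topo$molecule_type %in% occluder_types
  a <- sasa_cpp(frame$positions, topo$bead_radius, frame$box, probe,
                as.integer(n_sphere_points), compute, occl, TRUE)
  a[!compute] <- NA_real_
  a
}

#' Window-averaged per-residue SASA profile
#'
#' Per-frame bead areas are summed within each residue (so residue areas
#' conserve the per-bead total) and averaged over the frames of the
#' window sampled every `spacing` ns, then averaged over protein copies.
#'
#' @param traj A `cg_trajectory`.
#' @param topo A `bead_topology`.
#' @param window Optional length-2 time window (ns).
#' @param probe Probe radius (nm), default 0.56.
#' @param spacing Sampling interval (ns); must be a multiple of the frame
#'   interval. Default: every frame.
#' @param n_sphere_points Test points per sphere.
#' @inheritParams bead_sasa
#' @return A `sasa_profile` tibble with `residue_index`, `sasa_nm2`
#'   (mean over proteins and frames) and attributes `probe`, `n_frames`,
#'   `spacing`, `per_molecule` (residues x molecules matrix).
#' @export
residue_sasa_window <- function(traj, topo, window = NULL, probe = 0.56,
                                spacing = NULL, n_sphere_points = 960L,
                                compute_types = "PROTEIN",
                                occluder_types = c("PROTEIN", "DPPC",
                                                   "DLIPC", "CHOL")) {
  if (!is.null(window)) traj <- trajectory_window(traj, window[1], window[2])
  tt <- frame_times_of(traj)
  if (length(tt) > 1L) {
    dt <- tt[2] - tt[1]
    if (is.null(spacing)) spacing <- dt
    ratio <- spacing / dt
    if (abs(ratio - round(ratio)) > 1e-6 || round(ratio) < 1)
      abort("spacing must be a positive multiple of the frame interval",
            class = "cgagg_window_error")
    keep <- seq(1L, length(tt), by = as.integer(round(ratio)))
    traj <- structure(traj[keep], class = "cg_trajectory")
  } else if (is.null(spacing)) spacing <- NA_real_

  sel <- topo$molecule_type == "PROTEIN"
  mols <- sort(unique(topo$molecule_id[sel]))
  resv <- sort(unique(topo$residue_index[sel]))
  acc <- matrix(0, length(resv), length(mols),
                dimnames = list(resv, mols))
  for (f in traj) {
    a <- bead_sasa(f, topo, probe, n_sphere_points, compute_types,
                   occluder_types)
    sums <- tapply(a[sel], list(factor(topo$residue_index[sel], levels = resv),
                                factor(topo$molecule_id[sel], levels = mols)),
                   sum)
    sums[is.na(sums)] <- 0
    acc <- acc + sums
  }
  per_mol <- acc / length(traj)
  out <- tibble::tibble(residue_index = resv,
                        sasa_nm2 = unname(rowMeans(per_mol)))
  class(out) <- c("sasa_profile", class(out))
  attr(out, "probe") <- probe
  attr(out, "n_frames") <- length(traj)
  attr(out, "spacing") <- spacing
  attr(out, "per_molecule") <- per_mol
  out
}

#' Change in per-residue SASA between two windows
#'
#' `delta = late - early` per residue: residues buried at newly formed
#' protein-protein interfaces show large negative deltas. Both the signed
#' value and the burial magnitude `max(-delta, 0)` are reported, so the
#' burial threshold can be applied to the magnitude regardless of sign
#' convention.
#'
#' @param early,late `sasa_profile` objects over the same residues with
#'   the same probe.
#' @return A `delta_sasa` tibble: `residue_index`, `sasa_early`,
#'   `sasa_late`, `delta_nm2`, `burial_nm2`.
#' @export
delta_sasa <- function(early, late) {
  stopifnot(inherits(early, "sasa_profile"), inherits(late, "sasa_profile"))
  if (!isTRUE(all.equal(attr(early, "probe"), attr(late, "probe"))))
    abort("probe mismatch between windows; profiles are not comparable",
          class = "cgagg_sasa_error")
  if (!identical(early$residue_index, late$residue_index))
    abort("residue sets differ between windows", class = "cgagg_sasa_error")
  out <- tibble::tibble(residue_index = early$residue_index,
                        sasa_early = early$sasa_nm2,
                        sasa_late = late$sasa_nm2,
                        delta_nm2 = late$sasa_nm2 - early$sasa_nm2)
  out$burial_nm2 <- pmax(-out$delta_nm2, 0)
  class(out) <- c("delta_sasa", class(out))
  attr(out, "probe") <- attr(early, "probe")
  out
}

#' Residues buried beyond a threshold
#'
#' Filters residues whose burial magnitude (`max(-delta, 0)`) exceeds
#' `threshold`, sorted by magnitude descending. The conventional burial
#' threshold on these coarse-grained areas is 0.75 nm^2.
#'
#' @param delta A `delta_sasa`.
#' @param threshold Burial threshold (nm^2), default 0.75; strict
#'   inequality.
#' @return The filtered, sorted `delta_sasa` rows as a tibble.
#' @export
buried_residues <- function(delta, threshold = 0.75) {
  stopifnot(inherits(delta, "delta_sasa"))
  out <- delta[delta$burial_nm2 > threshold, ]
  tibble::as_tibble(out[order(-out$burial_nm2), ])
}

#' @rdname delta_sasa
#' @param object A `delta_sasa`.
#' @param ... Ignored.
#' @export
autoplot.delta_sasa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_index,
                                       y = .data$delta_nm2)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "residue", y = expression(Delta * SASA ~ (nm^2))) +
    ggplot2::theme_minimal()
}
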