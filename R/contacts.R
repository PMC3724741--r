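#' Accumulate residue-pair inter-protein contact counts
#'
#' For every frame and every unordered pair of protein molecules, the
#' count `C[i, j]` is incremented when the backbone bead of residue `i`
#' in one molecule and the backbone bead of residue `j` in the other lie
#' within `cutoff`. A single physical contact is stored symmetrically in
#' both `C[i, j]` and `C[j, i]`. All proteins must share the same residue
#' count `N_r` (the map is undefined otherwise).
#'
#' @param traj A `cg_trajectory` (restrict with [trajectory_window()]
#'   first to accumulate over an analysis window).
#' @param topo A `bead_topology`.
#' @param cutoff Backbone-bead contact cutoff (nm), default 0.75.
#' @return A `contact_accumulator`: list with `C` (`N_r x N_r` symmetric
#'   integer-valued matrix), `F` (frames), `M` (protein count), `N_r`, and
#'   `cutoff`.
#' @export
accumulate_residue_contacts <- function(traj, topo, cutoff = 0.75) {
  nr <- protein_residue_counts(topo)
  if (!length(nr)) abort("topology contains no proteins")
  if (length(unique(nr)) != 1L)
    abort("heterogeneous residue counts across proteins; contact map undefined",
          class = "cgagg_contact_error")
  n_r <- as.integer(nr[1])
  m <- length(nr)
  sel <- topo$molecule_type == "PROTEIN" & topo$bead_role == "BACKBONE"
  mol <- topo$molecule_id[sel]
  res <- topo$residue_index[sel]

  C <- matrix(0, n_r, n_r)
  for (f in traj) {
    pr <- neighbor_pairs(f$positions[sel, , drop = FALSE], f$box, cutoff)
    keep <- mol[pr$i] != mol[pr$j]
    if (!any(keep)) next
    ri <- res[pr$i[keep]]; rj <- res[pr$j[keep]]
    ma <- pmin(mol[pr$i[keep]], mol[pr$j[keep]])
    mb <- pmax(mol[pr$i[keep]], mol[pr$j[keep]])
    rmin <- pmin(ri, rj); rmax <- pmax(ri, rj)
    # binary per (molecule pair, unordered residue pair, frame): one
    # backbone bead per residue, so dedupe the two bead orientations
    uniq <- !duplicated(paste(ma, mb, rmin, rmax))
    inc <- table(factor(rmin[uniq], levels = seq_len(n_r)),
                 factor(rmax[uniq], levels = seq_len(n_r)))
    inc <- unclass(inc)
    dimnames(inc) <- NULL
    C <- C + inc + t(inc)
    diag(C) <- diag(C) - diag(inc)   # one count on the diagonal
  }
  structure(list(C = C, F = length(traj), M = m, N_r = n_r, cutoff = cutoff),
            class = "contact_accumulator")
}

#' Residue-pair contact probability map
#'
#' Normalizes accumulated counts to the probability that a randomly
#' chosen residue in one molecule contacts a randomly chosen residue in a
#' different molecule:
#' `P[i, j] = C[i, j] / (F * choose(M, 2) * N_r^2)` -- counts divided by
#' the number of frames, the number of molecule pairs, and the `N_r^2`
#' equally likely residue pairings. Under this normalization
#' `0 <= P[i, j] <= 1 / N_r^2`.
#'
#' @param acc A `contact_accumulator` with `F > 0`.
#' @return A `contact_map`: list with `P` (matrix), `N_r`, `M`, `F`,
#'   `cutoff`, and `norm` (the per-frame normalization constant
#'   `choose(M, 2) * N_r^2`).
#' @export
contact_probability <- function(acc) {
  stopifnot(inherits(acc, "contact_accumulator"))
  if (acc$F <= 0)
    abort("contact map undefined: zero frames accumulated",
          class = "cgagg_contact_error")
  if (acc$M < 2)
    abort("contact map undefined: need at least two proteins",
          class = "cgagg_contact_error")
  norm <- choose(acc$M, 2) * acc$N_r^2
  structure(list(P = acc$C / (acc$F * norm), N_r = acc$N_r, M = acc$M,
                 F = acc$F, cutoff = acc$cutoff, norm = norm),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> N_r = %d, M = %d, F = %d, max P = %.3g\n",
              x$N_r, x$M, x$F, max(x$P)))
  invisible(x)
}

#' Tidy a contact-probability map
#'
#' @param x A `contact_map`.
#' @param ... Ignored.
#' @return A tibble with `residue_i`, `residue_j`, `P` (upper triangle
#'   including the diagonal).
#' @export
tidy.contact_map <- function(x, ...) {
  idx <- which(upper.tri(x$P, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(residue_i = idx[, 1], residue_j = idx[, 2],
                 P = x$P[idx])
}

#' @rdname tidy.contact_map
#' @param object A `contact_map`.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidy(object)
  df2 <- df[df$residue_i != df$residue_j,
            c("residue_j", "residue_i", "P")]
  names(df2) <- c("residue_i", "residue_j", "P")
  ggplot2::ggplot(dplyr::bind_rows(df, df2),
                  ggplot2::aes(x = .data$residue_i, y = .data$residue_j,
                               fill = .data$P)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_minimal()
}

#' Residue pairs with high contact probability
#'
#' Strictly-greater-than filter on the probability map, sorted by
#' descending `P` with ties broken lexicographically by `(i, j)`.
#'
#' @param map A `contact_map`.
#' @param cutoff Probability cutoff (default `10.0e-9`, the conventional
#'   high-contact threshold for these maps).
#' @return A tibble `residue_i`, `residue_j`, `P` (upper triangle).
#' @export
high_contact_pairs <- function(map, cutoff = 10.0e-9) {
  stopifnot(inherits(map, "contact_map"))
  df <- tidy(map)
  df <- df[df$P > cutoff, ]
  df[order(-df$P, df$residue_i, df$residue_j), ]
}

#' Ratio of total per-frame inter-protein contacts between two ensembles
#'
#' `R = (sum(C_a) / F_a) / (sum(C_b) / F_b)`: total residue-pair contact
#' counts per frame, ratioed so windows of unequal length are comparable.
#' Used to compare contact formation across simulation conditions (for
#' instance different solvent models). Antisymmetric under swap:
#' `R(a, b) * R(b, a) = 1`.
#'
#' @param acc_a,acc_b `contact_accumulator` objects with the same `N_r`
#'   and nonzero frame counts.
#' @return The dimensionless ratio.
#' @export
contact_ratio_R <- function(acc_a, acc_b) {
  stopifnot(inherits(acc_a, "contact_accumulator"),
            inherits(acc_b, "contact_accumulator"))
  if (acc_a$N_r != acc_b$N_r)
    abort("accumulators have different N_r; ratio undefined",
          class = "cgagg_contact_error")
  if (acc_a$F <= 0 || acc_b$F <= 0)
    abort("both accumulators need at least one frame",
          class = "cgagg_contact_error")
  hb <- sum(acc_b$C) / acc_b$F
  if (hb == 0)
    abort("undefined ratio: denominator ensemble has zero contacts",
          class = "cgagg_contact_error")
  (sum(acc_a$C) / acc_a$F) / hb
}
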