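#' Inter-protein contact pairs in one frame
#'
#' Two proteins are in contact when any two of their backbone beads lie
#' within `cutoff` (minimum-image distance, closed interval). The search
#' uses a periodic cell-list index, so scaling is near-linear in bead
#' count.
#'
#' @param frame A `cg_frame`.
#' @param topo A `bead_topology` with at least one protein.
#' @param cutoff Contact cutoff (nm); default 0.75, the backbone-bead
#'   contact criterion.
#' @param bead_role Bead role the criterion applies to (default
#'   `"BACKBONE"`).
#' @return A tibble with columns `mol_a`, `mol_b` (`mol_a < mol_b`), one
#'   row per protein pair in contact.
#' @export
protein_contact_pairs <- function(frame, topo, cutoff = 0.75,
                                  bead_role = "BACKBONE") {
  sel <- topo$molecule_type == "PROTEIN" & topo$bead_role == bead_role
  if (!any(sel)) abort("topology contains no protein beads of that role")
  pos <- frame$positions[sel, , drop = FALSE]
  mol <- topo$molecule_id[sel]
  pr <- neighbor_pairs(pos, frame$box, cutoff)
  a <- mol[pr$i]; b <- mol[pr$j]
  keep <- a != b
  if (!any(keep)) return(tibble::tibble(mol_a = integer(0), mol_b = integer(0)))
  pa <- pmin(a[keep], b[keep]); pb <- pmax(a[keep], b[keep])
  dplyr::distinct(tibble::tibble(mol_a = pa, mol_b = pb)) |>
    dplyr::arrange(.data$mol_a, .data$mol_b)
}

#' Partition proteins into clusters from a contact-pair set
#'
#' Connected components of the contact graph via union-find; the label of
#' each cluster is canonicalized to the smallest protein id it contains.
#'
#' @param pairs A data frame with columns `mol_a`, `mol_b` (protein ids),
#'   or a 2-column matrix.
#' @param protein_ids Integer vector of all protein ids (isolated proteins
#'   become singleton clusters).
#' @return Named integer vector: for each protein id, its cluster label.
#' @export
assign_clusters <- function(pairs, protein_ids) {
  protein_ids <- sort(unique(as.integer(protein_ids)))
  parent <- seq_along(protein_ids)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  if (is.matrix(pairs)) pairs <- tibble::tibble(mol_a = pairs[, 1], mol_b = pairs[, 2])
  if (nrow(pairs)) {
    a <- match(as.integer(pairs$mol_a), protein_ids)
    b <- match(as.integer(pairs$mol_b), protein_ids)
    if (anyNA(a) || anyNA(b))
      abort("contact pairs reference ids outside protein_ids")
    for (k in seq_along(a)) {
      ra <- find_root(a[k]); rb <- find_root(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(parent), find_root, integer(1))
  canon <- tapply(protein_ids, roots, min)
  setNames(as.integer(canon[as.character(roots)]), protein_ids)
}

#' Per-frame cluster statistics over a trajectory
#'
#' Applies the backbone-bead contact criterion and connected-component
#' clustering to every frame, producing the cluster-count time series
#' (monomers count as size-1 clusters; the size multiset is retained so
#' either counting convention is recoverable).
#'
#' @inheritParams protein_contact_pairs
#' @param traj A `cg_trajectory`.
#' @return A `cluster_series` tibble with columns `time_ns`, `n_clusters`,
#'   `largest_size`, and list-columns `sizes` (cluster size multiset) and
#'   `labels` (named per-protein cluster labels).
#' @export
cluster_timeseries <- function(traj, topo, cutoff = 0.75,
                               bead_role = "BACKBONE") {
  ids <- sort(unique(topo$molecule_id[topo$molecule_type == "PROTEIN"]))
  if (!length(ids)) abort("topology contains no proteins")
  rows <- purrr::map(traj, function(f) {
    pr <- protein_contact_pairs(f, topo, cutoff, bead_role)
    lab <- assign_clusters(pr, ids)
    sz <- sort(as.integer(table(lab)), decreasing = TRUE)
    tibble::tibble(time_ns = f$time, n_clusters = length(sz),
                   largest_size = sz[1], sizes = list(sz),
                   labels = list(lab))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_series", class(out))
  out
}

#' Time at which aggregation reaches a target cluster count
#'
#' First time `t` such that `n_clusters <= target_count` holds for `dwell`
#' consecutive frames starting at `t`. The dwell requirement guards
#' against transient touches in noisy series.
#'
#' @param series A `cluster_series` (or any tibble with `time_ns` and
#'   `n_clusters`).
#' @param target_count Target cluster count (default 1, full aggregation).
#' @param dwell Number of consecutive frames required (default 5).
#' @return Time (ns), or `NA_real_` when the target is never held for
#'   `dwell` frames ("not reached").
#' @export
aggregation_time <- function(series, target_count = 1L, dwell = 5L) {
  if (dwell < 1L) abort("dwell must be >= 1")
  ok <- series$n_clusters <= target_count
  n <- length(ok)
  if (n < dwell) return(NA_real_)
  run <- stats::filter(as.numeric(ok), rep(1, dwell), sides = 1)
  hit <- which(run == dwell)
  if (!length(hit)) return(NA_real_)
  series$time_ns[hit[1] - dwell + 1L]
}

#' @export
print.cluster_series <- function(x, ...) {
  cat(sprintf("<cluster_series> %d frames, n_clusters %d -> %d\n",
              nrow(x), x$n_clusters[1], x$n_clusters[nrow(x)]))
  NextMethod()
}

#' @rdname cluster_timeseries
#' @param object A `cluster_series`.
#' @param ... Ignored.
#' @export
autoplot.cluster_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                       y = .data$n_clusters)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "number of clusters") +
    ggplot2::theme_minimal()
}
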