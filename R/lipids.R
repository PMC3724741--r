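#' Lipid beads in contact with a protein residue range
#'
#' Counts, per lipid species, the lipid beads (any role) lying within
#' `cutoff` of any bead belonging to the selected protein residues. A
#' lipid bead in contact with several proteins is counted once (globally).
#'
#' @param frame A `cg_frame`.
#' @param topo A `bead_topology`.
#' @param residue_range Length-2 integer range of protein residues
#'   (1-based, inclusive); e.g. `c(1, 179)` selects the G-domain plus
#'   linker of a 186-residue protein.
#' @param cutoff Contact cutoff (nm), default 0.75.
#' @return A tibble `molecule_type`, `n_beads` with one row per lipid
#'   species present in the topology (DPPC, DLIPC, CHOL).
#' @export
protein_lipid_contacts <- function(frame, topo, residue_range = NULL,
                                   cutoff = 0.75) {
  lipid_types <- c("DPPC", "DLIPC", "CHOL")
  is_prot <- topo$molecule_type == "PROTEIN"
  if (!any(is_prot)) abort("topology contains no proteins")
  if (is.null(residue_range))
    residue_range <- c(1L, max(topo$residue_index[is_prot]))
  if (length(residue_range) != 2L || residue_range[1] > residue_range[2] ||
      residue_range[1] < 1L)
    abort("residue_range must be a non-empty 1-based range c(lo, hi)")
  psel <- is_prot & topo$residue_index >= residue_range[1] &
    topo$residue_index <= residue_range[2]
  if (!any(psel)) abort("empty residue range: no protein beads selected")
  lsel <- topo$molecule_type %in% lipid_types
  species <- intersect(lipid_types, unique(topo$molecule_type))

  counts <- setNames(integer(length(species)), species)
  if (any(lsel)) {
    sel <- psel | lsel
    pos <- frame$positions[sel, , drop = FALSE]
    prot_flag <- psel[sel]
    type <- topo$molecule_type[sel]
    bead <- which(sel)
    pr <- neighbor_pairs(pos, frame$box, cutoff)
    cross <- xor(prot_flag[pr$i], prot_flag[pr$j])
    lip_idx <- ifelse(prot_flag[pr$i], pr$j, pr$i)[cross]
    lip_idx <- unique(lip_idx)     # each lipid bead counted once
    tb <- table(type[lip_idx])
    counts[names(tb)[names(tb) %in% species]] <-
      as.integer(tb[names(tb) %in% species])
  }
  tibble::tibble(molecule_type = species, n_beads = unname(counts[species]))
}

#' Lipid-domain preference of aggregated proteins
#'
#' Averages per-frame DPPC and DLiPC bead contact counts (via
#' [protein_lipid_contacts()] over all protein residues) across an
#' analysis window, and reports the liquid-ordered : liquid-disordered
#' contact ratio `count_DPPC / count_DLiPC` with a block-averaged standard
#' error (frames split into `n_blocks` contiguous time blocks, ratio
#' recomputed per block, standard error of the block means).
#'
#' Proteins sitting on the domain boundary give a ratio near 1; values
#' below 1 indicate liquid-disordered preference. If no DLiPC contact
#' occurs in any frame the ratio is undefined and reported as `NA`
#' (counts are still returned).
#'
#' @param traj A `cg_trajectory` with at least 2 frames (restrict with
#'   [trajectory_window()] first).
#' @param topo A `bead_topology` containing proteins and lipids.
#' @param cutoff Contact cutoff (nm), default 0.75.
#' @param n_blocks Number of time blocks for the error estimate.
#' @return A `domain_contact_stats` list: `counts` (tibble of per-species
#'   mean contact counts), `ratio_dppc_dlipc`, `stderr`, `n_frames`.
#' @export
domain_preference_ratio <- function(traj, topo, cutoff = 0.75,
                                    n_blocks = 5L) {
  if (length(traj) < 2L)
    abort("domain preference needs a window of at least 2 frames",
          class = "cgagg_window_error")
  per_frame <- purrr::map(traj, function(f) {
    pc <- protein_lipid_contacts(f, topo, cutoff = cutoff)
    setNames(pc$n_beads, pc$molecule_type)
  })
  mat <- do.call(rbind, per_frame)
  means <- colMeans(mat)
  counts <- tibble::tibble(molecule_type = colnames(mat),
                           mean_n_beads = unname(means))
  dppc <- if ("DPPC" %in% colnames(mat)) mat[, "DPPC"] else rep(0, nrow(mat))
  dlipc <- if ("DLIPC" %in% colnames(mat)) mat[, "DLIPC"] else rep(0, nrow(mat))
  if (sum(dlipc) == 0) {
    ratio <- NA_real_; se <- NA_real_
  } else {
    ratio <- mean(dppc) / mean(dlipc)
    blk <- cut(seq_len(nrow(mat)), breaks = min(n_blocks, nrow(mat)),
               labels = FALSE)
    bratio <- vapply(split(seq_len(nrow(mat)), blk), function(ix) {
      if (sum(dlipc[ix]) == 0) return(NA_real_)
      mean(dppc[ix]) / mean(dlipc[ix])
    }, numeric(1))
    bratio <- bratio[is.finite(bratio)]
    se <- if (length(bratio) >= 2L) sd(bratio) / sqrt(length(bratio)) else NA_real_
  }
  structure(list(counts = counts, ratio_dppc_dlipc = ratio, stderr = se,
                 n_frames = length(traj)),
            class = "domain_contact_stats")
}

#' @export
print.domain_contact_stats <- function(x, ...) {
  cat(sprintf("<domain_contact_stats> DPPC:DLiPC ratio = %s +/- %s (%d frames)\n",
              format(x$ratio_dppc_dlipc, digits = 4),
              format(x$stderr, digits = 2), x$n_frames))
  invisible(x)
}

#' Lipid de-mixing contact ratio per leaflet
#'
#' For each frame and leaflet, computes the fraction of DPPC contact
#' slots occupied by DLiPC:
#' `hetero / (hetero + 2 * homo)`, where `hetero` is the number of
#' DPPC--DLiPC bead pairs within `cutoff` and `homo` the number of
#' DPPC--DPPC pairs (each homo pair fills two DPPC slots). In a randomly
#' mixed field the expectation is `n_DLiPC / (n_DPPC + n_DLiPC - 1)`; the
#' ratio declines toward a stripe-boundary floor as the field de-mixes.
#'
#' Leaflets are assigned by the sign of z relative to the median z of all
#' lipid beads (flat synthetic bilayers), unless the topology carries an
#' explicit `leaflet` column.
#'
#' @param traj A `cg_trajectory`.
#' @param topo A `bead_topology` with lipid beads.
#' @param cutoff Contact cutoff (nm), default 0.75.
#' @return A tibble `time_ns`, `leaflet` (`"upper"`/`"lower"`), `ratio`.
#' @export
demixing_contact_ratio <- function(traj, topo, cutoff = 0.75) {
  lsel <- topo$molecule_type %in% c("DPPC", "DLIPC")
  if (!any(lsel))
    abort("topology contains no DPPC/DLiPC beads",
          class = "cgagg_contact_error")
  has_leaflet_col <- "leaflet" %in% names(attributes(topo)) ||
    "leaflet" %in% names(topo)
  type <- topo$molecule_type[lsel]
  rows <- purrr::map(traj, function(f) {
    pos <- f$positions[lsel, , drop = FALSE]
    leaf <- if (has_leaflet_col) {
      ifelse(topo$leaflet[lsel] == 1L, "lower", "upper")
    } else {
      zmed <- median(f$positions[topo$molecule_type %in%
                                   c("DPPC", "DLIPC", "CHOL"), 3])
      ifelse(pos[, 3] <= zmed, "lower", "upper")
    }
    purrr::map(c("lower", "upper"), function(lf) {
      ix <- leaf == lf
      if (!any(ix)) return(NULL)
      pr <- neighbor_pairs(pos[ix, , drop = FALSE], f$box, cutoff)
      ti <- type[ix][pr$i]; tj <- type[ix][pr$j]
      hetero <- sum(ti != tj)
      homo_dppc <- sum(ti == "DPPC" & tj == "DPPC")
      den <- hetero + 2 * homo_dppc
      tibble::tibble(time_ns = f$time, leaflet = lf,
                     ratio = if (den > 0) hetero / den else 0)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
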