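#' Construct and validate a bead topology
#'
#' A bead topology is the static per-bead metadata table shared by every
#' analysis stage: which molecule a bead belongs to, the molecule type,
#' the residue it represents, its role (one backbone bead per residue in
#' the coarse-grained mapping) and its radius for surface-area work.
#'
#' Validation enforces:
#' * required columns `bead_id` (0-based, contiguous), `molecule_id`,
#'   `molecule_type`, `residue_index` (1-based), `bead_role`, `bead_radius`;
#' * `molecule_type` in `PROTEIN, DPPC, DLIPC, CHOL, OTHER` and `bead_role`
#'   in `BACKBONE, SIDECHAIN, LIPID_TAIL, HEADGROUP, OTHER`;
#' * every protein has exactly one `BACKBONE` bead per residue and its
#'   residue indices span `1..N_r` contiguously;
#' * strictly positive bead radii.
#'
#' @param df A data frame with the columns above.
#' @return A validated `bead_topology` tibble.
#' @export
bead_topology <- function(df) {
  req <- c("bead_id", "molecule_id", "molecule_type", "residue_index",
           "bead_role", "bead_radius")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    abort(paste0("topology is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cgagg_topology_error")
  df <- tibble::as_tibble(df)[req]
  df$bead_id <- as.integer(df$bead_id)
  df$molecule_id <- as.integer(df$molecule_id)
  df$residue_index <- as.integer(df$residue_index)
  df$molecule_type <- as.character(df$molecule_type)
  df$bead_role <- as.character(df$bead_role)
  df$bead_radius <- as.numeric(df$bead_radius)

  bad_type <- setdiff(unique(df$molecule_type), MOLECULE_TYPES)
  if (length(bad_type))
    abort(paste0("unknown molecule_type token(s): ",
                 paste(bad_type, collapse = ", ")),
          class = "cgagg_topology_error")
  bad_role <- setdiff(unique(df$bead_role), BEAD_ROLES)
  if (length(bad_role))
    abort(paste0("unknown bead_role token(s): ",
                 paste(bad_role, collapse = ", ")),
          class = "cgagg_topology_error")
  if (!identical(df$bead_id, seq_len(nrow(df)) - 1L))
    abort("bead_id must be 0-based and contiguous in row order",
          class = "cgagg_topology_error")
  if (any(!is.finite(df$bead_radius)) || any(df$bead_radius <= 0))
    abort("bead_radius must be strictly positive for every bead",
          class = "cgagg_topology_error")

  prot <- df[df$molecule_type == "PROTEIN", ]
  if (nrow(prot)) {
    for (m in unique(prot$molecule_id)) {
      pm <- prot[prot$molecule_id == m, ]
      bb <- pm[pm$bead_role == "BACKBONE", ]
      if (any(duplicated(bb$residue_index)))
        abort(sprintf("protein %d has a duplicate BACKBONE bead for residue %d",
                      m, bb$residue_index[duplicated(bb$residue_index)][1]),
              class = "cgagg_topology_error")
      n_r <- max(pm$residue_index)
      if (!setequal(bb$residue_index, seq_len(n_r)))
        abort(sprintf(
          "protein %d: BACKBONE residue indices must span 1..%d contiguously",
          m, n_r), class = "cgagg_topology_error")
    }
  }
  class(df) <- c("bead_topology", class(df))
  df
}

#' Number of residues per protein in a topology
#'
#' @param topo A `bead_topology`.
#' @return Named integer vector, one entry per protein molecule.
#' @export
protein_residue_counts <- function(topo) {
  prot <- topo[topo$molecule_type == "PROTEIN" & topo$bead_role == "BACKBONE", ]
  if (!nrow(prot)) return(setNames(integer(0), character(0)))
  res <- tapply(prot$residue_index, prot$molecule_id, max)
  setNames(as.integer(res), names(res))
}

#' Read a bead topology table
#'
#' Reads a tab- or comma-separated table with a one-line header and the six
#' topology columns, and validates it (see [bead_topology()]).
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated `bead_topology` tibble.
#' @export
read_topology_table <- function(path) {
  if (!file.exists(path))
    abort(paste0("topology file not found: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  bead_topology(df)
}

#' Write a bead topology table
#'
#' Writes the six topology columns as TSV in deterministic column order.
#'
#' @param topo A `bead_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(topo, path) {
  readr::write_tsv(tibble::as_tibble(unclass(topo)), path, progress = FALSE)
  invisible(path)
}
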