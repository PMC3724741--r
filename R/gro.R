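#' Read a GRO coordinate file (single- or multi-frame)
#'
#' Parses the fixed-column GROMACS GRO format (positions in nm). Multiple
#' concatenated frames are supported; the frame time is taken from a
#' `t= <ns>` token on the title line when present, otherwise frames are
#' numbered 0, 1, 2, ... ns. Only orthorhombic boxes are accepted: a
#' 9-component box line with any nonzero off-diagonal term is rejected.
#'
#' The 5-character residue and atom id fields wrap at 100000 in large
#' systems; the reader reconstructs an unwrapped `residue_serial` by
#' change-detection on the raw residue field, so downstream topology
#' assignment is immune to the wrap.
#'
#' @param path Path to a `.gro` file.
#' @return A `cg_trajectory` with attribute `atoms`: a tibble with one row
#'   per bead (`resid_raw`, `resname`, `atom_name`, `residue_serial`)
#'   describing the first frame's naming, usable as a topology skeleton.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) abort(paste0("GRO file not found: ", path))
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  ln <- 1L
  fidx <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    title <- lines[ln]
    if (ln + 1L > length(lines))
      abort(sprintf("GRO parse error at line %d: missing atom-count line", ln + 1L),
            class = "cgagg_parse_error")
    nat <- suppressWarnings(as.integer(trimws(lines[ln + 1L])))
    if (is.na(nat) || nat < 1L)
      abort(sprintf("GRO parse error at line %d: malformed atom-count line '%s'",
                    ln + 1L, lines[ln + 1L]),
            class = "cgagg_parse_error")
    if (ln + 1L + nat + 1L > length(lines))
      abort(sprintf("GRO parse error: frame starting at line %d is truncated", ln),
            class = "cgagg_parse_error")
    al <- lines[(ln + 2L):(ln + 1L + nat)]
    x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
      abort(sprintf("GRO parse error at line %d: malformed coordinate fields",
                    ln + 1L + bad), class = "cgagg_parse_error")
    }
    box_fields <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[ln + 2L + nat]), "[[:space:]]+")[[1]]))
    if (anyNA(box_fields) || !(length(box_fields) %in% c(3L, 9L)))
      abort(sprintf("GRO parse error at line %d: malformed box line",
                    ln + 2L + nat), class = "cgagg_parse_error")
    if (length(box_fields) == 9L) {
      if (any(abs(box_fields[4:9]) > 0))
        abort("unsupported geometry: triclinic box with nonzero off-diagonal terms",
              class = "cgagg_unsupported_geometry")
      box_fields <- box_fields[1:3]
    }
    tm <- regmatches(title, regexec("t= *([0-9.eE+-]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else as.numeric(fidx)
    frames[[length(frames) + 1L]] <- cg_frame(time, box_fields, cbind(x, y, z))
    if (is.null(atoms)) {
      resid_raw <- as.integer(substr(al, 1L, 5L))
      resname <- trimws(substr(al, 6L, 10L))
      atom_name <- trimws(substr(al, 11L, 15L))
      changed <- c(TRUE, resid_raw[-1L] != resid_raw[-nat] |
                     resname[-1L] != resname[-nat])
      atoms <- tibble::tibble(
        resid_raw = resid_raw, resname = resname, atom_name = atom_name,
        residue_serial = cumsum(changed))
    }
    ln <- ln + 3L + nat
    fidx <- fidx + 1L
  }
  if (!length(frames)) abort("GRO file contains no frames",
                             class = "cgagg_parse_error")
  traj <- cg_trajectory(frames)
  attr(traj, "atoms") <- atoms
  traj
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Emits one GRO block per frame with the frame time recorded as `t= <ns>`
#' on the title line. Residue/atom naming comes from `atoms` (for instance
#' the skeleton returned by [read_gro()]) or, if absent, is derived from a
#' bead topology (`molecule_type` to residue name, `bead_role` to atom
#' name, one residue serial per `(molecule_id, residue_index)`).
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path.
#' @param atoms Optional tibble with `resid_raw`, `resname`, `atom_name`.
#' @param topo Optional `bead_topology` used when `atoms` is missing.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, atoms = NULL, topo = NULL) {
  if (inherits(traj, "cg_frame")) traj <- cg_trajectory(list(traj))
  if (is.null(atoms)) atoms <- attr(traj, "atoms")
  n <- nrow(traj[[1]]$positions)
  if (is.null(atoms)) {
    if (is.null(topo)) abort("write_gro needs `atoms` or `topo` for naming")
    resmap <- c(PROTEIN = "PROT", DPPC = "DPPC", DLIPC = "DLIPC",
                CHOL = "CHOL", OTHER = "OTHER")
    rolemap <- c(BACKBONE = "BB", SIDECHAIN = "SC", LIPID_TAIL = "TAIL",
                 HEADGROUP = "HEAD", OTHER = "OTH")
    serial <- cumsum(!duplicated(paste(topo$molecule_id, topo$residue_index)))
    atoms <- tibble::tibble(
      resid_raw = serial %% 100000L,
      resname = unname(resmap[topo$molecule_type]),
      atom_name = unname(rolemap[topo$bead_role]),
      residue_serial = serial)
  }
  if (nrow(atoms) != n) abort("atom naming table length mismatch")
  atomid <- seq_len(n) %% 100000L
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in traj) {
    writeLines(sprintf("cgagg frame t= %.5f", f$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resid_raw %% 100000L, atoms$resname,
                       atoms$atom_name, atomid,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}
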