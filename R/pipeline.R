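#' Run the full aggregation-analysis pipeline
#'
#' Chains cluster detection, residue contact-map accumulation, lateral
#' diffusion estimation, windowed SASA/burial analysis and lipid-domain
#' statistics over one trajectory, writing tabular artifacts and a
#' machine-readable JSON report. All stage parameters live in one config
#' so a full run is reproducible from a single artifact; the report
#' contains no timestamps, so identical inputs give byte-identical
#' reports.
#'
#' @param config A named list (see Details) or the path to a YAML file
#'   with the same structure.
#'
#' @details Config keys (all optional except `input` and `output_dir`):
#' * `input`: `trajectory` (GRO path) and `topology` (TSV path);
#' * `seed`: integer seed recorded in the report;
#' * `clusters`: `cutoff` (nm, 0.75), `dwell` (frames, 5);
#' * `contacts`: `cutoff`, `window` (ns pair), `high_p_cutoff` (10e-9);
#' * `diffusion`: `window`, `max_lag`, `fit_window` (ns pairs);
#' * `sasa`: `probe` (0.56), `early`/`late` windows (default first/last
#'   10% of the trajectory), `spacing`, `n_sphere_points` (960),
#'   `threshold` (0.75 nm^2);
#' * `domains`: `cutoff`, `window` (default last 25%); skipped when the
#'   topology has no lipids;
#' * `output_dir`: directory for `report.json`, `clusters.tsv`,
#'   `pmap.tsv`, `high_pairs.tsv`, `msd.tsv`, `dsasa.tsv`,
#'   `domains.tsv`.
#'
#' A failing stage aborts with the stage name; partial outputs are kept
#' and `MANIFEST` in the output directory marks the run incomplete.
#'
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)

  if (is.null(cfg$input$trajectory) || !file.exists(cfg$input$trajectory))
    abort("config validation: input trajectory path missing or nonexistent",
          class = "cgagg_config_error")
  if (is.null(cfg$input$topology) || !file.exists(cfg$input$topology))
    abort("config validation: input topology path missing or nonexistent",
          class = "cgagg_config_error")
  if (is.null(cfg$output_dir))
    abort("config validation: output_dir is required",
          class = "cgagg_config_error")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  done <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[cgagg] stage %-9s ...", name))
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(c("status: INCOMPLETE",
                   paste0("failed_stage: ", name),
                   paste0("completed: ", paste(done, collapse = ", "))),
                 file.path(cfg$output_dir, "MANIFEST"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "cgagg_stage_error")
    })
    message(sprintf("[cgagg] stage %-9s done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    done <<- c(done, name)
    res
  }

  io <- stage("load", {
    traj <- read_gro(cfg$input$trajectory)
    topo <- read_topology_table(cfg$input$topology)
    if (nrow(topo) != nrow(traj[[1]]$positions))
      abort("topology bead count does not match trajectory")
    list(traj = traj, topo = topo)
  })
  traj <- io$traj; topo <- io$topo
  tt <- frame_times(traj)
  span <- range(tt)

  cl <- stage("clusters", {
    s <- cluster_timeseries(traj, topo, cfg$clusters$cutoff)
    readr::write_tsv(s[c("time_ns", "n_clusters", "largest_size")],
                     file.path(cfg$output_dir, "clusters.tsv"),
                     progress = FALSE)
    s
  })

  cm <- stage("contacts", {
    tr <- traj
    if (!is.null(cfg$contacts$window))
      tr <- trajectory_window(traj, cfg$contacts$window[1],
                              cfg$contacts$window[2])
    acc <- accumulate_residue_contacts(tr, topo, cfg$contacts$cutoff)
    pm <- contact_probability(acc)
    readr::write_tsv(tidy(pm), file.path(cfg$output_dir, "pmap.tsv"),
                     progress = FALSE)
    hp <- high_contact_pairs(pm, cfg$contacts$high_p_cutoff)
    readr::write_tsv(hp, file.path(cfg$output_dir, "high_pairs.tsv"),
                     progress = FALSE)
    list(acc = acc, map = pm, high = hp)
  })

  dif <- stage("diffusion", {
    tracks <- unwrap_trajectory(traj, topo)
    prof <- msd_profile(tracks, window = cfg$diffusion$window,
                        max_lag = cfg$diffusion$max_lag)
    readr::write_tsv(tibble::as_tibble(prof),
                     file.path(cfg$output_dir, "msd.tsv"), progress = FALSE)
    est <- fit_diffusion(prof, cfg$diffusion$fit_window)
    list(profile = prof, estimate = est)
  })

  sas <- stage("sasa", {
    early_w <- cfg$sasa$early %||% c(span[1], span[1] + 0.1 * diff(span))
    late_w <- cfg$sasa$late %||% c(span[2] - 0.1 * diff(span), span[2])
    early_w <- snap_window(early_w, tt); late_w <- snap_window(late_w, tt)
    early <- residue_sasa_window(traj, topo, early_w, cfg$sasa$probe,
                                 cfg$sasa$spacing, cfg$sasa$n_sphere_points)
    late <- residue_sasa_window(traj, topo, late_w, cfg$sasa$probe,
                                cfg$sasa$spacing, cfg$sasa$n_sphere_points)
    ds <- delta_sasa(early, late)
    out <- tibble::as_tibble(ds)
    out$buried_flag <- out$burial_nm2 > cfg$sasa$threshold
    readr::write_tsv(out, file.path(cfg$output_dir, "dsasa.tsv"),
                     progress = FALSE)
    list(delta = ds, buried = buried_residues(ds, cfg$sasa$threshold),
         early_window = early_w, late_window = late_w)
  })

  dom <- NULL
  if (any(topo$molecule_type %in% c("DPPC", "DLIPC", "CHOL"))) {
    dom <- stage("domains", {
      w <- cfg$domains$window %||% c(span[2] - 0.25 * diff(span), span[2])
      w <- snap_window(w, tt)
      tr <- trajectory_window(traj, w[1], w[2])
      st <- domain_preference_ratio(tr, topo, cfg$domains$cutoff)
      dm <- demixing_contact_ratio(traj, topo, cfg$domains$cutoff)
      readr::write_tsv(dm, file.path(cfg$output_dir, "domains.tsv"),
                       progress = FALSE)
      list(stats = st, demixing = dm, window = w)
    })
  }

  report <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    parameters = cfg[c("clusters", "contacts", "diffusion", "sasa",
                       "domains")],
    trajectory = list(n_frames = length(traj), t_start_ns = span[1],
                      t_end_ns = span[2],
                      n_beads = nrow(traj[[1]]$positions)),
    clusters = list(
      initial_n_clusters = cl$n_clusters[1],
      final_n_clusters = cl$n_clusters[nrow(cl)],
      largest_final_size = cl$largest_size[nrow(cl)],
      aggregation_time_ns = aggregation_time(cl, dwell = cfg$clusters$dwell)),
    contacts = list(
      n_frames = cm$acc$F, n_proteins = cm$acc$M, n_residues = cm$acc$N_r,
      total_contacts_per_frame = sum(cm$acc$C) / cm$acc$F,
      max_P = max(cm$map$P), n_high_pairs = nrow(cm$high)),
    diffusion = list(
      D_1e8_cm2_s = dif$estimate$D, stderr = dif$estimate$stderr,
      fit_window_ns = dif$estimate$fit_window),
    sasa = list(
      early_window_ns = sas$early_window, late_window_ns = sas$late_window,
      n_buried = nrow(sas$buried),
      max_burial_nm2 = if (nrow(sas$delta)) max(sas$delta$burial_nm2) else 0),
    domains = if (is.null(dom)) NULL else list(
      ratio_dppc_dlipc = dom$stats$ratio_dppc_dlipc,
      stderr = dom$stats$stderr,
      window_ns = dom$window,
      final_demixing_ratio = mean(
        dom$demixing$ratio[dom$demixing$time_ns ==
                             max(dom$demixing$time_ns)]))
  )
  validate_report(report)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines("status: COMPLETE", file.path(cfg$output_dir, "MANIFEST"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

snap_window <- function(w, tt) {
  c(tt[which.min(abs(tt - w[1]))], tt[which.min(abs(tt - w[2]))])
}

pipeline_defaults <- function(config) {
  dflt <- list(
    seed = 1L,
    clusters = list(cutoff = 0.75, dwell = 5L),
    contacts = list(cutoff = 0.75, window = NULL, high_p_cutoff = 10.0e-9),
    diffusion = list(window = NULL, max_lag = NULL, fit_window = NULL),
    sasa = list(probe = 0.56, early = NULL, late = NULL, spacing = NULL,
                n_sphere_points = 960L, threshold = 0.75),
    domains = list(cutoff = 0.75, window = NULL))
  for (k in names(dflt)) {
    if (is.null(config[[k]])) config[[k]] <- dflt[[k]]
    else if (is.list(dflt[[k]]))
      for (kk in names(dflt[[k]]))
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- dflt[[k]][[kk]]
  }
  config
}

#' Validate a pipeline report against the bundled schema
#'
#' Checks the report structure against the JSON schema shipped in
#' `inst/schema/report-schema.json` (required keys and primitive types;
#' a lightweight structural validator).
#'
#' @param report A report list, or a path to a `report.json`.
#' @return `TRUE` invisibly; aborts on schema violations.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "cgagg"))
  req <- unlist(schema$required)
  missing_keys <- setdiff(req, names(report))
  if (length(missing_keys))
    abort(paste0("report schema violation; missing keys: ",
                 paste(missing_keys, collapse = ", ")),
          class = "cgagg_schema_error")
  if (!identical(as.character(report$schema_version),
                 schema$properties$schema_version$const))
    abort("report schema violation: wrong schema_version",
          class = "cgagg_schema_error")
  num_leaf <- c("clusters.initial_n_clusters", "clusters.final_n_clusters",
                "contacts.max_P", "diffusion.D_1e8_cm2_s")
  for (leaf in num_leaf) {
    parts <- strsplit(leaf, ".", fixed = TRUE)[[1]]
    v <- report[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || length(v) != 1L)
      abort(paste0("report schema violation: ", leaf, " must be a number"),
            class = "cgagg_schema_error")
  }
  invisible(TRUE)
}

#' Build a self-contained synthetic dataset on disk
#'
#' Generates a sticky-Brownian protein trajectory over a progressively
#' de-mixing ternary lipid field and writes it as a multi-frame GRO file,
#' a topology TSV and a ground-truth JSON sidecar, ready for
#' [run_pipeline()] or the file readers.
#'
#' Profiles:
#' * `tiny`: 8 proteins x 186 residues, 2000 lipid beads (5:3:2), 200
#'   frames at 4 ns -- a CI-scale dataset that builds in well under a
#'   minute;
#' * `paper_scale`: 32 proteins x 186 residues, 7320 lipid beads
#'   (3480:2304:1536), striped field.
#'
#' @param profile `"tiny"` or `"paper_scale"`.
#' @param dir Output directory.
#' @param seed RNG seed (all randomness derives from it).
#' @param n_frames Frame count override.
#' @return Invisibly, a list with the file paths (`trajectory`,
#'   `topology`, `truth`).
#' @export
make_fixture <- function(profile = c("tiny", "paper_scale"), dir,
                         seed = 1L, n_frames = NULL) {
  profile <- match.arg(profile)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (profile == "tiny") {
    np <- 8L; lip <- c(1000L, 600L, 400L); nf <- n_frames %||% 200L
    box_xy <- c(22, 23)   # quarter the reference area: keeps the tiny
                          # profile at a comparable protein density
  } else {
    np <- 32L; lip <- c(3480L, 2304L, 1536L); nf <- n_frames %||% 50L
    box_xy <- c(44, 46)
  }
  scfg <- sticky_sim_config(n_proteins = np, n_residues = 186L,
                            box_xy = box_xy, n_steps = nf - 1L, seed = seed)
  sim <- simulate_sticky_brownian(scfg)
  prot_topo <- sim$topology
  n_prot_beads <- nrow(prot_topo)

  frames <- vector("list", nf)
  lip_topo <- NULL
  for (k in seq_len(nf)) {
    dcfg <- domain_field_config(n_dppc = lip[1], n_dlipc = lip[2],
                                n_chol = lip[3], box_xy = box_xy,
                                seed = seed + k)
    fld <- generate_domain_field(dcfg, demix_progress = (k - 1) / max(1, nf - 1),
                                 time = sim$trajectory[[k]]$time)
    if (is.null(lip_topo)) lip_topo <- fld$topology
    pf <- sim$trajectory[[k]]
    frames[[k]] <- cg_frame(pf$time, pf$box,
                            rbind(pf$positions, fld$frame$positions))
  }
  topo <- bead_topology(tibble::tibble(
    bead_id = seq_len(n_prot_beads + nrow(lip_topo)) - 1L,
    molecule_id = c(prot_topo$molecule_id,
                    lip_topo$molecule_id + max(prot_topo$molecule_id)),
    molecule_type = c(prot_topo$molecule_type, lip_topo$molecule_type),
    residue_index = c(prot_topo$residue_index, lip_topo$residue_index),
    bead_role = c(prot_topo$bead_role, lip_topo$bead_role),
    bead_radius = c(prot_topo$bead_radius, lip_topo$bead_radius)))

  paths <- list(trajectory = file.path(dir, "frames.gro"),
                topology = file.path(dir, "topo.tsv"),
                truth = file.path(dir, "truth.json"))
  write_gro(cg_trajectory(frames), paths$trajectory, topo = topo)
  write_topology_table(topo, paths$topology)
  jsonlite::write_json(
    list(profile = profile, seed = seed,
         n_proteins = np, n_residues = 186L,
         lipid_counts = list(DPPC = lip[1], DLIPC = lip[2], CHOL = lip[3]),
         d_input = sim$truth$d_input,
         times = sim$truth$times,
         merges = sim$truth$merges,
         n_clusters = sim$truth$n_clusters,
         labels = sim$truth$labels,
         centers_x = sim$truth$centers_unwrapped[, , 1],
         centers_y = sim$truth$centers_unwrapped[, , 2]),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
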