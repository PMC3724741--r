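test_that("isolated and fully buried beads match closed forms", {
  fx <- make_sasa_fixture("single_sphere", r = 0.26)
  a <- bead_sasa(fx$frame, fx$topology, probe = 0.56, n_sphere_points = 960)
  expect_equal(a[1], 4 * pi * 0.82^2, tolerance = 0.005)

  fx2 <- make_sasa_fixture("buried_core")
  a2 <- bead_sasa(fx2$frame, fx2$topology, probe = 0.56)
  expect_equal(a2[1], 0)
})

test_that("two-sphere areas match the spherical-cap formula from touching to separated", {
  for (s in c(0.1, 0.4, 0.8, 1.2, 1.63, 1.7, 2.5)) {
    fx <- make_sasa_fixture("two_spheres", r = 0.26, separation = s)
    a <- bead_sasa(fx$frame, fx$topology, probe = 0.56, n_sphere_points = 960)
    expect_equal(sum(a), fx$analytic_sasa(0.56), tolerance = 0.02)
  }
})

test_that("per-residue sums conserve the per-bead total and windows average correctly", {
  set.seed(81)
  sys <- random_protein_system(3, 8, box = c(12, 12, 12), spread = 0.7)
  frames <- lapply(0:2, function(k) {
    p <- sys$frame$positions + matrix(rnorm(72, sd = 0.1), ncol = 3)
    cg_frame(k * 4, sys$frame$box, wrap_into_box_for_test(p, sys$frame$box))
  })
  traj <- cg_trajectory(frames)
  per_frame_total <- vapply(frames, function(f)
    sum(bead_sasa(f, sys$topo, 0.56, 240), na.rm = TRUE), numeric(1))

  prof1 <- residue_sasa_window(traj, sys$topo, window = c(0, 0) + c(0, 1e-7),
                               n_sphere_points = 240)
  # a single-frame window equals that frame's residue sums
  pm <- attr(prof1, "per_molecule")
  expect_equal(sum(pm), per_frame_total[1], tolerance = 1e-9)

  prof_all <- residue_sasa_window(traj, sys$topo, n_sphere_points = 240)
  expect_equal(sum(attr(prof_all, "per_molecule")), mean(per_frame_total),
               tolerance = 1e-9)

  # time-constant geometry: window average equals any single frame
  const_traj <- cg_trajectory(lapply(0:2, function(k)
    cg_frame(k * 4, sys$frame$box, sys$frame$positions)))
  pc <- residue_sasa_window(const_traj, sys$topo, n_sphere_points = 240)
  one <- residue_sasa_window(
    cg_trajectory(list(cg_frame(0, sys$frame$box, sys$frame$positions))),
    sys$topo, n_sphere_points = 240)
  expect_equal(pc$sasa_nm2, one$sasa_nm2, tolerance = 1e-12)

  # spacing must be a multiple of the frame interval
  expect_error(residue_sasa_window(traj, sys$topo, spacing = 6,
                                   n_sphere_points = 240),
               class = "cgagg_window_error")
})

test_that("SASA is invariant under rigid translation (with wrapping)", {
  set.seed(82)
  sys <- random_protein_system(2, 10, box = c(9, 9, 9), spread = 0.8)
  a0 <- bead_sasa(sys$frame, sys$topo, 0.56, 240)
  shifted <- wrap_into_box_for_test(
    sweep(sys$frame$positions, 2, c(3.123, -1.7, 4.4), `+`), sys$frame$box)
  a1 <- bead_sasa(cg_frame(0, sys$frame$box, shifted), sys$topo, 0.56, 240)
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("sphere-point refinement converges", {
  set.seed(83)
  sys <- random_protein_system(2, 9, box = c(10, 10, 10), spread = 0.5)
  tot <- vapply(c(240L, 960L, 3840L), function(np)
    sum(bead_sasa(sys$frame, sys$topo, 0.56, np), na.rm = TRUE), numeric(1))
  d1 <- abs(tot[2] - tot[1])
  d2 <- abs(tot[3] - tot[2])
  expect_lt(d2, d1)
})

test_that("per-bead areas agree with an independent reference implementation", {
  # expected values computed once with biotite.structure.sasa (Shrake-Rupley,
  # Fibonacci points, probe_radius = 5.6 A, vdw_radii = 10 * radii,
  # point_number = 3840, ignore_ions = FALSE) on this frozen 12-bead
  # arrangement (coordinates in A = 10 * nm), areas converted A^2 -> nm^2
  pos <- matrix(c(2.322, 1.317, 2.576, 2.092, 0.283, 2.927, 2.283, 2.358,
                  0.384, 1.351, 1.112, 2.78, 1.932, 2.468, 1.33, 0.682,
                  1.664, 0.191, 2.483, 1.895, 2.274, 1.064, 2.912, 2.679,
                  2.335, 0.584, 1.4, 0.131, 0.463, 2.049, 2.234, 2.903,
                  0.977, 1.111, 1.409, 0.568), ncol = 3, byrow = TRUE)
  radii <- c(0.239, 0.263, 0.246, 0.277, 0.261, 0.288, 0.279, 0.252, 0.288,
             0.286, 0.257, 0.25)
  expected <- c(2.341951, 6.040109, 5.338207, 5.892000, 3.977046, 6.454998,
                5.206082, 8.285560, 8.048156, 8.684787, 4.272594, 4.974790)
  topo <- bead_topology(data.frame(
    bead_id = 0:11, molecule_id = 1L, molecule_type = "PROTEIN",
    residue_index = 1:12, bead_role = "BACKBONE", bead_radius = radii))
  a <- bead_sasa(cg_frame(0, c(50, 50, 50), pos), topo, probe = 0.56,
                 n_sphere_points = 3840)
  expect_equal(a, expected, tolerance = 0.01)
})

test_that("delta-SASA localizes buried interface residues", {
  # monomer -> dimer: two 5-bead rods far apart, then side by side
  box <- c(20, 20, 20)
  rod <- cbind(seq(0, 2, by = 0.5), 0, 0)
  topo <- bead_topology(data.frame(
    bead_id = 0:9, molecule_id = rep(1:2, each = 5),
    molecule_type = "PROTEIN", residue_index = rep(1:5, 2),
    bead_role = "BACKBONE", bead_radius = 0.26))
  apart <- rbind(sweep(rod, 2, c(3, 3, 3), `+`),
                 sweep(rod, 2, c(3, 12, 3), `+`))
  close <- rbind(sweep(rod, 2, c(3, 3, 3), `+`),
                 sweep(rod, 2, c(3, 3.55, 3), `+`))
  early <- residue_sasa_window(cg_trajectory(list(cg_frame(0, box, apart))),
                               topo, n_sphere_points = 960)
  late <- residue_sasa_window(cg_trajectory(list(cg_frame(0, box, close))),
                              topo, n_sphere_points = 960)
  ds <- delta_sasa(early, late)
  expect_true(all(ds$delta_nm2 < 0))   # every rod residue is at the interface
  # magnitudes equal the direct two-configuration difference
  a_apart <- bead_sasa(cg_frame(0, box, apart), topo, 0.56, 960)
  a_close <- bead_sasa(cg_frame(0, box, close), topo, 0.56, 960)
  direct <- (tapply(a_close, topo$residue_index, sum) -
               tapply(a_apart, topo$residue_index, sum)) / 2  # mean of 2 copies
  expect_equal(ds$delta_nm2, as.vector(direct), tolerance = 1e-9)

  ident <- delta_sasa(early, early)
  expect_true(all(ident$delta_nm2 == 0))

  late14 <- residue_sasa_window(cg_trajectory(list(cg_frame(0, box, close))),
                                topo, probe = 0.14, n_sphere_points = 240)
  expect_error(delta_sasa(early, late14), class = "cgagg_sasa_error")
})

test_that("buried-residue extraction equals a brute-force filter", {
  set.seed(84)
  for (k in 1:10) {
    delta <- runif(40, -2, 2)
    ds <- tibble::tibble(residue_index = 1:40, sasa_early = 0, sasa_late = 0,
                         delta_nm2 = delta, burial_nm2 = pmax(-delta, 0))
    class(ds) <- c("delta_sasa", class(ds))
    attr(ds, "probe") <- 0.56
    got <- buried_residues(ds, threshold = 0.75)
    want <- which(pmax(-delta, 0) > 0.75)
    want <- want[order(-pmax(-delta, 0)[want])]
    expect_equal(got$residue_index, want)
  }
  empty <- tibble::tibble(residue_index = 1:5, sasa_early = 0, sasa_late = 0,
                          delta_nm2 = rep(0, 5), burial_nm2 = rep(0, 5))
  class(empty) <- c("delta_sasa", class(empty))
  expect_equal(nrow(buried_residues(empty)), 0)
})
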