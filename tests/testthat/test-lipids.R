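lipid_protein_fixture <- function(n_dppc_close, n_dlipc_close,
                                  n_far = 30, box = c(30, 30, 30)) {
  # protein = 3 beads at the box center; "close" lipids ring it within
  # 0.75 nm, "far" lipids sit > 5 nm away
  set.seed(71)
  ppos <- rbind(c(15, 15, 15), c(15.3, 15, 15), c(15, 15.3, 15))
  mk_ring <- function(n, rmin = 0.3, rmax = 0.7) {
    if (n == 0) return(matrix(numeric(0), 0, 3))
    th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    r <- runif(n, rmin, rmax)
    cbind(15 + r * cos(th), 15 + r * sin(th), 15)
  }
  close_d <- mk_ring(n_dppc_close)
  close_l <- mk_ring(n_dlipc_close, 0.3, 0.7)
  far <- if (n_far == 0) matrix(numeric(0), 0, 3) else
    cbind(runif(n_far, 0, 5), runif(n_far, 0, 5), 15)
  pos <- rbind(ppos, close_d, close_l, far)
  types <- c(rep("PROTEIN", 3), rep("DPPC", n_dppc_close),
             rep("DLIPC", n_dlipc_close),
             rep(c("DPPC", "DLIPC", "CHOL"), length.out = n_far))
  n <- nrow(pos)
  topo <- bead_topology(data.frame(
    bead_id = seq_len(n) - 1L,
    molecule_id = c(1L, 1L, 1L, seq_len(n - 3) + 1L),
    molecule_type = types,
    residue_index = c(1:3, rep(1L, n - 3)),
    bead_role = c(rep("BACKBONE", 3), rep("HEADGROUP", n - 3)),
    bead_radius = 0.26))
  list(frame = cg_frame(0, box, pos), topo = topo)
}

test_that("hand-placed lipid shells are counted exactly (ratio 0.85 fixture)", {
  fx <- lipid_protein_fixture(17, 20)
  got <- protein_lipid_contacts(fx$frame, fx$topo, residue_range = c(1, 3))
  counts <- setNames(got$n_beads, got$molecule_type)
  expect_equal(unname(counts["DPPC"]), 17L)
  expect_equal(unname(counts["DLIPC"]), 20L)
  expect_equal(unname(counts["CHOL"]), 0L)
  expect_equal(counts[["DPPC"]] / counts[["DLIPC"]], 0.85)
})

test_that("no lipids in range yields all-zero counts; empty range errors", {
  fx <- lipid_protein_fixture(0, 0)
  got <- protein_lipid_contacts(fx$frame, fx$topo)
  expect_true(all(got$n_beads == 0))
  expect_error(protein_lipid_contacts(fx$frame, fx$topo,
                                      residue_range = c(3, 1)))
})

test_that("lipid contact counts match a brute-force all-pairs scan", {
  set.seed(72)
  for (k in 1:3) {
    n_l <- 60
    box <- c(12, 12, 12)
    ppos <- matrix(runif(9, 4, 8), 3, 3)
    lpos <- cbind(runif(n_l) * 12, runif(n_l) * 12, runif(n_l) * 12)
    types <- sample(c("DPPC", "DLIPC", "CHOL"), n_l, TRUE)
    topo <- bead_topology(data.frame(
      bead_id = 0:(n_l + 2), molecule_id = c(1, 1, 1, seq_len(n_l) + 1),
      molecule_type = c(rep("PROTEIN", 3), types),
      residue_index = c(1:3, rep(1L, n_l)),
      bead_role = c(rep("BACKBONE", 3), rep("HEADGROUP", n_l)),
      bead_radius = 0.26))
    f <- cg_frame(0, box, rbind(ppos, lpos))
    got <- protein_lipid_contacts(f, topo, cutoff = 1.2)
    want <- setNames(c(0L, 0L, 0L), c("DPPC", "DLIPC", "CHOL"))
    for (j in seq_len(n_l)) {
      d <- sapply(1:3, function(i) brute_min_dist(ppos[i, ], lpos[j, ], box))
      if (min(d) <= 1.2) want[types[j]] <- want[types[j]] + 1L
    }
    counts <- setNames(got$n_beads, got$molecule_type)
    expect_equal(counts[c("DPPC", "DLIPC", "CHOL")],
                 want[c("DPPC", "DLIPC", "CHOL")])
  }
})

test_that("a boundary-straddling protein sees both domains equally", {
  # equal DPPC/DLiPC densities on either side of the stripe boundary;
  # protein = filled disc of beads centered on the boundary (x = 22),
  # replicated on both leaflets; each frame gets an independent field
  gx <- expand.grid(x = seq(-2, 2, by = 0.5), y = seq(-2, 2, by = 0.5))
  gx <- gx[gx$x^2 + gx$y^2 <= 4, ]
  ppos <- rbind(cbind(22 + gx$x, 23 + gx$y, 6),
                cbind(22 + gx$x, 23 + gx$y, 8))
  nb <- nrow(ppos)
  frames <- list()
  topo <- NULL
  for (k in 0:3) {
    cfg <- domain_field_config(n_dppc = 6000, n_dlipc = 6000, n_chol = 0,
                               stripe_fraction = 0.5, mixing_noise = 0,
                               seed = 73 + k)
    fld <- generate_domain_field(cfg, demix_progress = 1)
    if (is.null(topo)) {
      n_l <- nrow(fld$frame$positions)
      topo <- bead_topology(data.frame(
        bead_id = 0:(n_l + nb - 1),
        molecule_id = c(rep(1L, nb), fld$topology$molecule_id + 1L),
        molecule_type = c(rep("PROTEIN", nb), fld$topology$molecule_type),
        residue_index = c(seq_len(nb), fld$topology$residue_index),
        bead_role = c(rep("BACKBONE", nb), fld$topology$bead_role),
        bead_radius = 0.26))
    }
    frames[[k + 1]] <- cg_frame(k, fld$frame$box,
                                rbind(ppos, fld$frame$positions))
  }
  st <- domain_preference_ratio(cg_trajectory(frames), topo)
  expect_gt(st$ratio_dppc_dlipc, 0.75)
  expect_lt(st$ratio_dppc_dlipc, 1.33)
})

test_that("degenerate windows and lipid-free regions are reported, not crashed", {
  fx <- lipid_protein_fixture(10, 0, n_far = 0)
  traj <- cg_trajectory(list(fx$frame, cg_frame(1, fx$frame$box,
                                                fx$frame$positions)))
  st <- domain_preference_ratio(traj, fx$topo)
  expect_true(is.na(st$ratio_dppc_dlipc))
  expect_equal(st$counts$mean_n_beads[st$counts$molecule_type == "DPPC"], 10)
  expect_error(domain_preference_ratio(
    cg_trajectory(list(fx$frame)), fx$topo), class = "cgagg_window_error")
})

test_that("a fully mixed field matches the random-mixing expectation", {
  cfg <- domain_field_config(n_dppc = 3480, n_dlipc = 2304, n_chol = 1536,
                             seed = 74)
  fld <- generate_domain_field(cfg, demix_progress = 0)
  traj <- cg_trajectory(list(fld$frame))
  dm <- demixing_contact_ratio(traj, fld$topology)
  expected <- 2304 / (3480 + 2304 - 1)
  for (r in dm$ratio) expect_equal(r, expected, tolerance = 0.05)
})

test_that("a fully de-mixed stripe field sits near the boundary-contact floor", {
  cfg <- domain_field_config(n_dppc = 3480, n_dlipc = 2304, n_chol = 1536,
                             stripe_fraction = 0.35, mixing_noise = 0,
                             seed = 75)
  fld <- generate_domain_field(cfg, demix_progress = 1)
  dm <- demixing_contact_ratio(cg_trajectory(list(fld$frame)), fld$topology)
  mixed_expectation <- 2304 / (3480 + 2304 - 1)
  expect_true(all(dm$ratio < 0.25 * mixed_expectation))
  expect_true(all(dm$ratio > 0))

  # field of only DPPC: no hetero contacts at all
  cfg2 <- domain_field_config(n_dppc = 800, n_dlipc = 0, n_chol = 0, seed = 76)
  fld2 <- generate_domain_field(cfg2, demix_progress = 0)
  dm2 <- demixing_contact_ratio(cg_trajectory(list(fld2$frame)),
                                fld2$topology)
  expect_true(all(dm2$ratio == 0))
})

test_that("de-mixing progress produces a declining contact ratio", {
  cfg <- domain_field_config(n_dppc = 1500, n_dlipc = 1000, n_chol = 600,
                             seed = 77)
  ratios <- vapply(c(0, 0.5, 1), function(p) {
    fld <- generate_domain_field(cfg, demix_progress = p)
    dm <- demixing_contact_ratio(cg_trajectory(list(fld$frame)),
                                 fld$topology)
    mean(dm$ratio)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
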