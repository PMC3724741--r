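mk_acc <- function(C, F, M, N_r) {
  structure(list(C = C, F = F, M = M, N_r = N_r, cutoff = 0.75),
            class = "contact_accumulator")
}

test_that("contact-free and single-pair constructions accumulate exactly", {
  # two 30-residue proteins touching only at residue pair (10, 20)
  n_r <- 30L
  box <- c(40, 40, 40)
  pos <- matrix(0, 2 * n_r, 3)
  pos[1:n_r, 1] <- seq(1, by = 1.2, length.out = n_r)          # mol 1 row
  pos[1:n_r, 2] <- 10
  pos[n_r + (1:n_r), 1] <- seq(1, by = 1.2, length.out = n_r)  # mol 2 row
  pos[n_r + (1:n_r), 2] <- 20
  pos[n_r + 20, ] <- pos[10, ] + c(0, 0.5, 0)                  # the one contact
  topo <- bead_topology(data.frame(
    bead_id = 0:(2 * n_r - 1), molecule_id = rep(1:2, each = n_r),
    molecule_type = "PROTEIN", residue_index = rep(1:n_r, 2),
    bead_role = "BACKBONE", bead_radius = 0.26))
  traj <- cg_trajectory(lapply(0:4, function(k) cg_frame(k, box, pos)))

  acc <- accumulate_residue_contacts(traj, topo)
  expect_equal(acc$F, 5)
  expect_equal(acc$C[10, 20], 5)
  expect_equal(acc$C[20, 10], 5)
  expect_equal(sum(acc$C), 10)   # symmetric storage only

  pos2 <- pos; pos2[n_r + 20, 2] <- 20   # undo the contact
  acc0 <- accumulate_residue_contacts(
    cg_trajectory(list(cg_frame(0, box, pos2))), topo)
  expect_true(all(acc0$C == 0))
})

test_that("accumulation equals the O(M^2 N_r^2) brute-force oracle", {
  set.seed(51)
  for (k in 1:3) {
    sys <- random_protein_system(4, 12, box = c(8, 8, 8), spread = 0.9)
    traj <- cg_trajectory(lapply(0:4, function(t) {
      p <- sys$frame$positions + matrix(rnorm(nrow(sys$frame$positions) * 3,
                                              sd = 0.15), ncol = 3)
      cg_frame(t, sys$frame$box, wrap_into_box_for_test(p, sys$frame$box))
    }))
    acc <- accumulate_residue_contacts(traj, sys$topo, cutoff = 0.8)
    want <- brute_residue_contacts(traj, sys$topo, cutoff = 0.8)
    expect_equal(acc$C, want)
  }
})

test_that("probability normalization follows frames x molecule pairs x residue pairings", {
  # all-pairs contact in every frame -> P hits the 1/N_r^2 ceiling
  n_r <- 15L; M <- 4L; F <- 6L
  C <- matrix(0, n_r, n_r)
  C[10, 12] <- C[12, 10] <- F * choose(M, 2)
  pm <- contact_probability(mk_acc(C, F, M, n_r))
  expect_equal(pm$P[10, 12], 1 / n_r^2)
  expect_equal(pm$P[12, 10], 1 / n_r^2)
  expect_true(all(pm$P >= 0 & pm$P <= 1 / n_r^2))
  expect_equal(pm$P, t(pm$P))

  # per-frame normalization constant for the full-size system
  pm2 <- contact_probability(mk_acc(matrix(0, 186, 186), 1, 32, 186L))
  expect_equal(pm2$norm, 496 * 34596)

  expect_error(contact_probability(mk_acc(matrix(0, 5, 5), 0, 3, 5L)),
               class = "cgagg_contact_error")
})

test_that("the P-map bound and symmetry hold on accumulated random systems", {
  set.seed(52)
  sys <- random_protein_system(5, 10, box = c(6, 6, 6), spread = 1.2)
  traj <- cg_trajectory(list(sys$frame))
  acc <- accumulate_residue_contacts(traj, sys$topo, cutoff = 1.0)
  pm <- contact_probability(acc)
  expect_true(all(pm$P <= 1 / pm$N_r^2 + 1e-15))
  expect_equal(pm$P, t(pm$P))
})

test_that("high-contact extraction equals an exhaustive filter and sort", {
  set.seed(53)
  n_r <- 25L
  P <- matrix(0, n_r, n_r)
  idx <- which(upper.tri(P, diag = TRUE))
  vals <- sample(c(rep(0, 200), runif(length(idx) - 200, 0, 3e-8)))
  P[idx] <- vals
  P <- pmax(P, t(P))   # symmetrize keeping upper values
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  pm <- structure(list(P = P, N_r = n_r, M = 4, F = 2, cutoff = 0.75,
                       norm = 1), class = "contact_map")
  got <- high_contact_pairs(pm, cutoff = 10.0e-9)
  want <- list()
  for (i in 1:n_r) for (j in i:n_r)
    if (P[i, j] > 10.0e-9) want[[length(want) + 1]] <- c(i, j, P[i, j])
  want <- do.call(rbind, want)
  want <- want[order(-want[, 3], want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(got$residue_i, as.integer(want[, 1]))
  expect_equal(got$residue_j, as.integer(want[, 2]))
  expect_equal(got$P, want[, 3])

  empty <- structure(list(P = matrix(0, 5, 5), N_r = 5L, M = 2, F = 1,
                          cutoff = 0.75, norm = 1), class = "contact_map")
  expect_equal(nrow(high_contact_pairs(empty)), 0)
})

test_that("the contact ratio is 1 on identical ensembles and scale-invariant", {
  set.seed(54)
  C <- matrix(sample(0:5, 100, TRUE), 10, 10)
  C <- C + t(C)
  a <- mk_acc(C, 4, 3, 10L)
  expect_equal(contact_ratio_R(a, a), 1.0)

  # totals 59 vs 100 at equal frame count
  Ca <- matrix(0, 10, 10); Ca[1, 2] <- Ca[2, 1] <- 29.5
  Cb <- matrix(0, 10, 10); Cb[1, 2] <- Cb[2, 1] <- 50
  expect_equal(contact_ratio_R(mk_acc(Ca, 1, 3, 10L), mk_acc(Cb, 1, 3, 10L)),
               0.59)

  # halving frames with proportionally halved counts leaves R unchanged
  half <- mk_acc(C / 2, 2, 3, 10L)
  expect_equal(contact_ratio_R(half, a), 1.0)

  # antisymmetry under swap on random accumulators
  for (k in 1:10) {
    C1 <- matrix(sample(1:9, 25, TRUE), 5, 5); C1 <- C1 + t(C1)
    C2 <- matrix(sample(1:9, 25, TRUE), 5, 5); C2 <- C2 + t(C2)
    x <- mk_acc(C1, sample(1:5, 1), 4, 5L)
    y <- mk_acc(C2, sample(1:5, 1), 4, 5L)
    expect_equal(contact_ratio_R(x, y) * contact_ratio_R(y, x), 1.0)
  }
})

test_that("heterogeneous residue counts are rejected", {
  topo <- bead_topology(data.frame(
    bead_id = 0:4, molecule_id = c(1, 1, 1, 2, 2),
    molecule_type = "PROTEIN", residue_index = c(1, 2, 3, 1, 2),
    bead_role = "BACKBONE", bead_radius = 0.26))
  traj <- cg_trajectory(list(cg_frame(0, c(10, 10, 10), matrix(runif(15), 5, 3))))
  expect_error(accumulate_residue_contacts(traj, topo),
               class = "cgagg_contact_error")
})
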