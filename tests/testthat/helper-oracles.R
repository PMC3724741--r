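# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# minimum-image displacement by exhaustive search over all 27 periodic images
brute_min_image <- function(p1, p2, box) {
  best <- NULL
  best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    cand <- (p2 + c(ix, iy, iz) * box) - p1
    d <- sqrt(sum(cand^2))
    if (d < best_d) { best_d <- d; best <- cand }
  }
  best
}

brute_min_dist <- function(p1, p2, box) sqrt(sum(brute_min_image(p1, p2, box)^2))

# O(n^2) neighbor pairs
brute_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- brute_min_dist(pos[i, ], pos[j, ], box)
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      dist = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), dist = m[, 3])
}

# recursive depth-first-search connected components, labels = smallest id
dfs_components <- function(pairs, ids) {
  adj <- setNames(vector("list", length(ids)), as.character(ids))
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- as.character(pairs$mol_a[k]); b <- as.character(pairs$mol_b[k])
    adj[[a]] <- c(adj[[a]], pairs$mol_b[k])
    adj[[b]] <- c(adj[[b]], pairs$mol_a[k])
  }
  visited <- setNames(rep(FALSE, length(ids)), as.character(ids))
  labels <- setNames(rep(NA_integer_, length(ids)), as.character(ids))
  for (s in ids) {
    if (visited[as.character(s)]) next
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      vc <- as.character(v)
      if (visited[vc]) next
      visited[vc] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[vc]])
    }
    labels[as.character(comp)] <- min(comp)
  }
  labels
}

# O(M^2 * N_r^2) residue-contact accumulation, binary per molecule pair
brute_residue_contacts <- function(traj, topo, cutoff) {
  sel <- topo$molecule_type == "PROTEIN" & topo$bead_role == "BACKBONE"
  mols <- sort(unique(topo$molecule_id[sel]))
  n_r <- max(topo$residue_index[sel])
  C <- matrix(0, n_r, n_r)
  for (f in traj) {
    for (ai in seq_along(mols)) for (bi in seq_along(mols)) {
      if (ai >= bi) next
      for (i in seq_len(n_r)) for (j in seq_len(n_r)) {
        if (i > j) next
        pa <- f$positions[sel & topo$molecule_id == mols[ai] &
                            topo$residue_index == i, , drop = FALSE]
        pb <- f$positions[sel & topo$molecule_id == mols[bi] &
                            topo$residue_index == j, , drop = FALSE]
        hit <- brute_min_dist(pa[1, ], pb[1, ], f$box) <= cutoff
        if (i != j) {
          pa2 <- f$positions[sel & topo$molecule_id == mols[ai] &
                               topo$residue_index == j, , drop = FALSE]
          pb2 <- f$positions[sel & topo$molecule_id == mols[bi] &
                               topo$residue_index == i, , drop = FALSE]
          hit <- hit || brute_min_dist(pa2[1, ], pb2[1, ], f$box) <= cutoff
        }
        if (hit) {
          C[i, j] <- C[i, j] + 1
          if (i != j) C[j, i] <- C[j, i] + 1
        }
      }
    }
  }
  C
}

# double-loop MSD over all origins and lags
brute_msd <- function(tracks, max_lag) {
  mols <- sort(unique(tracks$molecule_id))
  tt <- sort(unique(tracks$time_ns))
  dt <- tt[2] - tt[1]
  k_max <- floor(max_lag / dt)
  msd <- numeric(k_max + 1)
  for (k in 0:k_max) {
    acc <- c()
    for (m in mols) {
      sub <- tracks[tracks$molecule_id == m, ]
      sub <- sub[order(sub$time_ns), ]
      for (o in seq_len(nrow(sub) - k)) {
        acc <- c(acc, (sub$x[o + k] - sub$x[o])^2 + (sub$y[o + k] - sub$y[o])^2)
      }
    }
    msd[k + 1] <- mean(acc)
  }
  data.frame(lag_ns = (0:k_max) * dt, msd_nm2 = msd)
}

# small random protein system: n proteins of n_res backbone beads
random_protein_system <- function(n_prot, n_res, box = c(10, 10, 10),
                                  spread = 0.6) {
  pos <- matrix(0, n_prot * n_res, 3)
  for (p in seq_len(n_prot)) {
    ctr <- runif(3) * box
    rows <- ((p - 1) * n_res + 1):(p * n_res)
    pos[rows, ] <- rep(ctr, each = n_res) +
      matrix(runif(n_res * 3, -spread, spread), n_res, 3)
    pos[rows, ] <- cbind(pos[rows, 1] %% box[1], pos[rows, 2] %% box[2],
                         pos[rows, 3] %% box[3])
  }
  topo <- bead_topology(data.frame(
    bead_id = seq_len(n_prot * n_res) - 1L,
    molecule_id = rep(seq_len(n_prot), each = n_res),
    molecule_type = "PROTEIN",
    residue_index = rep(seq_len(n_res), n_prot),
    bead_role = "BACKBONE", bead_radius = 0.26))
  list(frame = cg_frame(0, box, pos), topo = topo)
}

wrap_into_box_for_test <- function(pos, box) {
  cbind(pos[, 1] %% box[1], pos[, 2] %% box[2], pos[, 3] %% box[3])
}
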