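# Independently coded brute-force references. These deliberately share no
# code with the package implementations they check.

# Daura neighbour clustering, re-derived directly from its definition
oracle_daura <- function(M, cutoff) {
  n <- nrow(M)
  alive <- seq_len(n)
  out <- list()
  while (length(alive)) {
    best_center <- NA
    best_count <- -1
    for (i in alive) {
      cnt <- 0
      for (j in alive) if (M[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best_count) {
        best_count <- cnt
        best_center <- i
      }
    }
    members <- alive[vapply(alive, function(j) M[best_center, j] <= cutoff,
                            logical(1))]
    out[[length(out) + 1]] <- list(center_model = best_center,
                                   member_models = members,
                                   size = length(members))
    alive <- setdiff(alive, members)
  }
  sizes <- vapply(out, `[[`, integer(1), "size")
  centers <- vapply(out, `[[`, integer(1), "center_model")
  out[order(-sizes, centers)]
}

# greedy energy-ordered pose clustering on precomputed pose-atom coordinates
# (list of natom x 3 matrices, poses already sorted by increasing energy)
oracle_greedy_cluster <- function(coord_list, energies, cutoff) {
  n <- length(coord_list)
  assigned <- rep(FALSE, n)
  clusters <- list()
  while (any(!assigned)) {
    seed <- which(!assigned)[1]
    members <- integer(0)
    for (j in which(!assigned)) {
      rmsd <- sqrt(mean(rowSums((coord_list[[j]] - coord_list[[seed]])^2)))
      if (rmsd <= cutoff) members <- c(members, j)
    }
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1]] <- list(members = members,
                                             mean_energy = mean(energies[members]))
  }
  clusters
}

# residue contact counting by explicit double loop over atom pairs
oracle_contacts <- function(rec_xyz, rec_reskey, probe_xyz, radius) {
  counts <- setNames(integer(length(unique(rec_reskey))), unique(rec_reskey))
  for (i in seq_len(nrow(rec_xyz))) {
    for (j in seq_len(nrow(probe_xyz))) {
      d <- sqrt(sum((rec_xyz[i, ] - probe_xyz[j, ])^2))
      if (d <= radius) {
        counts[rec_reskey[i]] <- counts[rec_reskey[i]] + 1L
      }
    }
  }
  counts
}

# minimal superposed RMSD by dense Euler-angle grid search with local
# refinement (independent of the SVD route)
oracle_min_rmsd <- function(mobile, reference, n_grid = 24) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  rot_euler <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cc <- cos(ang[3]); sc <- sin(ang[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3)
    Rz2 %*% Ry %*% Rz1
  }
  f <- function(ang) sqrt(mean(rowSums((A %*% t(rot_euler(ang)) - B)^2)))
  grid1 <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  grid2 <- seq(0, pi, length.out = n_grid)
  best <- c(0, 0, 0)
  best_v <- f(best)
  for (a1 in grid1) for (a2 in grid2) for (a3 in grid1) {
    v <- f(c(a1, a2, a3))
    if (v < best_v) {
      best_v <- v
      best <- c(a1, a2, a3)
    }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# direct Lennard-Jones + distance-dependent-dielectric Coulomb pair sum,
# written independently of the compiled kernel
oracle_pair_energy <- function(probe_xyz, psig, peps, pq,
                               rec_xyz, rsig, reps, rq,
                               cutoff = 8, cap = 100, rmin = 0.6) {
  e <- 0
  for (i in seq_len(nrow(probe_xyz))) {
    for (j in seq_len(nrow(rec_xyz))) {
      r <- sqrt(sum((probe_xyz[i, ] - rec_xyz[j, ])^2))
      if (r > cutoff) next
      sig <- (psig[i] + rsig[j]) / 2
      eps <- sqrt(peps[i] * reps[j])
      lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
      e <- e + min(lj, cap)
      if (pq[i] * rq[j] != 0) {
        reff <- max(r, rmin)
        e <- e + 1389.35458 * pq[i] * rq[j] / (4 * reff^2)
      }
    }
  }
  e
}
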