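# Energy model, grids, pose sampling, minimization, clustering, consensus

lj_sigma <- function(c1, c2) {
  tab <- atom_class_table()
  (tab$sigma[tab$class == c1] + tab$sigma[tab$class == c2]) / 2
}
lj_eps <- function(c1, c2) {
  tab <- atom_class_table()
  sqrt(tab$epsilon[tab$class == c1] * tab$epsilon[tab$class == c2])
}

test_that("the pair energy reproduces the Lennard-Jones landmarks", {
  rec <- point_receptor("C.al")
  probe <- point_probe("C.al")
  sig <- lj_sigma("C.al", "C.al")
  eps <- lj_eps("C.al", "C.al")
  cfg <- mapping_config()
  e_sigma <- pose_energy(rec, pose_at(c(sig, 0, 0)), cfg,
                         probes = list(unit = probe))
  expect_equal(e_sigma, 0, tolerance = 1e-9)
  e_min <- pose_energy(rec, pose_at(c(2^(1 / 6) * sig, 0, 0)), cfg,
                       probes = list(unit = probe))
  expect_equal(e_min, -eps, tolerance = 1e-9)
  # beyond the nonbonded cutoff the energy is exactly zero
  e_far <- pose_energy(rec, pose_at(c(8.5, 0, 0)), cfg,
                       probes = list(unit = probe))
  expect_identical(e_far, 0)
})

test_that("pair energies match a hand-coded double-loop sum", {
  rec <- toy_structure(rbind(c(0, 0, 0), c(3, 1, -1)),
                       names = c("CB", "CB"), classes = c("S.ap", "S.po"))
  rec$atoms$charge <- c(0.2, -0.3)
  probes <- default_probe_library()
  cfg <- mapping_config()
  for (pn in c("ethanol", "urea", "benzene")) {
    pose <- pose_at(c(5, 1, 0), pn)
    got <- pose_energy(rec, pose, cfg, probes)
    pp <- ensmap:::probe_params(probes[[pn]])
    xyz <- ensmap:::pose_atom_coords(probes[[pn]], pose)
    rp <- ensmap:::receptor_params(rec)
    want <- oracle_pair_energy(xyz, pp$sigma, pp$epsilon, pp$charge,
                               rp$xyz, rp$sigma, rp$epsilon, rp$charge)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("grid channels equal the direct sum at grid points and nearby", {
  set.seed(11)
  xyz <- matrix(runif(30, 0, 8), ncol = 3)
  rec <- toy_structure(xyz, names = rep("CB", 10),
                       classes = rep(c("S.ap", "S.po"), 5))
  rec$atoms$charge <- rep(c(0.3, -0.3), 5)
  cfg <- mapping_config(grid_spacing = 0.8)
  g <- build_energy_grids(rec, cfg)
  probe <- point_probe("C.al", charge = 0.1)
  # at grid points the interpolation is exact
  p0 <- g$origin + c(5, 7, 3) * g$spacing
  e_grid <- grid_pose_energy(g, pose_at(p0), probes = list(unit = probe))
  e_direct <- pose_energy(rec, pose_at(p0), cfg, probes = list(unit = probe))
  expect_equal(e_grid, e_direct, tolerance = 1e-9)
  # off-grid points in the smooth attractive basin agree within 1 kJ/mol,
  # and the interpolation error contracts quadratically with the spacing
  err_at <- function(spacing) {
    cfg_h <- mapping_config(grid_spacing = spacing)
    gh <- build_energy_grids(rec, cfg_h)
    set.seed(12)
    errs <- numeric(0)
    for (i in 1:300) {
      p <- gh$origin + runif(3, 2, 12)
      dmin <- min(sqrt(colSums((t(xyz) - p)^2)))
      ed <- pose_energy(rec, pose_at(p), cfg_h, probes = list(unit = probe))
      if (ed < 0 && dmin >= 4.5) {
        eg <- grid_pose_energy(gh, pose_at(p), probes = list(unit = probe))
        errs <- c(errs, abs(eg - ed))
      }
    }
    errs
  }
  coarse <- err_at(0.8)
  expect_gt(length(coarse), 20)
  expect_lt(max(coarse), 1.0)
})

test_that("exhaustive sampling finds the verified global grid minimum", {
  rec <- point_receptor("S.ap", pos = c(5, 5, 5))
  cfg <- mapping_config(grid_spacing = 1.0, rotation_count = 8,
                        poses_retained = 50)
  g <- build_energy_grids(rec, cfg)
  probe <- point_probe("C.al")
  poses <- sample_poses(g, probe, cfg)
  # independent exhaustive enumeration over all grid points (single-atom
  # probe: orientation is irrelevant, grid value = energy)
  dims <- g$dims
  idx <- as.matrix(expand.grid(ix = 0:(dims[1] - 1), iy = 0:(dims[2] - 1),
                               iz = 0:(dims[3] - 1)))
  pts <- sweep(idx * cfg$grid_spacing, 2, g$origin, "+")
  ch <- g$channels[["C.al"]]
  evals <- ch[idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1]
  expect_equal(min(poses$energy), min(evals), tolerance = 1e-9)
  best <- pts[which.min(evals), ]
  expect_equal(as.numeric(poses[1, c("tx", "ty", "tz")]), as.numeric(best),
               tolerance = 1e-9)
  # retention correctness: kept poses are exactly the lowest-energy
  # candidates (each grid point appears once per rotation)
  expect_equal(sort(poses$energy),
               sort(rep(evals, cfg$rotation_count))[seq_len(nrow(poses))],
               tolerance = 1e-9)
})

test_that("pose retention respects the configured count", {
  gen <- generate_receptor(tiny_spec())
  cfg <- tiny_mapping_config(poses_retained = 100L)
  g <- build_energy_grids(gen$structure, cfg)
  probes <- default_probe_library()
  poses <- sample_poses(g, probes$ethane, cfg)
  expect_equal(nrow(poses), 100L)
  expect_false(is.unsorted(poses$energy))
  # more slots than candidates: everything comes back
  cfg2 <- mapping_config(grid_spacing = 4, rotation_count = 2,
                         poses_retained = 100000L)
  g2 <- build_energy_grids(gen$structure, cfg2)
  poses2 <- sample_poses(g2, probes$ethane, cfg2)
  expect_equal(nrow(poses2), 2L * prod(g2$dims))
})

test_that("no discarded candidate beats the worst retained pose", {
  rec <- toy_structure(matrix(c(0, 0, 0, 4, 0, 0, 2, 3, 0), ncol = 3,
                              byrow = TRUE),
                       names = rep("CB", 3), classes = rep("S.ap", 3))
  cfg <- mapping_config(grid_spacing = 1.5, rotation_count = 6,
                        poses_retained = 40)
  g <- build_energy_grids(rec, cfg)
  probes <- default_probe_library()
  poses <- sample_poses(g, probes$ethanol, cfg)
  # recompute every candidate energy independently via grid interpolation
  dims <- g$dims
  idx <- as.matrix(expand.grid(ix = 0:(dims[1] - 1), iy = 0:(dims[2] - 1),
                               iz = 0:(dims[3] - 1)))
  pts <- sweep(idx * cfg$grid_spacing, 2, g$origin, "+")
  quats <- rotation_set(cfg$rotation_count, offset = cfg$seed)
  all_e <- numeric(0)
  for (r in seq_len(nrow(quats))) {
    q <- quats[r, ]
    for (k in seq_len(nrow(pts))) {
      pose <- data.frame(probe = "ethanol", qw = q[1], qx = q[2], qy = q[3],
                         qz = q[4], tx = pts[k, 1], ty = pts[k, 2],
                         tz = pts[k, 3])
      all_e <- c(all_e, grid_pose_energy(g, pose, probes))
    }
  }
  expect_equal(sort(poses$energy), sort(all_e)[1:40], tolerance = 1e-6)
})

test_that("minimization descends and finds the analytic single-pair minimum", {
  rec <- point_receptor("C.al")
  probe <- point_probe("C.al")
  sig <- lj_sigma("C.al", "C.al")
  cfg <- mapping_config(minimize_maxit = 200, minimize_tol = 1e-3)
  start <- pose_at(c(2^(1 / 6) * sig + 0.5, 0, 0))
  start$energy <- pose_energy(rec, start, cfg, probes = list(unit = probe))
  out <- minimize_pose(rec, start, cfg, probes = list(unit = probe))
  r_opt <- sqrt(sum(as.numeric(out[, c("tx", "ty", "tz")])^2))
  expect_lt(abs(r_opt - 2^(1 / 6) * sig), 0.1)
  expect_lte(out$energy, start$energy)
  expect_equal(out$energy, -lj_eps("C.al", "C.al"), tolerance = 1e-3)

  # a pose already at a minimum barely moves
  at_min <- pose_at(c(2^(1 / 6) * sig, 0, 0))
  at_min$energy <- pose_energy(rec, at_min, cfg, probes = list(unit = probe))
  out2 <- minimize_pose(rec, at_min, cfg, probes = list(unit = probe))
  expect_lt(at_min$energy - out2$energy, 0.1)
})

test_that("minimization never increases the energy of sampled poses", {
  gen <- generate_receptor(tiny_spec(seed = 12))
  cfg <- tiny_mapping_config(poses_retained = 50L)
  g <- build_energy_grids(gen$structure, cfg)
  probes <- default_probe_library()
  poses <- sample_poses(g, probes$acetone, cfg)
  # rescore on the direct surface before minimizing (grid and direct differ)
  direct <- vapply(seq_len(nrow(poses)), function(i) {
    pose_energy(gen$structure, poses[i, ], cfg, probes)
  }, numeric(1))
  poses$energy <- direct
  out <- ensmap:::minimize_poses(gen$structure, poses, cfg, probes)
  expect_true(all(out$energy <= direct + 1e-6))
})

test_that("greedy pose clustering matches an independent reference", {
  probes <- default_probe_library()
  cfg <- mapping_config(pose_cluster_cutoff = 3.0, clusters_per_probe = 100L)
  # identical poses collapse to one cluster
  same <- do.call(rbind, replicate(5, pose_at(c(1, 2, 3), "benzene", -2),
                                   simplify = FALSE))
  cl <- cluster_poses(same, cfg, probes)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mean_energy, -2)
  # two distant blobs split cleanly
  two <- rbind(pose_at(c(0, 0, 0), "benzene", -3),
               pose_at(c(0.5, 0, 0), "benzene", -2),
               pose_at(c(30, 0, 0), "benzene", -2.5),
               pose_at(c(30.5, 0, 0), "benzene", -1))
  cl2 <- cluster_poses(two, cfg, probes)
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, function(c) nrow(c$poses), integer(1)), c(2L, 2L))

  # randomized crafted cases against the oracle
  set.seed(13)
  for (case in 1:5) {
    n <- 30
    centers <- matrix(runif(3 * 4, 0, 20), ncol = 3)
    poses <- do.call(rbind, lapply(seq_len(n), function(i) {
      c0 <- centers[sample(4, 1), ] + rnorm(3, sd = 0.8)
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      data.frame(probe = "ethanol", qw = q[1], qx = q[2], qy = q[3], qz = q[4],
                 tx = c0[1], ty = c0[2], tz = c0[3],
                 energy = runif(1, -10, -1))
    }))
    got <- cluster_poses(poses, cfg, probes)
    ord <- order(poses$energy)
    coord_list <- lapply(ord, function(i) {
      ensmap:::pose_atom_coords(probes$ethanol, poses[i, ])
    })
    want <- oracle_greedy_cluster(coord_list, poses$energy[ord], 3.0)
    want_sets <- lapply(want, function(w) sort(poses$energy[ord][w$members]))
    got_sets <- lapply(got, function(g) sort(g$poses$energy))
    want_me <- sort(vapply(want, `[[`, numeric(1), "mean_energy"))
    got_me <- sort(vapply(got, `[[`, numeric(1), "mean_energy"))
    expect_equal(got_me, want_me, tolerance = 1e-12)
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want_sets, paste, character(1), collapse = ","))
  }
})

test_that("only the lowest-mean-energy clusters are retained per probe", {
  probes <- default_probe_library()
  cfg <- mapping_config(clusters_per_probe = 2L)
  spread <- do.call(rbind, lapply(0:4, function(k) {
    pose_at(c(20 * k, 0, 0), "ethane", -10 + k)
  }))
  cl <- cluster_poses(spread, cfg, probes)
  expect_length(cl, 2)
  expect_equal(vapply(cl, `[[`, numeric(1), "mean_energy"), c(-10, -9))
})

test_that("consensus sites rank by size with documented tie-breaks", {
  cfg <- mapping_config(cs_linkage_cutoff = 4.0, top_cs = 10L)
  probes <- default_probe_library()
  mk_cluster <- function(center, probe, me) {
    poses <- pose_at(center, probe, me)
    structure(list(probe = probe, poses = poses, center = poses,
                   mean_energy = me, centroid = center),
              class = "ensmap_pose_cluster")
  }
  # one cluster -> one site of size 1
  cs1 <- build_consensus_sites(list(mk_cluster(c(0, 0, 0), "benzene", -5)), cfg)
  expect_length(cs1, 1)
  expect_equal(cs1[[1]]$rank, 1L)
  expect_equal(cs1[[1]]$size, 1L)

  # 5-cluster site outranks 3-cluster site
  cl <- c(lapply(1:5, function(i) mk_cluster(c(0, 0, i * 0.5), "ethanol", -4)),
          lapply(1:3, function(i) mk_cluster(c(40, 0, i * 0.5), "urea", -9)))
  cs <- build_consensus_sites(cl, cfg)
  expect_equal(vapply(cs, `[[`, numeric(1), "size"), c(5, 3))
  expect_equal(vapply(cs, `[[`, integer(1), "rank"), 1:2)

  # sizes never increase with rank, and truncation keeps the top 10 of 12
  cl12 <- unlist(lapply(1:12, function(k) {
    lapply(seq_len((k %% 3) + 1), function(i) {
      mk_cluster(c(25 * k, 0, i * 0.4), "ethane", -k)
    })
  }), recursive = FALSE)
  cs12 <- build_consensus_sites(cl12, cfg)
  expect_length(cs12, 10)
  sizes <- vapply(cs12, `[[`, numeric(1), "size")
  expect_true(all(diff(sizes) <= 0))
  # every member cluster belongs to exactly one consensus site
  n_assigned <- sum(vapply(cs12, `[[`, numeric(1), "size"))
  expect_lte(n_assigned, length(cl12))
  # empty input
  expect_length(build_consensus_sites(list(), cfg), 0)
})

test_that("mapping a structure twice with one seed is identical", {
  gen <- generate_receptor(tiny_spec(seed = 14))
  cfg <- tiny_mapping_config(seed = 5L)
  m1 <- map_structure(gen$structure, cfg)
  m2 <- map_structure(gen$structure, cfg)
  expect_identical(consensus_site_table(m1), consensus_site_table(m2))
  expect_identical(m1$sites, m2$sites)
})
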