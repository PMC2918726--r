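# Single-structure hot-spot mapping: rigid probes docked exhaustively over
# precomputed energy grids, pose retention/minimization/clustering per probe,
# and cross-probe consensus-site construction.

#' Mapping configuration
#'
#' Parameters of the probe-mapping stage. Defaults follow the standard
#' protocol: 2000 poses retained per probe, the six lowest-mean-energy pose
#' clusters kept per probe, and the 10 largest consensus sites reported.
#'
#' @param grid_spacing grid spacing in Angstrom (default 0.8).
#' @param rotation_count number of quasi-uniform probe orientations (500).
#' @param poses_retained low-energy poses kept per probe (default 2000).
#' @param clusters_per_probe pose clusters retained per probe (default 6).
#' @param pose_cluster_cutoff pose-cluster RMSD cutoff, Angstrom (default 3).
#' @param cs_linkage_cutoff consensus-site single-linkage cutoff, Angstrom (4).
#' @param top_cs number of consensus sites reported (default 10).
#' @param nonbonded_cutoff pair interaction truncation, Angstrom (default 8).
#' @param clash_cap per-pair Lennard-Jones cap, kJ/mol (default 100).
#' @param dielectric electrostatic model; only `"4r"` (distance-dependent
#'   dielectric eps(r) = 4r) is implemented.
#' @param coulomb_rmin distance floor for the Coulomb term, Angstrom (0.6).
#' @param minimize_maxit max steepest-descent iterations per pose (60).
#' @param minimize_tol force/torque convergence tolerance (kJ/mol/Angstrom).
#' @param seed deterministic offset of the orientation sequence.
#' @return object of class `ensmap_mapping_config`.
#' @export
mapping_config <- function(grid_spacing = 0.8, rotation_count = 500L,
                           poses_retained = 2000L, clusters_per_probe = 6L,
                           pose_cluster_cutoff = 3.0, cs_linkage_cutoff = 4.0,
                           top_cs = 10L, nonbonded_cutoff = 8.0,
                           clash_cap = 100, dielectric = "4r",
                           coulomb_rmin = 0.6, minimize_maxit = 60L,
                           minimize_tol = 1.0, seed = 1L) {
  stopifnot(grid_spacing > 0, rotation_count >= 1, poses_retained >= 1,
            clusters_per_probe >= 1, pose_cluster_cutoff > 0,
            cs_linkage_cutoff > 0, top_cs >= 1, nonbonded_cutoff > 0,
            clash_cap > 0, coulomb_rmin > 0, minimize_maxit >= 1)
  if (!identical(dielectric, "4r")) {
    stop("only the distance-dependent dielectric model '4r' is implemented")
  }
  structure(list(
    grid_spacing = grid_spacing, rotation_count = as.integer(rotation_count),
    poses_retained = as.integer(poses_retained),
    clusters_per_probe = as.integer(clusters_per_probe),
    pose_cluster_cutoff = pose_cluster_cutoff,
    cs_linkage_cutoff = cs_linkage_cutoff, top_cs = as.integer(top_cs),
    nonbonded_cutoff = nonbonded_cutoff, clash_cap = clash_cap,
    dielectric = dielectric, coulomb_rmin = coulomb_rmin,
    minimize_maxit = as.integer(minimize_maxit), minimize_tol = minimize_tol,
    seed = as.integer(seed)
  ), class = "ensmap_mapping_config")
}

# receptor heavy-atom coordinates and nonbonded parameters
receptor_params <- function(receptor) {
  a <- receptor$atoms[receptor$atoms$is_heavy, , drop = FALSE]
  if (!nrow(a)) stop("receptor has no heavy atoms")
  pars <- class_params(a$atom_class)
  list(xyz = as.matrix(a[, c("x", "y", "z")]), sigma = pars$sigma,
       epsilon = pars$epsilon, charge = a$charge)
}

probe_params <- function(probe) {
  a <- probe$atoms[toupper(probe$atoms$element) != "H", , drop = FALSE]
  pars <- class_params(a$atom_class)
  list(body = as.matrix(a[, c("x", "y", "z")]), sigma = pars$sigma,
       epsilon = pars$epsilon, charge = a$charge, classes = a$atom_class)
}

#' Build energy grids for a receptor
#'
#' For every probe atom class one Lennard-Jones channel (value at a grid
#' point = sum over receptor heavy atoms of the capped, truncated 12-6 pair
#' energy for that class), plus one electrostatic channel holding the
#' distance-dependent-dielectric Coulomb potential per unit probe charge.
#' The box encloses all receptor heavy atoms with a margin equal to the
#' nonbonded cutoff, so any point outside the box is beyond the cutoff from
#' every atom and scores exactly zero.
#'
#' @param receptor an `ensmap_structure` with at least one heavy atom.
#' @param config a [mapping_config()].
#' @param channel_classes atom classes to build channels for (default: the
#'   classes used by the default probe library).
#' @return object of class `ensmap_grid`.
#' @export
build_energy_grids <- function(receptor, config = mapping_config(),
                               channel_classes = NULL) {
  rp <- receptor_params(receptor)
  if (is.null(channel_classes)) {
    channel_classes <- sort(unique(unlist(lapply(default_probe_library(),
      function(p) p$atoms$atom_class))))
  }
  cpar <- class_params(channel_classes)
  lo <- apply(rp$xyz, 2, min) - config$nonbonded_cutoff
  hi <- apply(rp$xyz, 2, max) + config$nonbonded_cutoff
  dims <- as.integer(floor((hi - lo) / config$grid_spacing)) + 2L
  npts <- prod(as.numeric(dims))
  if (npts * (length(channel_classes) + 1) > 2.5e8) {
    stop(sprintf("grid too large: %d x %d x %d points x %d channels",
                 dims[1], dims[2], dims[3], length(channel_classes) + 1))
  }
  grids <- cpp_build_grids(rp$xyz, rp$sigma, rp$epsilon, rp$charge,
                           lo, config$grid_spacing, dims,
                           cpar$sigma, cpar$epsilon,
                           config$nonbonded_cutoff, config$clash_cap,
                           config$coulomb_rmin)
  names(grids) <- c(channel_classes, "elec")
  structure(list(origin = lo, spacing = config$grid_spacing, dims = dims,
                 channels = grids, channel_classes = channel_classes,
                 config = config),
            class = "ensmap_grid")
}

#' @export
print.ensmap_grid <- function(x, ...) {
  cat(sprintf("<ensmap_grid> %d x %d x %d @ %.2f A, channels: %s + elec\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(x$channel_classes, collapse = ", ")))
  invisible(x)
}

# atom coordinates of a probe in a given pose (quaternion + translation)
pose_atom_coords <- function(probe, pose) {
  R <- quat_to_mat(c(pose$qw, pose$qx, pose$qy, pose$qz))
  pp <- probe_params(probe)
  sweep(pp$body %*% t(R), 2, c(pose$tx, pose$ty, pose$tz), "+")
}

#' Direct (non-grid) interaction energy of a pose
#'
#' Exact pairwise sum over probe heavy atoms x receptor heavy atoms of the
#' truncated, capped Lennard-Jones term plus the distance-dependent-dielectric
#' Coulomb term - the reference the grid approximation is checked against.
#'
#' @param receptor an `ensmap_structure`.
#' @param pose one-row pose data.frame (columns `probe`, `qw`..`qz`,
#'   `tx`..`tz`).
#' @param config a [mapping_config()].
#' @param probes probe library (default [default_probe_library()]).
#' @return energy in kJ/mol.
#' @export
pose_energy <- function(receptor, pose, config = mapping_config(),
                        probes = default_probe_library()) {
  probe <- probes[[pose$probe]]
  if (is.null(probe)) stop("unknown probe: ", pose$probe)
  pp <- probe_params(probe)
  rp <- receptor_params(receptor)
  xyz <- pose_atom_coords(probe, pose)
  cpp_pose_energy(xyz, pp$sigma, pp$epsilon, pp$charge,
                  rp$xyz, rp$sigma, rp$epsilon, rp$charge,
                  config$nonbonded_cutoff, config$clash_cap,
                  config$coulomb_rmin)
}

#' Grid-interpolated energy of a pose
#'
#' Scores a pose by trilinear interpolation of the precomputed channels, the
#' same quantity the exhaustive sampler optimizes. Used to audit the grid
#' approximation against [pose_energy()].
#'
#' @param grids an `ensmap_grid`.
#' @param pose one-row pose data.frame.
#' @param probes probe library.
#' @return energy in kJ/mol.
#' @export
grid_pose_energy <- function(grids, pose, probes = default_probe_library()) {
  probe <- probes[[pose$probe]]
  pp <- probe_params(probe)
  xyz <- pose_atom_coords(probe, pose)
  e <- 0
  for (i in seq_len(nrow(xyz))) {
    ch <- grids$channels[[pp$classes[i]]]
    e <- e + cpp_interp(ch, grids$dims, grids$origin, grids$spacing,
                        xyz[i, , drop = FALSE])
    if (pp$charge[i] != 0) {
      e <- e + pp$charge[i] * cpp_interp(grids$channels[["elec"]], grids$dims,
                                         grids$origin, grids$spacing,
                                         xyz[i, , drop = FALSE])
    }
  }
  e
}

#' Exhaustively sample probe poses on the energy grids
#'
#' Scores every orientation of the deterministic rotation set at every grid
#' translation (probe centroid on grid points) by summing interpolated
#' channel values over probe atoms, and returns the `poses_retained`
#' lowest-energy poses sorted ascending by energy (ties broken by rotation
#' index then grid index).
#'
#' @param grids an `ensmap_grid`.
#' @param probe an `ensmap_probe`.
#' @param config a [mapping_config()].
#' @return pose data.frame with columns `probe`, `qw`, `qx`, `qy`, `qz`,
#'   `tx`, `ty`, `tz`, `energy`, `rotation_index`, `grid_index`.
#' @export
sample_poses <- function(grids, probe, config = mapping_config()) {
  pp <- probe_params(probe)
  chanidx <- match(pp$classes, grids$channel_classes)
  if (anyNA(chanidx)) {
    stop("grid lacks channels for probe classes: ",
         paste(unique(pp$classes[is.na(chanidx)]), collapse = ", "))
  }
  quats <- rotation_set(config$rotation_count, offset = config$seed)
  rot <- apply(quats, 1, function(q) as.vector(quat_to_mat(q)))
  res <- cpp_sample_poses(grids$channels, grids$dims, grids$origin,
                          grids$spacing, pp$body, chanidx - 1L, pp$charge,
                          rot, config$poses_retained)
  ri <- as.integer(res[, 1])
  gi <- res[, 2] - 1  # 0-based linear grid index
  nx <- grids$dims[1]; ny <- grids$dims[2]
  ix <- gi %% nx
  iy <- (gi %/% nx) %% ny
  iz <- gi %/% (nx * ny)
  data.frame(
    probe = probe$name,
    qw = quats[ri, 1], qx = quats[ri, 2], qy = quats[ri, 3], qz = quats[ri, 4],
    tx = grids$origin[1] + ix * grids$spacing,
    ty = grids$origin[2] + iy * grids$spacing,
    tz = grids$origin[3] + iz * grids$spacing,
    energy = res[, 3],
    rotation_index = ri,
    grid_index = as.integer(res[, 2]),
    stringsAsFactors = FALSE
  )
}

# batch rigid-body minimization of poses against the direct pairwise energy
minimize_poses <- function(receptor, poses, config = mapping_config(),
                           probes = default_probe_library()) {
  if (!nrow(poses)) return(poses)
  probe <- probes[[poses$probe[1]]]
  pp <- probe_params(probe)
  rp <- receptor_params(receptor)
  R0 <- t(apply(poses, 1, function(r) {
    as.vector(quat_to_mat(as.numeric(r[c("qw", "qx", "qy", "qz")])))
  }))
  t0 <- as.matrix(poses[, c("tx", "ty", "tz")])
  out <- cpp_minimize_poses(pp$body, pp$sigma, pp$epsilon, pp$charge,
                            rp$xyz, rp$sigma, rp$epsilon, rp$charge,
                            R0, t0, config$nonbonded_cutoff, config$clash_cap,
                            config$coulomb_rmin, config$minimize_maxit,
                            config$minimize_tol)
  for (i in seq_len(nrow(poses))) {
    q <- mat_to_quat(matrix(out[i, 1:9], 3, 3))
    poses$qw[i] <- q[1]; poses$qx[i] <- q[2]
    poses$qy[i] <- q[3]; poses$qz[i] <- q[4]
  }
  poses$tx <- out[, 10]; poses$ty <- out[, 11]; poses$tz <- out[, 12]
  poses$energy <- out[, 13]
  poses$converged <- out[, 14] == 1
  poses
}

#' Locally minimize a single pose (rigid body, 6 degrees of freedom)
#'
#' Steepest descent with backtracking line search on the direct pairwise
#' energy; monotone, so the returned energy never exceeds the input energy.
#' Non-convergence within the iteration budget returns the best pose found,
#' flagged `converged = FALSE`.
#'
#' @param receptor an `ensmap_structure`.
#' @param pose one-row pose data.frame.
#' @param config a [mapping_config()].
#' @param probes probe library.
#' @return the updated one-row pose data.frame with a `converged` column.
#' @export
minimize_pose <- function(receptor, pose, config = mapping_config(),
                          probes = default_probe_library()) {
  minimize_poses(receptor, pose, config, probes)
}

#' Greedy energy-ordered clustering of probe poses
#'
#' The lowest-energy unassigned pose seeds a cluster; every unassigned pose
#' whose probe heavy-atom RMSD to the seed (computed in the receptor frame,
#' without re-superposition) is within `pose_cluster_cutoff` joins; repeat
#' until all poses are assigned. The `clusters_per_probe` clusters with the
#' lowest mean interaction energy are retained.
#'
#' @param poses pose data.frame for a single probe type.
#' @param config a [mapping_config()].
#' @param probes probe library.
#' @return list of pose clusters, each
#'   `list(probe, poses, center, mean_energy, centroid)`; the center is the
#'   lowest-energy member and `centroid` its probe centroid position.
#' @export
cluster_poses <- function(poses, config = mapping_config(),
                          probes = default_probe_library()) {
  if (!nrow(poses)) return(list())
  if (length(unique(poses$probe)) != 1) {
    stop("cluster_poses expects poses of a single probe type")
  }
  poses <- poses[order(poses$energy), , drop = FALSE]
  probe <- probes[[poses$probe[1]]]
  n <- nrow(poses)
  natom <- sum(toupper(probe$atoms$element) != "H")
  # flattened per-pose atom coordinates (n x 3*natom)
  AC <- t(vapply(seq_len(n), function(i) {
    as.vector(pose_atom_coords(probe, poses[i, ]))
  }, numeric(3 * natom)))
  assigned <- rep(FALSE, n)
  clusters <- list()
  cut2 <- config$pose_cluster_cutoff^2
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    d2 <- rowSums((AC - matrix(AC[seed, ], n, ncol(AC), byrow = TRUE))^2) / natom
    members <- which(!assigned & d2 <= cut2)
    assigned[members] <- TRUE
    mem <- poses[members, , drop = FALSE]
    clusters[[length(clusters) + 1]] <- structure(list(
      probe = probe$name,
      poses = mem,
      center = mem[1, , drop = FALSE],
      mean_energy = mean(mem$energy),
      centroid = as.numeric(mem[1, c("tx", "ty", "tz")])
    ), class = "ensmap_pose_cluster")
  }
  me <- vapply(clusters, `[[`, numeric(1), "mean_energy")
  clusters <- clusters[order(me)]
  clusters[seq_len(min(config$clusters_per_probe, length(clusters)))]
}

#' Aggregate probe pose clusters into ranked consensus sites
#'
#' Single-linkage clustering of pose-cluster centers (distance between the
#' centroid positions of the cluster-center poses) at `cs_linkage_cutoff`.
#' Consensus sites are ranked by the number of probe clusters they
#' incorporate (ties: lower mean of member cluster mean energies, then the
#' lexicographically first member probe name); the `top_cs` largest are kept.
#'
#' @param clusters list of pose clusters pooled over all probe types.
#' @param config a [mapping_config()].
#' @return list of consensus sites, each `list(rank, clusters, size,
#'   center_of_mass, mean_energy)`.
#' @export
build_consensus_sites <- function(clusters, config = mapping_config()) {
  if (!length(clusters)) return(list())
  centers <- t(vapply(clusters, `[[`, numeric(3), "centroid"))
  if (length(clusters) == 1) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(centers), method = "single")
    memb <- stats::cutree(hc, h = config$cs_linkage_cutoff)
  }
  sites <- lapply(unique(memb), function(g) {
    idx <- which(memb == g)
    cl <- clusters[idx]
    me <- vapply(cl, `[[`, numeric(1), "mean_energy")
    list(
      clusters = cl,
      size = length(cl),
      center_of_mass = colMeans(centers[idx, , drop = FALSE]),
      mean_energy = mean(me),
      first_probe = sort(vapply(cl, `[[`, character(1), "probe"))[1]
    )
  })
  sizes <- vapply(sites, `[[`, numeric(1), "size")
  menergy <- vapply(sites, `[[`, numeric(1), "mean_energy")
  fp <- vapply(sites, `[[`, character(1), "first_probe")
  ord <- order(-sizes, menergy, fp)
  sites <- sites[ord][seq_len(min(config$top_cs, length(sites)))]
  for (i in seq_along(sites)) sites[[i]]$rank <- i
  lapply(sites, function(s) {
    structure(s[c("rank", "clusters", "size", "center_of_mass",
                  "mean_energy")], class = "ensmap_consensus_site")
  })
}

#' @export
print.ensmap_consensus_site <- function(x, ...) {
  cat(sprintf("<CS%d> %d probe clusters, mean energy %.1f kJ/mol, center (%.1f, %.1f, %.1f)\n",
              x$rank, x$size, x$mean_energy, x$center_of_mass[1],
              x$center_of_mass[2], x$center_of_mass[3]))
  invisible(x)
}

#' Map a single receptor structure
#'
#' End-to-end single-structure mapping: energy grids, exhaustive pose
#' sampling, pose minimization and greedy clustering per probe, then
#' consensus-site construction across probes. Deterministic for a fixed
#' configuration.
#'
#' @param receptor an `ensmap_structure`.
#' @param config a [mapping_config()].
#' @param probes probe library (default all 16).
#' @return object of class `ensmap_mapping`: list with `sites` (ranked
#'   consensus sites), `probe_clusters` (retained pose clusters per probe),
#'   and `config`.
#' @export
map_structure <- function(receptor, config = mapping_config(),
                          probes = default_probe_library()) {
  grids <- build_energy_grids(receptor, config,
                              channel_classes = sort(unique(unlist(
                                lapply(probes, function(p) p$atoms$atom_class)))))
  probe_clusters <- list()
  for (pn in names(probes)) {
    poses <- sample_poses(grids, probes[[pn]], config)
    poses <- minimize_poses(receptor, poses, config, probes)
    poses <- poses[order(poses$energy), , drop = FALSE]
    probe_clusters[[pn]] <- cluster_poses(poses, config, probes)
  }
  sites <- build_consensus_sites(unlist(probe_clusters, recursive = FALSE,
                                        use.names = FALSE), config)
  structure(list(sites = sites, probe_clusters = probe_clusters,
                 config = config),
            class = "ensmap_mapping")
}

#' @export
print.ensmap_mapping <- function(x, ...) {
  cat(sprintf("<ensmap_mapping> %d consensus sites from %d probe types\n",
              length(x$sites), length(x$probe_clusters)))
  for (s in x$sites) print(s)
  invisible(x)
}

#' Consensus-site summary table
#'
#' @param mapping an `ensmap_mapping`.
#' @return data.frame with one row per consensus site: rank, size, member
#'   probe types, mean energy and center coordinates.
#' @export
consensus_site_table <- function(mapping) {
  if (!length(mapping$sites)) {
    return(data.frame(rank = integer(0), size = integer(0), probes = character(0),
                      mean_energy = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  do.call(rbind, lapply(mapping$sites, function(s) {
    data.frame(
      rank = s$rank, size = s$size,
      probes = paste(sort(unique(vapply(s$clusters, `[[`, character(1),
                                        "probe"))), collapse = ","),
      mean_energy = s$mean_energy,
      x = s$center_of_mass[1], y = s$center_of_mass[2], z = s$center_of_mass[3],
      stringsAsFactors = FALSE
    )
  }))
}
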