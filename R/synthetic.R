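# Synthetic pseudo-receptor ensembles with planted, ground-truth-labelled
# orthosteric and (transiently open) allosteric pockets. These stand in for
# MD-derived receptor ensembles so the whole pipeline is testable end to end.

#' Specification for a synthetic pseudo-receptor ensemble
#'
#' The receptor is a bundle of `n_helices` ideal helices of pseudo-residues
#' (one backbone `CA` bead plus one sidechain `CB` bead per residue) around a
#' central "orthosteric" lumen holding a rigid reference ligand. Two adjacent
#' helices carry an apolar-lined interface that is sealed in the base
#' conformation; in a `pocket_open_fraction` of the models the pair breathes
#' outward by `breathing_amplitude`, opening a lateral surface groove (the
#' planted allosteric pocket). Each model additionally receives isotropic
#' Gaussian coordinate jitter (`jitter_sigma`) and, if `global_motion`, a
#' random rigid-body rotation + translation.
#'
#' @param n_helices number of helices (default 7, a GPCR-like bundle).
#' @param residues_per_helix residues per helix (default 18).
#' @param bundle_radius distance of each helix axis from the bundle axis, in
#'   Angstrom (default 13.7; small enough to seal inter-helix seams, large
#'   enough to keep all nonbonded atoms >= 2.5 Apart).
#' @param pocket_open_fraction fraction of models with the groove open
#'   (default 0.4).
#' @param breathing_amplitude outward displacement of the two groove helices
#'   in open models, Angstrom (default 6).
#' @param jitter_sigma per-coordinate Gaussian jitter, Angstrom (default 0.05).
#' @param global_motion apply a random rigid-body displacement per model.
#' @param n_models number of conformers (default 24).
#' @param seed RNG seed; the full generation is reproducible bit-for-bit.
#' @return object of class `ensmap_synthetic_spec`.
#' @export
synthetic_spec <- function(n_helices = 7L, residues_per_helix = 18L,
                           bundle_radius = 13.7, pocket_open_fraction = 0.4,
                           breathing_amplitude = 6.0, jitter_sigma = 0.05,
                           global_motion = TRUE, n_models = 24L, seed = 1L) {
  stopifnot(n_helices >= 3L, residues_per_helix >= 4L, bundle_radius > 0,
            pocket_open_fraction >= 0, pocket_open_fraction <= 1,
            breathing_amplitude >= 0, jitter_sigma >= 0, n_models >= 1L)
  structure(list(
    n_helices = as.integer(n_helices),
    residues_per_helix = as.integer(residues_per_helix),
    bundle_radius = bundle_radius,
    pocket_open_fraction = pocket_open_fraction,
    breathing_amplitude = breathing_amplitude,
    jitter_sigma = jitter_sigma,
    global_motion = isTRUE(global_motion),
    n_models = as.integer(n_models),
    seed = as.integer(seed)
  ), class = "ensmap_synthetic_spec")
}

# fixed helix geometry constants (Angstrom / degrees)
.helix_radius <- 2.0     # CA distance from the helix axis
.helix_rise <- 1.5       # rise per residue
.helix_twist <- 100      # twist per residue, degrees
.bead_length <- 2.6     # CA -> CB bond length (> min nonbonded distance)
.groove_helices <- c(1L, 2L)
.groove_face_cos <- cos(60 * pi / 180)  # cone half-angle for "facing" beads
.groove_gate_cos <- cos(105 * pi / 180)  # outer bound of the gatekeeper shell
.gate_bead_length <- 3.6  # longer flanking beads narrow the open groove mouth
.pocket_label_radius <- 5.0  # heavy atoms within this of the pocket hot region line it
.orthosteric_label_radius <- 5.0  # matches the default orthosteric_radius
.ligand_ring_radius <- 5.4
.ligand_ring_atoms <- 10L

# bead class palette repeated along each helix: mixture of apolar, polar and
# oppositely charged sidechain beads
.bead_palette <- c("BAP", "BPO", "BAP", "BCP", "BAP", "BPO", "BAP", "BCM")

# helix axis center (xy) for helix h
helix_center <- function(h, n_helices, bundle_radius) {
  phi <- 2 * pi * (h - 1) / n_helices
  bundle_radius * c(cos(phi), sin(phi))
}

# base (closed) receptor geometry; returns atoms table plus per-atom helix id
build_base_geometry <- function(spec) {
  H <- spec$n_helices
  nres <- spec$residues_per_helix
  z0 <- -(nres - 1) * .helix_rise / 2
  rows <- vector("list", H * nres)
  helix_of_res <- integer(H * nres)
  # groove pair and the direction from each groove helix toward its partner
  g <- .groove_helices
  cg <- lapply(g, helix_center, n_helices = H, bundle_radius = spec$bundle_radius)
  res_global <- 0L
  for (h in seq_len(H)) {
    c_h <- helix_center(h, H, spec$bundle_radius)
    phi0 <- atan2(c_h[2], c_h[1])
    for (r in seq_len(nres)) {
      res_global <- res_global + 1L
      helix_of_res[res_global] <- h
      alpha <- phi0 + pi + (r - 1) * .helix_twist * pi / 180
      u <- c(cos(alpha), sin(alpha))
      z <- z0 + (r - 1) * .helix_rise
      ca <- c(c_h + .helix_radius * u, z)
      resname <- .bead_palette[(r - 1) %% length(.bead_palette) + 1]
      if (r <= 2 || r >= nres - 1) resname <- "BTM"
      # Helix termini carry polar end caps (deep wells: termini and loop
      # anchors are probe magnets on real receptors, and they keep the
      # sealed receptor busy binding probes at genuine generic sites). On
      # the groove pair, beads facing the partner helix are the strongly
      # dispersive pocket lining; the flanking "gatekeeper" beads are
      # longer and bulky (large sigma), plugging the outer seam crevices
      # while sealed and walling the groove into a slot once the pair
      # breathes open.
      blen <- .bead_length
      if (h %in% g) {
        other <- cg[[which(g != h)]]
        d_other <- other - c_h
        d_other <- d_other / sqrt(sum(d_other^2))
        mid <- r > 2 && r < nres - 1  # everywhere between the end caps
        facing <- sum(u * d_other)
        if (mid && facing > .groove_face_cos) {
          resname <- "BGR"
        } else if (mid && facing > .groove_gate_cos) {
          resname <- "BGK"
          blen <- .gate_bead_length
        }
      }
      cb <- c(c_h + (.helix_radius + blen) * u, z)
      rows[[res_global]] <- data.frame(
        name = c("CA", "CB"), element = c("C", "C"),
        resname = resname, resid = res_global, chain = "A", ins = "",
        x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3]),
        stringsAsFactors = FALSE
      )
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  list(atoms = atoms, helix_of_res = helix_of_res)
}

# rigid reference ligand: ring of carbons plus a central oxygen, in the lumen
build_ligand <- function() {
  k <- seq_len(.ligand_ring_atoms)
  ang <- 2 * pi * (k - 1) / .ligand_ring_atoms
  atoms <- data.frame(
    serial = c(k, .ligand_ring_atoms + 1L),
    name = c(sprintf("C%d", k), "O1"),
    element = c(rep("C", .ligand_ring_atoms), "O"),
    resname = "LIG", resid = 1L, chain = "L", ins = "",
    x = c(.ligand_ring_radius * cos(ang), 0),
    y = c(.ligand_ring_radius * sin(ang), 0),
    z = c(rep(0, .ligand_ring_atoms), 0),
    record = "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

# outward bisector of the groove pair and displaced coordinates for a model
groove_displacement <- function(spec) {
  g <- .groove_helices
  c1 <- helix_center(g[1], spec$n_helices, spec$bundle_radius)
  c2 <- helix_center(g[2], spec$n_helices, spec$bundle_radius)
  d <- (c1 + c2) / 2
  d / sqrt(sum(d^2))
}

apply_breathing <- function(xyz, helix_of_atom, spec) {
  d <- groove_displacement(spec)
  sel <- helix_of_atom %in% .groove_helices
  xyz[sel, 1] <- xyz[sel, 1] + spec$breathing_amplitude * d[1]
  xyz[sel, 2] <- xyz[sel, 2] + spec$breathing_amplitude * d[2]
  xyz
}

# Planted pocket, located energetically: within the seam wedge vacated by the
# displaced helix pair, score every point of a coarse lattice with a single
# apolar-bead probe (Lennard-Jones sum over the open-state receptor) and keep
# the minimum as the pocket center plus all points within 70% of that minimum
# as the pocket's hot region. Deterministic; geometry + energy model only.
find_groove_pocket <- function(structure_open, spec) {
  xyz_open <- coords(structure_open, heavy_only = TRUE)
  a <- structure_open$atoms[structure_open$atoms$is_heavy, , drop = FALSE]
  pars <- class_params(a$atom_class)
  probe <- class_params("C.al")
  sig <- (pars$sigma + probe$sigma) / 2
  eps <- sqrt(pars$epsilon * probe$epsilon)

  H <- spec$n_helices
  phi1 <- 2 * pi * (.groove_helices[1] - 1) / H
  dphi <- 2 * pi / H
  rad_lo <- spec$bundle_radius - 3
  rad_hi <- spec$bundle_radius + spec$breathing_amplitude + 3
  zmax <- (spec$residues_per_helix - 1) * .helix_rise / 2 - 2

  gx <- seq(-rad_hi, rad_hi, by = 0.75)
  pts <- as.matrix(expand.grid(x = gx, y = gx, z = seq(-zmax, zmax, by = 0.75)))
  rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ang <- (atan2(pts[, 2], pts[, 1]) - phi1) %% (2 * pi)
  keep <- rad >= rad_lo & rad <= rad_hi & ang >= 0 & ang <= dphi
  pts <- pts[keep, , drop = FALSE]

  e <- vapply(seq_len(nrow(pts)), function(i) {
    r <- sqrt((xyz_open[, 1] - pts[i, 1])^2 + (xyz_open[, 2] - pts[i, 2])^2 +
              (xyz_open[, 3] - pts[i, 3])^2)
    in_rng <- r <= 8
    s6 <- (sig[in_rng] / r[in_rng])^6
    sum(pmin(4 * eps[in_rng] * (s6 * s6 - s6), 100))
  }, numeric(1))
  emin <- min(e)
  if (emin >= 0) stop("planted groove has no attractive pocket; spec infeasible")
  hot <- pts[e <= 0.7 * emin, , drop = FALSE]
  list(center = pts[which.min(e), ], hot_points = hot, min_energy = emin)
}

#' Generate the base synthetic receptor with ground-truth labels
#'
#' Builds the closed (groove sealed) conformation, the reference ligand in the
#' central lumen, and ground-truth residue labels: orthosteric residues have a
#' heavy atom within 5 Angstrom of the ligand; allosteric residues have a
#' heavy atom within 7 Angstrom of the planted groove center in the *open*
#' conformation (and are never also orthosteric). Deterministic: no RNG used.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `structure` (closed receptor, `ensmap_structure`),
#'   `ligand` (`ensmap_structure`), `truth` (ground-truth list with
#'   `orthosteric_residues`, `allosteric_residues`, `allosteric_center`,
#'   `open_models`), and `helix_of_res`.
#' @export
generate_receptor <- function(spec = synthetic_spec()) {
  geom <- build_base_geometry(spec)
  receptor <- new_structure(geom$atoms)
  xyz <- coords(receptor)
  dmin <- min(dist(xyz))
  if (dmin < 2.5) {
    stop(sprintf(paste0("geometrically infeasible spec: minimal inter-atomic",
                        " distance %.2f A < 2.5 A (bundle_radius too small)"),
                 dmin))
  }
  ligand <- build_ligand()

  ridx <- residue_index(receptor)
  keys_per_atom <- residue_keys(receptor)
  # orthosteric: any heavy atom within the labelling radius of any ligand atom
  lxyz <- coords(ligand, heavy_only = TRUE)
  min_d_lig <- apply(xyz, 1, function(p) {
    sqrt(min((lxyz[, 1] - p[1])^2 + (lxyz[, 2] - p[2])^2 + (lxyz[, 3] - p[3])^2))
  })
  ortho <- unique(keys_per_atom[min_d_lig <= .orthosteric_label_radius])

  # allosteric: lining of the open groove's hot region
  helix_of_atom <- rep(geom$helix_of_res, each = 2L)
  xyz_open <- apply_breathing(xyz, helix_of_atom, spec)
  pocket <- find_groove_pocket(set_coords(receptor, xyz_open), spec)
  center <- pocket$center
  min_d_poc <- apply(xyz_open, 1, function(p) {
    sqrt(min((pocket$hot_points[, 1] - p[1])^2 +
             (pocket$hot_points[, 2] - p[2])^2 +
             (pocket$hot_points[, 3] - p[3])^2))
  })
  allo <- setdiff(unique(keys_per_atom[min_d_poc <= .pocket_label_radius]), ortho)

  truth <- list(
    orthosteric_residues = ortho,
    allosteric_residues = allo,
    allosteric_center = center,
    open_models = integer(0)
  )
  list(structure = receptor, ligand = ligand, truth = truth,
       helix_of_res = geom$helix_of_res, spec = spec)
}

# random unit quaternion -> rotation matrix (for the global rigid motion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_mat(q)
}

#' Generate a synthetic conformer ensemble
#'
#' Derives `n_models` conformers from the base receptor. Models selected as
#' "open" (a seeded draw of `round(pocket_open_fraction * n_models)` models)
#' receive the outward breathing displacement of the two groove helices; all
#' models then receive Gaussian jitter and, optionally, a random rigid-body
#' displacement (applied last, so superposition removes it exactly).
#' Per-model randomness is seeded with `seed + model_id`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ensemble` (`ensmap_ensemble`), `truth` (ground truth,
#'   including `open_models`), `base` (closed receptor), `ligand`, `spec`.
#' @export
generate_ensemble <- function(spec = synthetic_spec()) {
  base <- generate_receptor(spec)
  xyz0 <- coords(base$structure)
  helix_of_atom <- rep(base$helix_of_res, each = 2L)
  n <- spec$n_models
  k <- round(spec$pocket_open_fraction * n)
  set.seed(spec$seed)
  open_models <- if (k > 0) sort(sample.int(n, k)) else integer(0)

  models <- vector("list", n)
  for (m in seq_len(n)) {
    xyz <- xyz0
    if (m %in% open_models) xyz <- apply_breathing(xyz, helix_of_atom, spec)
    set.seed(spec$seed + m)
    if (spec$jitter_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sigma),
                          ncol = 3)
    }
    if (spec$global_motion) {
      R <- random_rotation()
      shift <- stats::runif(3, -4, 4)
      xyz <- xyz %*% t(R)
      xyz <- sweep(xyz, 2, shift, "+")
    }
    st <- set_coords(base$structure, xyz)
    st$model_id <- m
    models[[m]] <- st
  }
  ens <- new_ensemble(models)
  truth <- base$truth
  truth$open_models <- open_models
  list(ensemble = ens, truth = truth, base = base$structure,
       ligand = base$ligand, spec = spec)
}
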