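# Small programmatic fixtures shared across the suite.

# toy structure with arbitrary coordinates; one CA + optional CB per residue
toy_structure <- function(xyz, names = NULL, resid = NULL, chain = "A",
                          element = "C", classes = NULL) {
  n <- nrow(xyz)
  if (is.null(names)) names <- rep("CA", n)
  if (is.null(resid)) resid <- seq_len(n)
  atoms <- data.frame(
    serial = seq_len(n), name = names, element = rep(element, length.out = n),
    resname = "GLY", resid = resid, chain = chain, ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  if (!is.null(classes)) atoms$atom_class <- classes
  new_structure(atoms)
}

# a single-atom receptor of a given class at the origin
point_receptor <- function(class = "C.al", charge = 0, pos = c(0, 0, 0)) {
  atoms <- data.frame(
    serial = 1L, name = "X1", element = "C", resname = "XXX", resid = 1L,
    chain = "A", ins = "", x = pos[1], y = pos[2], z = pos[3],
    atom_class = class, charge = charge, stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

# a rigid single-atom probe of a given class (built with package internals
# only through the public pose interface: plain list mimicking ensmap_probe)
point_probe <- function(class = "C.al", charge = 0, name = "unit") {
  atoms <- data.frame(name = "X1", element = "C", x = 0, y = 0, z = 0,
                      atom_class = class, charge = charge,
                      stringsAsFactors = FALSE)
  structure(list(name = name, code = "UNI", atoms = atoms,
                 net_charge = charge), class = "ensmap_probe")
}

# identity pose at a translation
pose_at <- function(t, probe = "unit", energy = NA_real_) {
  data.frame(probe = probe, qw = 1, qx = 0, qy = 0, qz = 0,
             tx = t[1], ty = t[2], tz = t[3], energy = energy,
             stringsAsFactors = FALSE)
}

# small, fast synthetic spec (feasible geometry, no groove ambitions)
tiny_spec <- function(n_models = 6L, ...) {
  synthetic_spec(n_helices = 5L, residues_per_helix = 8L,
                 n_models = n_models, ...)
}

# coarse mapping config for fast tests
tiny_mapping_config <- function(poses_retained = 150L, ...) {
  mapping_config(grid_spacing = 1.2, rotation_count = 20L,
                 poses_retained = poses_retained, minimize_maxit = 20L, ...)
}
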