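# The 16-member rigid organic probe library. Geometries are idealized
# heavy-atom-only rigid bodies built from standard bond lengths and angles;
# hydrogens are folded into their heavy atoms (united-atom convention), and
# partial charges are simple dipole assignments that sum to the (zero) net
# charge of each neutral fragment.

probe_atom <- function(name, element, x, y, z, class, q) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             atom_class = class, charge = q, stringsAsFactors = FALSE)
}

# tetrahedral unit directions
.tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# regular hexagon of aromatic carbons in the xy plane, C1 on +x
ring6 <- function(r = 1.40) {
  ang <- 2 * pi * (0:5) / 6
  cbind(r * cos(ang), r * sin(ang), 0)
}

# direction making the tetrahedral angle with -v, tilted toward perp
bond_dir <- function(v, perp) {
  v <- v / sqrt(sum(v^2))
  p <- perp - sum(perp * v) * v
  p <- p / sqrt(sum(p^2))
  (-v) * (-1 / 3) + p * sqrt(8) / 3
}

build_probe <- function(name, code, atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  atoms$x <- atoms$x - ctr[1]
  atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  structure(list(name = name, code = code, atoms = atoms,
                 net_charge = sum(atoms$charge)),
            class = "ensmap_probe")
}

#' @export
print.ensmap_probe <- function(x, ...) {
  cat(sprintf("<probe %s (%s)> %d heavy atoms, net charge %+.2f\n",
              x$name, x$code, nrow(x$atoms), x$net_charge))
  invisible(x)
}

#' The default 16-probe fragment library
#'
#' Sixteen small organic probe molecules spanning a range of hydrophobicity
#' and hydrogen-bonding character: ethanol, isopropanol, isobutanol, acetone,
#' acetaldehyde, dimethyl ether, cyclohexane, ethane, acetonitrile, urea,
#' methylamine, phenol, benzaldehyde, benzene, acetamide and
#' N,N-dimethylformamide. Each probe is a rigid heavy-atom body with its
#' centroid at the origin, per-atom nonbonded classes and partial charges.
#'
#' @return named list of 16 `ensmap_probe` objects.
#' @export
default_probe_library <- function() {
  p <- list()

  p$ethane <- build_probe("ethane", "ETH", rbind(
    probe_atom("C1", "C", -0.77, 0, 0, "C.al", 0),
    probe_atom("C2", "C", 0.77, 0, 0, "C.al", 0)))

  # ethanol: C1(methyl)-C2-O, tetrahedral angle at C2
  o_dir <- c(cos(109.47 * pi / 180), sin(109.47 * pi / 180), 0)
  p$ethanol <- build_probe("ethanol", "EOH", rbind(
    probe_atom("C1", "C", 1.53, 0, 0, "C.al", 0),
    probe_atom("C2", "C", 0, 0, 0, "C.al", 0.20),
    probe_atom("O1", "O", 1.43 * o_dir[1], 1.43 * o_dir[2], 0, "O.hy", -0.20)))

  t <- 1.53 * .tet
  p$isopropanol <- build_probe("isopropanol", "IPA", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.al", 0.20),
    probe_atom("C2", "C", t[1, 1], t[1, 2], t[1, 3], "C.al", 0),
    probe_atom("C3", "C", t[2, 1], t[2, 2], t[2, 3], "C.al", 0),
    probe_atom("O1", "O", 1.43 * .tet[3, 1], 1.43 * .tet[3, 2],
               1.43 * .tet[3, 3], "O.hy", -0.20)))

  # isobutanol: (CH3)2-CH-CH2-OH
  c3 <- 1.53 * .tet[3, ]
  od <- bond_dir(-.tet[3, ], .tet[1, ])
  p$isobutanol <- build_probe("isobutanol", "IBU", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.al", 0),
    probe_atom("C2", "C", t[1, 1], t[1, 2], t[1, 3], "C.al", 0),
    probe_atom("C3", "C", t[2, 1], t[2, 2], t[2, 3], "C.al", 0),
    probe_atom("C4", "C", c3[1], c3[2], c3[3], "C.al", 0.20),
    probe_atom("O1", "O", c3[1] + 1.43 * od[1], c3[2] + 1.43 * od[2],
               c3[3] + 1.43 * od[3], "O.hy", -0.20)))

  # trigonal carbonyl fragments: C=O along +y, substituents at +-120 degrees
  sub1 <- c(sin(pi / 3), -0.5, 0)
  sub2 <- c(-sin(pi / 3), -0.5, 0)
  p$acetone <- build_probe("acetone", "ACT", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.co", 0.45),
    probe_atom("O1", "O", 0, 1.22, 0, "O.ca", -0.45),
    probe_atom("C2", "C", 1.52 * sub1[1], 1.52 * sub1[2], 0, "C.al", 0),
    probe_atom("C3", "C", 1.52 * sub2[1], 1.52 * sub2[2], 0, "C.al", 0)))

  p$acetaldehyde <- build_probe("acetaldehyde", "AAL", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.co", 0.45),
    probe_atom("O1", "O", 0, 1.22, 0, "O.ca", -0.45),
    probe_atom("C2", "C", 1.52 * sub1[1], 1.52 * sub1[2], 0, "C.al", 0)))

  # dimethyl ether: C-O-C, 111 degree angle at O
  half <- 111 / 2 * pi / 180
  p$`dimethyl ether` <- build_probe("dimethyl ether", "DME", rbind(
    probe_atom("O1", "O", 0, 0, 0, "O.ca", -0.30),
    probe_atom("C1", "C", 1.41 * sin(half), -1.41 * cos(half), 0, "C.al", 0.15),
    probe_atom("C2", "C", -1.41 * sin(half), -1.41 * cos(half), 0, "C.al", 0.15)))

  # cyclohexane chair: alternating ring pucker
  ang <- 2 * pi * (0:5) / 6
  p$cyclohexane <- build_probe("cyclohexane", "CHX", do.call(rbind, lapply(1:6,
    function(k) probe_atom(sprintf("C%d", k), "C", 1.468 * cos(ang[k]),
                           1.468 * sin(ang[k]), 0.25 * (-1)^k, "C.al", 0))))

  p$acetonitrile <- build_probe("acetonitrile", "ACN", rbind(
    probe_atom("C1", "C", -1.46, 0, 0, "C.al", 0),
    probe_atom("C2", "C", 0, 0, 0, "C.co", 0.28),
    probe_atom("N1", "N", 1.16, 0, 0, "N.pl", -0.28)))

  p$urea <- build_probe("urea", "URE", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.co", 0.65),
    probe_atom("O1", "O", 0, 1.22, 0, "O.ca", -0.45),
    probe_atom("N1", "N", 1.38 * sub1[1], 1.38 * sub1[2], 0, "N.pl", -0.10),
    probe_atom("N2", "N", 1.38 * sub2[1], 1.38 * sub2[2], 0, "N.pl", -0.10)))

  p$methylamine <- build_probe("methylamine", "MAM", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.al", 0.25),
    probe_atom("N1", "N", 1.47, 0, 0, "N.pl", -0.25)))

  rg <- ring6()
  ring_atoms <- function(cls = "C.ar", q = 0) {
    do.call(rbind, lapply(1:6, function(k) {
      probe_atom(sprintf("C%d", k), "C", rg[k, 1], rg[k, 2], rg[k, 3], cls, q)
    }))
  }
  p$benzene <- build_probe("benzene", "BNZ", ring_atoms())

  ph <- ring_atoms()
  ph$charge[1] <- 0.20
  p$phenol <- build_probe("phenol", "PHN", rbind(
    ph, probe_atom("O1", "O", 1.40 + 1.36, 0, 0, "O.hy", -0.20)))

  bz <- ring_atoms()
  c7 <- c(1.40 + 1.48, 0, 0)
  p$benzaldehyde <- build_probe("benzaldehyde", "BZA", rbind(
    bz,
    probe_atom("C7", "C", c7[1], c7[2], c7[3], "C.co", 0.45),
    probe_atom("O1", "O", c7[1] + 1.22 * cos(pi / 3),
               c7[2] + 1.22 * sin(pi / 3), 0, "O.ca", -0.45)))

  p$acetamide <- build_probe("acetamide", "ACM", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.co", 0.60),
    probe_atom("O1", "O", 0, 1.22, 0, "O.ca", -0.45),
    probe_atom("N1", "N", 1.35 * sub1[1], 1.35 * sub1[2], 0, "N.pl", -0.30),
    probe_atom("C2", "C", 1.52 * sub2[1], 1.52 * sub2[2], 0, "C.al", 0.15)))

  # N,N-dimethylformamide: HC(=O)N(CH3)2
  nn <- 1.35 * sub1
  m1 <- nn + 1.45 * c(sin(pi / 3), 0.5, 0)
  m2 <- nn + 1.45 * c(0, -1, 0)
  p$`N,N-dimethylformamide` <- build_probe("N,N-dimethylformamide", "DMF", rbind(
    probe_atom("C1", "C", 0, 0, 0, "C.co", 0.45),
    probe_atom("O1", "O", 0, 1.22, 0, "O.ca", -0.45),
    probe_atom("N1", "N", nn[1], nn[2], 0, "N.pl", -0.30),
    probe_atom("C2", "C", m1[1], m1[2], 0, "C.al", 0.15),
    probe_atom("C3", "C", m2[1], m2[2], 0, "C.al", 0.15)))

  p
}
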