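#' Nonbonded atom-class parameter table
#'
#' Internal united-atom style parameter palette used by the energy model.
#' Each atom of a receptor or probe carries an `atom_class` that resolves to a
#' Lennard-Jones `sigma` (Angstrom), well depth `epsilon` (kJ/mol) and a
#' default partial charge (e). Hydrogens are folded into their heavy atoms
#' (united-atom convention), so only heavy-atom classes appear.
#'
#' Classes starting with `S.` are the pseudo-receptor sidechain bead classes
#' of the synthetic generator; `BB` is its backbone C-alpha bead.
#'
#' @return data.frame with columns `class`, `sigma`, `epsilon`, `charge`.
#' @export
atom_class_table <- function() {
  data.frame(
    class   = c("C.al", "C.ar", "C.co", "O.hy", "O.ca", "N.pl",
                "BB", "S.ap", "S.po", "S.cp", "S.cm", "S.tm", "S.gr", "S.gk", "H"),
    sigma   = c(3.75, 3.70, 3.55, 3.07, 2.96, 3.25,
                4.00, 4.20, 3.80, 3.90, 3.90, 3.80, 4.20, 4.20, 0.00),
    epsilon = c(0.45, 0.40, 0.30, 0.65, 0.75, 0.70,
                0.40, 0.60, 0.70, 0.70, 0.70, 1.00, 1.40, 0.60, 0.00),
    charge  = c(0, 0, 0, 0, 0, 0,
                0, 0, 0, 0.4, -0.4, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# resolve atom classes to (sigma, epsilon) vectors; unknown classes error
class_params <- function(classes) {
  tab <- atom_class_table()
  i <- match(classes, tab$class)
  if (anyNA(i)) {
    stop("unknown atom class(es): ", paste(unique(classes[is.na(i)]), collapse = ", "))
  }
  list(sigma = tab$sigma[i], epsilon = tab$epsilon[i], charge = tab$charge[i])
}

# Default class assignment for atoms read from PDB. The synthetic generator
# encodes the sidechain bead class in the residue name (BAP/BPO/BCP/BCM), so
# a write/read round-trip preserves nonbonded parameters; anything else falls
# back to an element-based rule.
bead_resname_class <- c(BAP = "S.ap", BPO = "S.po", BCP = "S.cp",
                        BCM = "S.cm", BTM = "S.tm", BGR = "S.gr",
                        BGK = "S.gk")

default_atom_class <- function(name, element, resname = NULL) {
  cls <- rep(NA_character_, length(name))
  if (!is.null(resname)) {
    is_bead <- resname %in% names(bead_resname_class) & name == "CB"
    cls[is_bead] <- bead_resname_class[resname[is_bead]]
  }
  todo <- is.na(cls)
  cls[todo] <- ifelse(name[todo] == "CA", "BB",
    ifelse(element[todo] == "C", "C.al",
      ifelse(element[todo] == "N", "N.pl",
        ifelse(element[todo] == "O", "O.ca",
          ifelse(element[todo] == "H", "H", "C.al")))))
  cls
}
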