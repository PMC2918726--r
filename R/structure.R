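#' @useDynLib ensmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats hclust cutree dist setNames
#' @importFrom utils head write.table
NULL

#' Construct a single-conformer structure
#'
#' A structure is an ordered atom table plus a residue index. Atom order is
#' significant and preserved by all I/O. Residues are keyed by
#' `(chain, residue number, insertion code)`; atom indices are 1-based.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `ins`, `x`, `y`, `z` and optionally
#'   `atom_class`, `charge`, `record`.
#' @param model_id integer model identifier (1-based position in an ensemble).
#' @return object of class `ensmap_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  req <- c("serial", "name", "element", "resname", "resid", "chain", "ins",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(atoms$atom_class)) {
    atoms$atom_class <- default_atom_class(atoms$name, atoms$element,
                                           atoms$resname)
  }
  if (is.null(atoms$charge)) {
    atoms$charge <- class_params(atoms$atom_class)$charge
  }
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  atoms$is_heavy <- toupper(atoms$element) != "H"
  rownames(atoms) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "ensmap_structure")
}

#' @export
print.ensmap_structure <- function(x, ...) {
  cat(sprintf("<ensmap_structure> model %d: %d atoms, %d residues\n",
              x$model_id, nrow(x$atoms), length(unique(residue_keys(x)))))
  invisible(x)
}

#' Atom coordinates of a structure
#' @param structure an `ensmap_structure`.
#' @param heavy_only if `TRUE`, restrict to non-hydrogen atoms.
#' @return numeric matrix (n x 3), in Angstrom.
#' @export
coords <- function(structure, heavy_only = FALSE) {
  a <- structure$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Residue keys of each atom
#'
#' @param structure an `ensmap_structure`.
#' @return character vector, one `chain:resid:ins` key per atom.
#' @export
residue_keys <- function(structure) {
  a <- structure$atoms
  paste(a$chain, a$resid, a$ins, sep = ":")
}

#' Residue index: atom ranges per residue
#'
#' @param structure an `ensmap_structure`.
#' @return data.frame with one row per residue (`key`, `chain`, `resid`,
#'   `ins`, `first`, `last`, `natoms`), covering every atom exactly once.
#' @export
residue_index <- function(structure) {
  keys <- residue_keys(structure)
  ord_keys <- unique(keys)
  idx <- split(seq_along(keys), factor(keys, levels = ord_keys))
  a <- structure$atoms
  first <- vapply(idx, min, integer(1))
  data.frame(
    key = ord_keys,
    chain = a$chain[first],
    resid = a$resid[first],
    ins = a$ins[first],
    first = first,
    last = vapply(idx, max, integer(1)),
    natoms = lengths(idx),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Construct a conformer ensemble
#'
#' All models must have identical atom counts, atom names and residue keys;
#' the first inconsistent model is reported.
#'
#' @param models list of `ensmap_structure` objects.
#' @param alignment_selection integer atom indices used for superposition
#'   (defaults to all C-alpha / backbone-bead atoms named `CA`).
#' @return object of class `ensmap_ensemble`.
#' @export
new_ensemble <- function(models, alignment_selection = NULL) {
  if (!length(models)) stop("ensemble needs at least one model")
  ref <- models[[1]]
  for (m in seq_along(models)) {
    mod <- models[[m]]
    if (nrow(mod$atoms) != nrow(ref$atoms)) {
      stop(sprintf("model %d has %d atoms; model 1 has %d", m,
                   nrow(mod$atoms), nrow(ref$atoms)))
    }
    bad <- which(mod$atoms$name != ref$atoms$name |
                 residue_keys(mod) != residue_keys(ref))
    if (length(bad)) {
      stop(sprintf("model %d: atom %d (%s %s) does not match model 1 (%s %s)",
                   m, bad[1], mod$atoms$name[bad[1]], residue_keys(mod)[bad[1]],
                   ref$atoms$name[bad[1]], residue_keys(ref)[bad[1]]))
    }
    models[[m]]$model_id <- as.integer(m)
  }
  if (is.null(alignment_selection)) {
    alignment_selection <- which(ref$atoms$name == "CA")
    if (!length(alignment_selection)) {
      alignment_selection <- which(ref$atoms$is_heavy)
    }
  }
  if (any(alignment_selection < 1L | alignment_selection > nrow(ref$atoms))) {
    stop("alignment_selection indices out of range")
  }
  structure(list(models = models,
                 alignment_selection = as.integer(alignment_selection)),
            class = "ensmap_ensemble")
}

#' @export
print.ensmap_ensemble <- function(x, ...) {
  cat(sprintf("<ensmap_ensemble> %d models x %d atoms (%d alignment atoms)\n",
              length(x$models), nrow(x$models[[1]]$atoms),
              length(x$alignment_selection)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble an `ensmap_ensemble`.
#' @return integer.
#' @export
n_models <- function(ensemble) length(ensemble$models)

#' Select atoms by a simple expression
#'
#' Supported clauses, combined with `and`: `all`, `heavy` (non-hydrogen),
#' `name <N1>[,N2,...]`, `chain <C1>[,C2,...]`,
#' `resid <spec>` where spec is a comma list of numbers and `a-b` ranges.
#' The result is a deterministic, order-preserving 1-based index vector.
#' An empty selection warns and returns `integer(0)`.
#'
#' @param structure an `ensmap_structure`.
#' @param expression selection string, e.g. `"resid 10-12 and name CA"`.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (!length(clauses) || !nzchar(trimws(expression))) {
    stop("empty selection expression")
  }
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    arg <- if (length(tok) > 1) paste(tok[-1], collapse = "") else ""
    if (kw == "all") {
      next
    } else if (kw %in% c("heavy", "noh")) {
      keep <- keep & a$is_heavy
    } else if (kw == "name") {
      if (!nzchar(arg)) stop("malformed selection clause: ", cl)
      keep <- keep & a$name %in% strsplit(arg, ",")[[1]]
    } else if (kw == "chain") {
      if (!nzchar(arg)) stop("malformed selection clause: ", cl)
      keep <- keep & a$chain %in% strsplit(arg, ",")[[1]]
    } else if (kw == "resid") {
      if (!nzchar(arg)) stop("malformed selection clause: ", cl)
      parts <- strsplit(arg, ",")[[1]]
      ids <- integer(0)
      for (p in parts) {
        if (grepl("^-?[0-9]+--?[0-9]+$", p) && grepl("-", substring(p, 2))) {
          m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
          if (length(m) != 3) stop("malformed resid range: ", p)
          ids <- c(ids, seq(as.integer(m[2]), as.integer(m[3])))
        } else if (grepl("^-?[0-9]+$", p)) {
          ids <- c(ids, as.integer(p))
        } else {
          stop("malformed resid spec: ", p)
        }
      }
      keep <- keep & a$resid %in% ids
    } else {
      stop("unknown selection keyword: ", kw)
    }
  }
  out <- which(keep)
  if (!length(out)) warning("selection matched no atoms: ", expression)
  out
}
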