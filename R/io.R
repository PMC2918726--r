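# PDB reading/writing. Parsing of individual models is delegated to bio3d;
# this layer handles MODEL/ENDMDL splitting, cross-model consistency checks
# and the probe-pose output convention.

# parse one model's worth of PDB lines via bio3d
parse_pdb_block <- function(lines, model_id, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(lines, "END"), tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE)),
    error = function(e) {
      stop(sprintf("unparseable PDB content in model %d of %s: %s",
                   model_id, path, conditionMessage(e)), call. = FALSE)
    })
  at <- pdb$atom
  n_lines <- sum(grepl("^(ATOM|HETATM)", lines))
  if (is.null(at) || nrow(at) < n_lines) {
    stop(sprintf("unparseable ATOM/HETATM line in model %d of %s (%d of %d records read)",
                 model_id, path, if (is.null(at)) 0L else nrow(at), n_lines),
         call. = FALSE)
  }
  # altloc policy: keep highest occupancy, ties -> first encountered
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    o <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      i <- which(key == k)
      best <- i[which.max(o[i])]
      keep[setdiff(i, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                        substr(trimws(at$elety), 1, 1), at$elesy))
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = toupper(elem),
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    ins = ifelse(is.na(at$insert) | !nzchar(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    record = at$type,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, model_id = model_id)
}

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' Splits the file on `MODEL`/`ENDMDL` records (a file without them is a
#' single implicit model) and checks that every model carries the same atoms
#' in the same order; the first offending model and atom are reported.
#' Hydrogens are retained but flagged `is_heavy = FALSE`. Alternate locations
#' keep the highest-occupancy copy (ties: first encountered).
#'
#' @param path PDB file path.
#' @return an `ensmap_ensemble`.
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    blocks <- list(lines[grepl("^(ATOM|HETATM|TER)", lines)])
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    blocks <- mapply(function(s, e) {
      b <- lines[(s + 1):(e - 1)]
      b[grepl("^(ATOM|HETATM|TER)", b)]
    }, starts, ends[seq_along(starts)], SIMPLIFY = FALSE)
  }
  if (!length(blocks) || !length(blocks[[1]])) {
    stop("no ATOM/HETATM records found in ", path)
  }
  models <- lapply(seq_along(blocks), function(i) {
    parse_pdb_block(blocks[[i]], i, path)
  })
  new_ensemble(models)
}

# fixed-width PDB ATOM/HETATM line
format_pdb_line <- function(record, serial, name, resname, chain, resid, ins,
                            x, y, z, segid = "", element = "") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          record, serial %% 100000, name_fmt, substr(resname, 1, 4),
          substr(chain, 1, 1), resid %% 10000,
          ifelse(nzchar(ins), ins, " "), x, y, z, 1.0, 0.0,
          segid, substr(element, 1, 2))
}

structure_pdb_lines <- function(structure) {
  a <- structure$atoms
  vapply(seq_len(nrow(a)), function(i) {
    format_pdb_line(a$record[i], a$serial[i], a$name[i], a$resname[i],
                    a$chain[i], a$resid[i], a$ins[i], a$x[i], a$y[i], a$z[i],
                    segid = "", element = a$element[i])
  }, character(1))
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble an `ensmap_ensemble` (or a single `ensmap_structure`).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb_models <- function(ensemble, path) {
  if (inherits(ensemble, "ensmap_structure")) {
    ensemble <- new_ensemble(list(ensemble))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con), add = TRUE)
  for (m in seq_along(ensemble$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(structure_pdb_lines(ensemble$models[[m]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure plus consensus-site probe poses as a PDB file
#'
#' Protein atoms are written as `ATOM` records; every probe pose becomes one
#' `HETATM` residue whose residue name is the probe's 3-letter code. The
#' consensus-site rank is encoded in the chain identifier (rank 1-9 as digits
#' `1`..`9`, rank 10 as `0`) and in the segment identifier (`CS01`, `CS02`,
#' ...). Columns are fixed-width PDB.
#'
#' @param structure receptor `ensmap_structure`.
#' @param sites list of consensus sites as returned by
#'   [build_consensus_sites()] (may be empty).
#' @param path output file path.
#' @param probes probe library used to expand pose atoms
#'   (default [default_probe_library()]).
#' @return invisibly, `path`.
#' @export
write_pdb_with_probes <- function(structure, sites, path,
                                  probes = default_probe_library()) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con), add = TRUE)
  writeLines(structure_pdb_lines(structure), con)
  serial <- max(structure$atoms$serial, 0L)
  resno <- 0L
  for (cs in sites) {
    chain_id <- as.character(cs$rank %% 10)
    segid <- sprintf("CS%02d", cs$rank)
    for (pc in cs$clusters) {
      probe <- probes[[pc$probe]]
      for (k in seq_len(nrow(pc$poses))) {
        resno <- resno + 1L
        xyz <- pose_atom_coords(probe, pc$poses[k, ])
        for (j in seq_len(nrow(xyz))) {
          serial <- serial + 1L
          writeLines(format_pdb_line("HETATM", serial, probe$atoms$name[j],
                                     probe$code, chain_id, resno, "",
                                     xyz[j, 1], xyz[j, 2], xyz[j, 3],
                                     segid = segid,
                                     element = probe$atoms$element[j]), con)
        }
      }
    }
  }
  writeLines("END", con)
  invisible(path)
}
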