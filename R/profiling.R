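# Ensemble residue profiling: heavy-atom probe contact counting per residue,
# percentage ranking across the ensemble, orthosteric classification by
# ligand proximity, and grouping of non-orthosteric residues into sites.

#' Profiling configuration
#'
#' @param contact_radius probe/protein heavy-atom contact radius, Angstrom
#'   (default 5.0, boundary inclusive).
#' @param top_n number of top probe-interacting residues analysed (40).
#' @param orthosteric_radius residue-to-ligand heavy-atom radius used for the
#'   orthosteric / non-orthosteric split, Angstrom (default 5.0).
#' @param site_linkage_cutoff single-linkage cutoff on minimal inter-residue
#'   heavy-atom distance when grouping non-orthosteric residues (default 5.0).
#' @return object of class `ensmap_profiling_config`.
#' @export
profiling_config <- function(contact_radius = 5.0, top_n = 40L,
                             orthosteric_radius = 5.0,
                             site_linkage_cutoff = 5.0) {
  stopifnot(contact_radius > 0, top_n >= 1, orthosteric_radius > 0,
            site_linkage_cutoff > 0)
  structure(list(contact_radius = contact_radius, top_n = as.integer(top_n),
                 orthosteric_radius = orthosteric_radius,
                 site_linkage_cutoff = site_linkage_cutoff),
            class = "ensmap_profiling_config")
}

# all poses belonging to the retained consensus sites of a mapping
#' Collect the probe poses belonging to a mapping's consensus sites
#' @param mapping an `ensmap_mapping`.
#' @return pose data.frame (all member poses of all retained CS clusters).
#' @export
collect_cs_poses <- function(mapping) {
  dfs <- list()
  for (cs in mapping$sites) {
    for (pc in cs$clusters) dfs[[length(dfs) + 1]] <- pc$poses
  }
  if (!length(dfs)) {
    return(data.frame(probe = character(0), qw = numeric(0), qx = numeric(0),
                      qy = numeric(0), qz = numeric(0), tx = numeric(0),
                      ty = numeric(0), tz = numeric(0), energy = numeric(0)))
  }
  common <- Reduce(intersect, lapply(dfs, names))
  do.call(rbind, lapply(dfs, function(d) d[, common, drop = FALSE]))
}

# expanded heavy-atom coordinates of a set of poses
pose_set_coords <- function(poses, probes = default_probe_library()) {
  if (!nrow(poses)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(seq_len(nrow(poses)), function(i) {
    pose_atom_coords(probes[[poses$probe[i]]], poses[i, ])
  }))
}

#' Count probe contacts per residue
#'
#' An interaction is counted whenever a non-hydrogen probe atom lies within
#' `contact_radius` (inclusive) of a non-hydrogen protein atom; the count for
#' a residue is the number of such atom pairs, summed over all poses.
#'
#' @param structure the mapped `ensmap_structure`.
#' @param poses pose data.frame (typically [collect_cs_poses()] output).
#' @param config a [profiling_config()].
#' @param probes probe library.
#' @return named integer vector: contact count per residue key (in residue
#'   order; zero-count residues included).
#' @export
count_contacts <- function(structure, poses, config = profiling_config(),
                           probes = default_probe_library()) {
  ridx <- residue_index(structure)
  a <- structure$atoms
  heavy <- which(a$is_heavy)
  keys <- residue_keys(structure)
  res_of_atom <- match(keys[heavy], ridx$key)
  counts <- setNames(integer(nrow(ridx)), ridx$key)
  if (!nrow(poses)) return(counts)
  pxyz <- pose_set_coords(poses, probes)
  cc <- cpp_count_contacts(as.matrix(a[heavy, c("x", "y", "z")]),
                           as.integer(res_of_atom), nrow(ridx),
                           pxyz, config$contact_radius)
  counts[] <- cc
  counts
}

#' Aggregate per-structure contact counts into ranked residue profiles
#'
#' Sums contact counts over structures, expresses each residue's total as a
#' percentage of all protein-probe contacts in the ensemble, and ranks
#' residues by count (ties: lower residue number, then chain).
#'
#' @param per_structure_counts list of named count vectors from
#'   [count_contacts()] (consistent residue keys).
#' @return data.frame (class `ensmap_profiles`) with columns `key`, `chain`,
#'   `resid`, `raw_count`, `percentage`, `rank`.
#' @export
aggregate_profiles <- function(per_structure_counts) {
  if (!length(per_structure_counts)) stop("no count maps supplied")
  keys <- names(per_structure_counts[[1]])
  for (cc in per_structure_counts) {
    if (!identical(names(cc), keys)) {
      stop("inconsistent residue keys across count maps")
    }
  }
  total <- Reduce(`+`, per_structure_counts)
  grand <- sum(total)
  pct <- if (grand > 0) 100 * total / grand else {
    warning("no probe contacts at all; percentages set to 0")
    rep(0, length(total))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, character(1), 1)
  resid <- as.integer(vapply(parts, `[`, character(1), 2))
  ord <- order(-total, resid, chain)
  prof <- data.frame(key = keys, chain = chain, resid = resid,
                     raw_count = as.integer(total), percentage = as.numeric(pct),
                     stringsAsFactors = FALSE)[ord, , drop = FALSE]
  prof$rank <- seq_len(nrow(prof))
  rownames(prof) <- NULL
  class(prof) <- c("ensmap_profiles", class(prof))
  prof
}

#' Classify residues as orthosteric or non-orthosteric
#'
#' A residue is orthosteric when any of its heavy atoms in the reference
#' structure lies within `orthosteric_radius` of any ligand heavy atom.
#' With a missing ligand every residue is non-orthosteric (with a warning).
#'
#' @param profiles an `ensmap_profiles` data.frame.
#' @param reference the reference `ensmap_structure` (shares residue keys).
#' @param ligand ligand `ensmap_structure` (or `NULL`).
#' @param config a [profiling_config()].
#' @return profiles with an added logical `orthosteric` column.
#' @export
classify_orthosteric <- function(profiles, reference, ligand,
                                 config = profiling_config()) {
  if (is.null(ligand) || !nrow(ligand$atoms)) {
    warning("no ligand supplied; all residues classified non-orthosteric")
    profiles$orthosteric <- FALSE
    return(profiles)
  }
  lxyz <- coords(ligand, heavy_only = TRUE)
  a <- reference$atoms
  heavy <- which(a$is_heavy)
  keys <- residue_keys(reference)[heavy]
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  mind <- vapply(seq_len(nrow(xyz)), function(i) {
    sqrt(min((lxyz[, 1] - xyz[i, 1])^2 + (lxyz[, 2] - xyz[i, 2])^2 +
             (lxyz[, 3] - xyz[i, 3])^2))
  }, numeric(1))
  ortho_keys <- unique(keys[mind <= config$orthosteric_radius])
  profiles$orthosteric <- profiles$key %in% ortho_keys
  profiles
}

#' Select the top probe-interacting residues
#'
#' First `min(top_n, number of residues with nonzero count)` profiles in rank
#' order.
#'
#' @param profiles ranked `ensmap_profiles`.
#' @param config a [profiling_config()].
#' @return the truncated profiles data.frame.
#' @export
select_top_n <- function(profiles, config = profiling_config()) {
  nonzero <- sum(profiles$raw_count > 0)
  head(profiles[order(profiles$rank), , drop = FALSE],
       min(config$top_n, nonzero))
}

# minimal heavy-atom distance between every pair of the given residues
min_residue_distances <- function(reference, keys) {
  a <- reference$atoms
  heavy <- which(a$is_heavy)
  akeys <- residue_keys(reference)[heavy]
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  n <- length(keys)
  M <- matrix(0, n, n)
  idx <- lapply(keys, function(k) which(akeys == k))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      xi <- xyz[idx[[i]], , drop = FALSE]
      xj <- xyz[idx[[j]], , drop = FALSE]
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
      M[i, j] <- M[j, i] <- sqrt(max(min(d2), 0))
    }
  }
  M
}

#' Group non-orthosteric top residues into candidate allosteric sites
#'
#' Single-linkage clustering of the non-orthosteric residues from the top-N
#' list, using the minimal inter-residue heavy-atom distance in the reference
#' structure with cutoff `site_linkage_cutoff`. Sites are numbered by
#' descending summed contact percentage. Every pose contacting a residue of a
#' site is attached to that site.
#'
#' @param top_profiles classified top-N `ensmap_profiles`.
#' @param reference reference `ensmap_structure`.
#' @param poses pose data.frame used for probe attachment (may be empty).
#' @param config a [profiling_config()].
#' @param probes probe library.
#' @return list of site groups, each `list(site_id, residues, percentage,
#'   pose_idx)`; empty when no non-orthosteric residues exist.
#' @export
group_sites <- function(top_profiles, reference, poses,
                        config = profiling_config(),
                        probes = default_probe_library()) {
  nono <- top_profiles[!top_profiles$orthosteric, , drop = FALSE]
  if (!nrow(nono)) return(list())
  keys <- nono$key
  if (length(keys) == 1) {
    memb <- 1L
  } else {
    M <- min_residue_distances(reference, keys)
    hc <- stats::hclust(stats::as.dist(M), method = "single")
    memb <- stats::cutree(hc, h = config$site_linkage_cutoff)
  }
  groups <- lapply(unique(memb), function(g) {
    rows <- nono[memb == g, , drop = FALSE]
    list(residues = rows$key, percentage = sum(rows$percentage))
  })
  ord <- order(-vapply(groups, `[[`, numeric(1), "percentage"))
  groups <- groups[ord]

  # attach poses by contact with any residue of the site
  pose_contacts <- NULL
  if (!is.null(poses) && nrow(poses)) {
    a <- reference$atoms
    heavy <- which(a$is_heavy)
    akeys <- residue_keys(reference)[heavy]
    xyz <- as.matrix(a[heavy, c("x", "y", "z")])
    pose_contacts <- lapply(seq_len(nrow(poses)), function(i) {
      pxyz <- pose_atom_coords(probes[[poses$probe[i]]], poses[i, ])
      d2 <- outer(rowSums(pxyz^2), rowSums(xyz^2), "+") - 2 * pxyz %*% t(xyz)
      unique(akeys[apply(d2 <= config$contact_radius^2, 2, any)])
    })
  }
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    pidx <- integer(0)
    if (!is.null(pose_contacts)) {
      pidx <- which(vapply(pose_contacts, function(k) {
        any(k %in% groups[[g]]$residues)
      }, logical(1)))
    }
    out[[g]] <- structure(list(site_id = g, residues = groups[[g]]$residues,
                               percentage = groups[[g]]$percentage,
                               pose_idx = pidx),
                          class = "ensmap_site_group")
  }
  out
}

#' @export
print.ensmap_site_group <- function(x, ...) {
  cat(sprintf("<site %d> %.1f%% of contacts, %d residues, %d bound poses\n",
              x$site_id, x$percentage, length(x$residues), length(x$pose_idx)))
  invisible(x)
}

#' Jaccard overlap between two residue-key sets
#' @param a,b character vectors of residue keys.
#' @return |intersection| / |union| (0 when both empty).
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Profile an ensemble of mapped structures
#'
#' Convenience wrapper over the profiling stage: counts consensus-site probe
#' contacts per residue in every mapped structure, aggregates to ensemble
#' percentages, classifies against the ligand, truncates to the top N and
#' groups non-orthosteric residues into sites.
#'
#' @param structures list of `ensmap_structure` (the mapped representatives).
#' @param mappings list of `ensmap_mapping`, parallel to `structures`.
#' @param reference reference structure for classification and grouping.
#' @param ligand ligand structure (or `NULL`).
#' @param config a [profiling_config()].
#' @param probes probe library.
#' @return list with `profiles` (full ranked table), `top` (classified top-N),
#'   `sites` (site groups), `poses` (pooled CS poses).
#' @export
profile_ensemble <- function(structures, mappings, reference, ligand,
                             config = profiling_config(),
                             probes = default_probe_library()) {
  stopifnot(length(structures) == length(mappings))
  counts <- vector("list", length(structures))
  all_poses <- list()
  for (i in seq_along(structures)) {
    poses <- collect_cs_poses(mappings[[i]])
    counts[[i]] <- count_contacts(structures[[i]], poses, config, probes)
    all_poses[[i]] <- poses
  }
  profiles <- aggregate_profiles(counts)
  profiles <- classify_orthosteric(profiles, reference, ligand, config)
  top <- select_top_n(profiles, config)
  poses <- do.call(rbind, all_poses)
  sites <- group_sites(top, reference, poses, config, probes)
  list(profiles = profiles, top = top, sites = sites, poses = poses)
}
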