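# Ensemble reduction: superposition, pairwise RMSD and GROMOS (Daura)
# neighbour clustering, then representative extraction with occupancy.

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` using the
#' atoms in `selection` for the fit (proper rotation, det +1, via SVD of the
#' covariance matrix). The transform is applied to *all* atoms of `mobile`;
#' the returned RMSD is computed on the selection after the transform.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param reference n x 3 coordinate matrix to fit to (same atom order).
#' @param selection integer atom indices used for the fit (>= 3 non-collinear
#'   points; default all atoms).
#' @return list with `rotation` (3 x 3), `translation` (such that
#'   `transformed = mobile %*% t(rotation) + translation`), `rmsd` (Angstrom,
#'   on the selection) and `coords` (all transformed atoms).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must have the same number of atoms")
  }
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("selection needs at least 3 atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop("degenerate (collinear or coincident) selection for superposition")
  }
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  translation <- cb - as.vector(R %*% ca)
  fitted <- sweep(mobile %*% t(R), 2, translation, "+")
  dsel <- fitted[selection, , drop = FALSE] - B
  list(rotation = R, translation = translation,
       rmsd = sqrt(mean(rowSums(dsel^2))), coords = fitted)
}

#' Pairwise superposed RMSD matrix of an ensemble
#'
#' Entry (i, j) is the RMSD over the ensemble's `alignment_selection` after
#' Kabsch superposition of model i onto model j (fit and measure on the same
#' atom set).
#'
#' @param ensemble an `ensmap_ensemble`.
#' @return symmetric n x n matrix of RMSDs in Angstrom, class `ensmap_rmsd`.
#' @export
pairwise_rmsd_matrix <- function(ensemble) {
  sel <- ensemble$alignment_selection
  xyz <- lapply(ensemble$models, function(m) coords(m)[sel, , drop = FALSE])
  n <- length(xyz)
  M <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- kabsch_superpose(xyz[[i]], xyz[[j]])$rmsd
        M[i, j] <- r
        M[j, i] <- r
      }
    }
  }
  class(M) <- c("ensmap_rmsd", class(M))
  M
}

#' GROMOS (Daura) neighbour clustering of an RMSD matrix
#'
#' Iteratively takes the structure with the most neighbours within `cutoff`
#' (ties: lowest model id) as a cluster center, removes it together with its
#' neighbours as one cluster, and repeats until no structures remain.
#' Clusters are returned ranked by size, ties by lower center id.
#'
#' @param rmsd_matrix symmetric RMSD matrix (Angstrom).
#' @param cutoff neighbour cutoff in Angstrom (> 0); neighbourhood is
#'   inclusive (RMSD <= cutoff).
#' @return list of clusters, each `list(center_model, member_models, size)`.
#' @export
gromos_cluster <- function(rmsd_matrix, cutoff) {
  M <- unclass(rmsd_matrix)
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("rmsd_matrix must be square")
  if (max(abs(M - t(M))) > 1e-8) stop("rmsd_matrix must be symmetric")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(M)
  adj <- M <= cutoff
  remaining <- rep(TRUE, n)
  clusters <- list()
  while (any(remaining)) {
    ids <- which(remaining)
    counts <- vapply(ids, function(i) sum(adj[i, remaining]), integer(1))
    center <- ids[which.max(counts)]  # which.max takes the first = lowest id
    members <- ids[adj[center, ids]]
    clusters[[length(clusters) + 1]] <- list(
      center_model = center,
      member_models = members,
      size = length(members)
    )
    remaining[members] <- FALSE
  }
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  centers <- vapply(clusters, `[[`, integer(1), "center_model")
  clusters[order(-sizes, centers)]
}

#' Retain top clusters and extract representative structures
#'
#' Keeps the `k` largest clusters (all of them if fewer) and returns their
#' center structures, superposed onto the first representative so all
#' representatives share one frame. The report carries per-cluster size and
#' the trajectory occupancy of the retained set.
#'
#' @param clusters ranked cluster list from [gromos_cluster()].
#' @param ensemble the `ensmap_ensemble` the matrix was computed from.
#' @param k number of clusters to retain (default 15).
#' @param cutoff the clustering cutoff, echoed into the report.
#' @return list with `representatives` (an `ensmap_ensemble`) and `report`
#'   (class `ensmap_reduction_report`: data.frame of retained clusters,
#'   `cutoff`, `k`, `occupancy` as a percentage of all models covered).
#' @export
select_representatives <- function(clusters, ensemble, k = 15L, cutoff = NA) {
  if (k < 1) stop("k must be >= 1")
  kept <- clusters[seq_len(min(k, length(clusters)))]
  n_total <- n_models(ensemble)
  covered <- sum(vapply(kept, function(cl) as.numeric(cl$size), numeric(1)))
  occupancy <- 100 * covered / n_total

  sel <- ensemble$alignment_selection
  reps <- lapply(kept, function(cl) ensemble$models[[cl$center_model]])
  if (length(reps) > 1) {
    ref_xyz <- coords(reps[[1]])
    for (i in seq_along(reps)[-1]) {
      fit <- kabsch_superpose(coords(reps[[i]]), ref_xyz, sel)
      reps[[i]] <- set_coords(reps[[i]], fit$coords)
    }
  }
  report <- structure(list(
    clusters = data.frame(
      rank = seq_along(kept),
      center_model = as.integer(vapply(kept, function(cl) {
        as.numeric(cl$center_model)
      }, numeric(1))),
      size = as.integer(vapply(kept, function(cl) as.numeric(cl$size),
                               numeric(1)))
    ),
    members = lapply(kept, `[[`, "member_models"),
    cutoff = cutoff,
    k = as.integer(k),
    occupancy = occupancy
  ), class = "ensmap_reduction_report")
  list(representatives = new_ensemble(reps, alignment_selection = sel),
       report = report)
}

#' @export
print.ensmap_reduction_report <- function(x, ...) {
  cat(sprintf("<reduction> %d clusters retained (cutoff %.2f A), occupancy %.1f%%\n",
              nrow(x$clusters), x$cutoff, x$occupancy))
  print(x$clusters)
  invisible(x)
}

#' Reduce an ensemble to representative structures
#'
#' Convenience wrapper: pairwise RMSD, Daura clustering at `cutoff`, then
#' representative extraction of the top `k` clusters.
#'
#' @param ensemble an `ensmap_ensemble`.
#' @param cutoff RMSD cutoff in Angstrom (default 1.5).
#' @param k clusters to retain (default 15).
#' @return as [select_representatives()].
#' @export
reduce_ensemble <- function(ensemble, cutoff = 1.5, k = 15L) {
  M <- pairwise_rmsd_matrix(ensemble)
  cl <- gromos_cluster(M, cutoff)
  select_representatives(cl, ensemble, k = k, cutoff = cutoff)
}
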