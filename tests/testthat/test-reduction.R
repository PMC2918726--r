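# Superposition, RMSD matrices, Daura clustering and representative selection

test_that("superposing a structure onto itself is the identity", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("a rigidly moved copy superposes back to zero RMSD", {
  set.seed(2)
  X <- matrix(rnorm(45), ncol = 3)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # 90 degrees about z
  Y <- sweep(X %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$coords, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch RMSD matches a dense rotation-grid brute force", {
  set.seed(3)
  for (rep in 1:3) {
    X <- matrix(rnorm(18), ncol = 3)
    Y <- X + matrix(rnorm(18, sd = 0.3), ncol = 3)
    fit <- kabsch_superpose(Y, X)
    brute <- oracle_min_rmsd(Y, X)
    expect_lt(abs(fit$rmsd - brute), 1e-3)
    # the closed-form solution can never be beaten by the grid search
    expect_lte(fit$rmsd, brute + 1e-9)
  }
})

test_that("kabsch agrees with the bio3d fitting routine", {
  set.seed(4)
  X <- matrix(rnorm(60), ncol = 3)
  Y <- X + matrix(rnorm(60, sd = 0.5), ncol = 3)
  fit <- kabsch_superpose(Y, X)
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(X)), mobile = as.vector(t(Y))))
  rmsd_bio3d <- sqrt(mean(colSums(matrix(xyz_fit - as.vector(t(X)), nrow = 3)^2)))
  expect_equal(fit$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_superpose(line, line + 0.1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
})

test_that("pairwise RMSD matrix is consistent with direct recomputation", {
  gen <- generate_ensemble(tiny_spec(seed = 5, n_models = 5))
  ens <- gen$ensemble
  M <- pairwise_rmsd_matrix(ens)
  expect_equal(diag(M), rep(0, 5))
  expect_equal(unclass(M), t(unclass(M)), tolerance = 1e-12, ignore_attr = TRUE)
  sel <- ens$alignment_selection
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- kabsch_superpose(coords(ens$models[[i]])[sel, ],
                            coords(ens$models[[j]])[sel, ])$rmsd
    expect_equal(M[i, j], ref, tolerance = 1e-12)
  }
  # identical models give an all-zero matrix
  same <- new_ensemble(rep(list(ens$models[[1]]), 3))
  expect_lt(max(pairwise_rmsd_matrix(same)), 1e-12)
})

test_that("Daura clustering handles the degenerate extremes", {
  M <- matrix(0.1, 4, 4); diag(M) <- 0
  cl <- gromos_cluster(M, cutoff = 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 4L)
  M2 <- matrix(5, 4, 4); diag(M2) <- 0
  cl2 <- gromos_cluster(M2, cutoff = 1)
  expect_length(cl2, 4)
  expect_true(all(vapply(cl2, `[[`, integer(1), "size") == 1L))
})

test_that("a crafted two-clique matrix matches the independent oracle", {
  # models 1-3 and 4-6 form cliques; cross distances large
  M <- matrix(10, 6, 6)
  M[1:3, 1:3] <- 0.5
  M[4:6, 4:6] <- 0.5
  diag(M) <- 0
  got <- gromos_cluster(M, cutoff = 1)
  want <- oracle_daura(M, 1)
  expect_equal(got, want)
  expect_equal(got[[1]]$member_models, 1:3)
  expect_equal(got[[2]]$member_models, 4:6)
})

test_that("clusters partition the model set and respect the cutoff", {
  set.seed(6)
  for (case in 1:10) {
    n <- sample(4:12, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), ncol = 2)))
    cl <- gromos_cluster(D, cutoff = 1)
    members <- unlist(lapply(cl, `[[`, "member_models"))
    expect_setequal(members, seq_len(n))
    expect_equal(length(members), n)  # disjoint + exhaustive
    for (c in cl) {
      expect_true(all(D[c$center_model, c$member_models] <= 1))
      expect_true(c$center_model %in% c$member_models)
    }
  }
})

test_that("increasing the cutoff never increases the cluster count", {
  set.seed(7)
  D <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  counts <- vapply(c(0.2, 0.5, 1, 2, 4), function(h) {
    length(gromos_cluster(D, h))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is invariant under model relabelling", {
  set.seed(8)
  D <- as.matrix(dist(matrix(rnorm(16), ncol = 2)))
  perm <- sample(8)
  Dp <- D[perm, perm]
  cl <- gromos_cluster(D, 1)
  clp <- gromos_cluster(Dp, 1)
  # sizes must agree up to the documented lowest-id tie-break (membership
  # itself may differ when neighbour counts tie)
  expect_length(clp, length(cl))
  expect_equal(sort(vapply(cl, `[[`, integer(1), "size")),
               sort(vapply(clp, `[[`, integer(1), "size")))
  # the permuted result is still a partition of the permuted labels
  members_p <- sort(perm[unlist(lapply(clp, `[[`, "member_models"))])
  expect_equal(members_p, 1:8)
})

test_that("representative selection truncates, reports occupancy and breaks ties", {
  gen <- generate_ensemble(tiny_spec(seed = 9, n_models = 6))
  ens <- gen$ensemble
  # 20 singleton clusters, k = 15 -> 15 representatives
  fake <- lapply(1:20, function(i) list(center_model = ((i - 1) %% 6) + 1L,
                                        member_models = ((i - 1) %% 6) + 1L,
                                        size = 1L))
  out <- select_representatives(fake, ens, k = 15, cutoff = 1.5)
  expect_equal(n_models(out$representatives), 15L)

  # fewer clusters than k: all retained, occupancy 100%
  cl <- gromos_cluster(pairwise_rmsd_matrix(ens), cutoff = 50)
  out2 <- select_representatives(cl, ens, k = 15, cutoff = 50)
  expect_equal(n_models(out2$representatives), length(cl))
  expect_equal(out2$report$occupancy, 100)

  # equal-size tie at the boundary: lower center id retained
  tie <- list(list(center_model = 5L, member_models = 5L, size = 2L),
              list(center_model = 2L, member_models = 2L, size = 1L),
              list(center_model = 4L, member_models = 4L, size = 1L))
  out3 <- select_representatives(tie[order(-c(2, 1, 1),
                                           c(5, 2, 4))], ens, k = 2)
  expect_equal(out3$report$clusters$center_model, c(5L, 2L))
})

test_that("two well-separated conformational states are recovered exactly", {
  spec <- synthetic_spec(jitter_sigma = 0.1, global_motion = TRUE,
                         breathing_amplitude = 5, pocket_open_fraction = 0.5,
                         n_models = 10, seed = 10)
  gen <- generate_ensemble(spec)
  red <- reduce_ensemble(gen$ensemble, cutoff = 1.5, k = 15)
  expect_equal(nrow(red$report$clusters), 2L)
  open_set <- gen$truth$open_models
  m1 <- sort(red$report$members[[1]])
  m2 <- sort(red$report$members[[2]])
  got <- if (red$report$clusters$center_model[1] %in% open_set) {
    list(open = m1, closed = m2)
  } else {
    list(open = m2, closed = m1)
  }
  expect_equal(got$open, open_set)
  expect_equal(got$closed, sort(setdiff(1:10, open_set)))
})
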