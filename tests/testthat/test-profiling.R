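# Residue contact profiling, classification and site grouping

test_that("the 5 A contact boundary is inclusive", {
  cfg <- profiling_config(contact_radius = 5.0)
  st <- toy_structure(matrix(c(0, 0, 0), ncol = 3), names = "CB",
                      classes = "S.ap")
  probes <- list(unit = point_probe())
  near <- pose_at(c(4.9, 0, 0))
  far <- pose_at(c(5.1, 0, 0))
  expect_equal(unname(count_contacts(st, near, cfg, probes)), 1L)
  expect_equal(unname(count_contacts(st, far, cfg, probes)), 0L)
  exact <- pose_at(c(5.0, 0, 0))
  expect_equal(unname(count_contacts(st, exact, cfg, probes)), 1L)
})

test_that("contacts count heavy-atom pairs", {
  # a 3-heavy-atom probe fully inside 5 A of a 2-heavy-atom residue -> 6
  st <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                      names = c("CA", "CB"), resid = c(1, 1),
                      classes = c("BB", "S.ap"))
  cfg <- profiling_config()
  probes <- default_probe_library()
  pose <- pose_at(c(0.8, 1.5, 0), "ethanol")
  expect_equal(unname(count_contacts(st, pose, cfg, probes)), 6L)
  # empty pose list gives an all-zero map
  none <- count_contacts(st, pose[0, ], cfg, probes)
  expect_equal(unname(none), 0L)
})

test_that("contact counting matches the brute-force oracle on random cases", {
  set.seed(21)
  probes <- default_probe_library()
  cfg <- profiling_config()
  for (case in 1:10) {
    n_res <- sample(3:6, 1)
    xyz <- matrix(runif(n_res * 2 * 3, 0, 15), ncol = 3)
    st <- toy_structure(xyz, names = rep(c("CA", "CB"), n_res),
                        resid = rep(seq_len(n_res), each = 2),
                        classes = rep(c("BB", "S.ap"), n_res))
    pn <- sample(names(probes), 3)
    poses <- do.call(rbind, lapply(pn, function(p) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      data.frame(probe = p, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
                 tx = runif(1, 0, 15), ty = runif(1, 0, 15),
                 tz = runif(1, 0, 15), energy = -1)
    }))
    got <- count_contacts(st, poses, cfg, probes)
    pxyz <- do.call(rbind, lapply(seq_len(nrow(poses)), function(i) {
      ensmap:::pose_atom_coords(probes[[poses$probe[i]]], poses[i, ])
    }))
    want <- oracle_contacts(xyz, rep(residue_index(st)$key, each = 2), pxyz, 5)
    expect_equal(got[names(want)], want)
  }
})

test_that("aggregation normalizes percentages and ranks deterministically", {
  c1 <- c("A:1:" = 4L, "A:2:" = 0L, "A:3:" = 0L, "A:4:" = 0L)
  prof <- aggregate_profiles(list(c1))
  expect_equal(prof$percentage[prof$key == "A:1:"], 100)
  c2 <- c("A:1:" = 1L, "A:2:" = 1L, "A:3:" = 1L, "A:4:" = 1L)
  prof2 <- aggregate_profiles(list(c2))
  expect_equal(prof2$percentage, rep(25, 4))
  expect_equal(prof2$rank, 1:4)
  expect_equal(prof2$resid, 1:4)  # count ties broken by lower residue number

  set.seed(22)
  maps <- lapply(1:4, function(i) {
    setNames(as.integer(rpois(6, 5)), sprintf("A:%d:", 1:6))
  })
  prof3 <- aggregate_profiles(maps)
  expect_equal(sum(prof3$percentage), 100, tolerance = 1e-9)
  direct <- Reduce(`+`, maps)
  expect_equal(prof3$raw_count[match(names(direct), prof3$key)],
               unname(direct))
  expect_false(is.unsorted(-prof3$raw_count))
  # summing over structures equals summing the maps
  expect_equal(sum(prof3$raw_count), sum(unlist(maps)))
})

test_that("zero contacts everywhere warns and yields zero percentages", {
  c0 <- c("A:1:" = 0L, "A:2:" = 0L)
  expect_warning(prof <- aggregate_profiles(list(c0)), "no probe contacts")
  expect_equal(prof$percentage, c(0, 0))
})

test_that("orthosteric classification follows ligand proximity", {
  ref <- toy_structure(rbind(c(0, 0, 0), c(20, 0, 0)),
                       names = c("CB", "CB"), resid = c(1, 2),
                       classes = c("S.ap", "S.ap"))
  lig <- toy_structure(matrix(c(3, 0, 0), ncol = 3), names = "C1")
  prof <- aggregate_profiles(list(c("A:1:" = 3L, "A:2:" = 5L)))
  out <- classify_orthosteric(prof, ref, lig, profiling_config())
  expect_true(out$orthosteric[out$key == "A:1:"])   # 3 A away
  expect_false(out$orthosteric[out$key == "A:2:"])  # 17 A away
  expect_warning(out2 <- classify_orthosteric(prof, ref, NULL), "ligand")
  expect_false(any(out2$orthosteric))
})

test_that("synthetic classification recovers the generator's orthosteric set", {
  gen <- generate_receptor(synthetic_spec())
  keys <- residue_index(gen$structure)$key
  counts <- setNames(rep(1L, length(keys)), keys)
  prof <- aggregate_profiles(list(counts))
  out <- classify_orthosteric(prof, gen$structure, gen$ligand,
                              profiling_config(orthosteric_radius = 5))
  expect_setequal(out$key[out$orthosteric], gen$truth$orthosteric_residues)
})

test_that("top-N selection truncates at N or at the nonzero count", {
  keys <- sprintf("A:%d:", 1:100)
  counts <- setNames(c(100:1), keys)
  prof <- aggregate_profiles(list(counts))
  top <- select_top_n(prof, profiling_config(top_n = 40))
  expect_equal(nrow(top), 40L)
  expect_equal(top$rank, 1:40)
  counts2 <- setNames(c(rep(5L, 12), rep(0L, 88)), keys)
  top2 <- select_top_n(aggregate_profiles(list(counts2)),
                       profiling_config(top_n = 40))
  expect_equal(nrow(top2), 12L)
  # boundary tie: lower residue number retained
  counts3 <- setNames(c(9L, rep(5L, 3), 0L), sprintf("A:%d:", c(1, 4, 2, 3, 5)))
  top3 <- select_top_n(aggregate_profiles(list(counts3)),
                       profiling_config(top_n = 2))
  expect_equal(top3$key, c("A:1:", "A:2:"))
})

test_that("site grouping splits distant clumps and chains close ones", {
  # two clumps of two residues, 20 A apart
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(23, 0, 0), c(26, 0, 0))
  ref <- toy_structure(xyz, names = rep("CB", 4), resid = 1:4,
                       classes = rep("S.ap", 4))
  prof <- aggregate_profiles(list(setNames(c(4L, 3L, 2L, 1L),
                                           sprintf("A:%d:", 1:4))))
  prof$orthosteric <- FALSE
  sites <- group_sites(prof, ref, NULL, profiling_config())
  expect_length(sites, 2)
  expect_setequal(sites[[1]]$residues, c("A:1:", "A:2:"))
  expect_setequal(sites[[2]]$residues, c("A:3:", "A:4:"))
  # site ids follow summed percentage
  expect_gt(sites[[1]]$percentage, sites[[2]]$percentage)

  # chain-wise proximity merges everything (single linkage)
  xyz2 <- cbind(seq(0, 12, by = 4), 0, 0)
  ref2 <- toy_structure(xyz2, names = rep("CB", 4), resid = 1:4,
                        classes = rep("S.ap", 4))
  sites2 <- group_sites(prof, ref2, NULL, profiling_config())
  expect_length(sites2, 1)
  expect_length(sites2[[1]]$residues, 4)

  # orthosteric residues never enter groups; none non-orthosteric -> empty
  prof$orthosteric <- TRUE
  expect_length(group_sites(prof, ref, NULL, profiling_config()), 0)
})

test_that("poses attach to the sites whose residues they contact", {
  xyz <- rbind(c(0, 0, 0), c(30, 0, 0))
  ref <- toy_structure(xyz, names = c("CB", "CB"), resid = 1:2,
                       classes = c("S.ap", "S.ap"))
  prof <- aggregate_profiles(list(setNames(c(2L, 1L), c("A:1:", "A:2:"))))
  prof$orthosteric <- FALSE
  probes <- list(unit = point_probe())
  poses <- rbind(pose_at(c(3, 0, 0)), pose_at(c(33, 0, 0)))
  sites <- group_sites(prof, ref, poses, profiling_config(), probes)
  expect_length(sites, 2)
  expect_equal(sites[[1]]$pose_idx, 1L)
  expect_equal(sites[[2]]$pose_idx, 2L)
})

test_that("the jaccard overlap behaves on edge cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
})
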