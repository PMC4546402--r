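test_that("pairwise RMSD matches closed forms and a naive oracle", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(pairwise_rmsd(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0), "+")
  expect_equal(pairwise_rmsd(a, b), 5)
  b2 <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  naive <- sqrt(sum((a - b2)^2) / 10)
  expect_equal(pairwise_rmsd(a, b2), naive, tolerance = 1e-9)
  expect_error(pairwise_rmsd(a, a[1:5, ]), "mismatch")
  # with superposition a pure rigid motion has zero RMSD
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(pairwise_rmsd(a, sweep(a %*% t(R), 2, c(1, 2, 3), "+"),
                             superpose = TRUE), 0, tolerance = 1e-9)
})

test_that("clustering recovers planted structure and bounds diameters", {
  g <- gen_clustered_confs(k = 4, separation_A = 20, spread_A = 0.5,
                           n_per_cluster = 8, seed = 11)
  cl <- cluster_ensemble(g$ensemble, cutoff = 2)
  expect_equal(cl$n_clusters, 4)
  # planted and found partitions agree
  expect_true(all(table(g$cluster_ids, cl$assignment) %in% c(0L, 8L)))
  # complete-linkage guarantee: intra-cluster pairs within the cutoff
  natoms <- ncol(g$ensemble$xyz) / 3
  for (cid in unique(cl$assignment)) {
    rows <- g$ensemble$xyz[cl$assignment == cid, , drop = FALSE]
    expect_lte(max(dist(rows) / sqrt(natoms)), 2)
  }
  # identical conformations collapse to one cluster
  same <- g$ensemble
  same$xyz <- same$xyz[rep(1, 5), ]
  expect_equal(cluster_ensemble(same)$n_clusters, 1)
  # cluster count is non-increasing in the cutoff
  g2 <- gen_clustered_confs(k = 3, separation_A = 6, spread_A = 1,
                            n_per_cluster = 10, seed = 12)
  ncl <- vapply(c(0.5, 1, 2, 4, 8),
                function(h) cluster_ensemble(g2$ensemble, cutoff = h)$n_clusters,
                integer(1))
  expect_true(all(diff(ncl) <= 0))
  expect_error(cluster_ensemble(matrix(numeric(0), 0, 9)), "empty")
})

test_that("two-stage clustering agrees with exact on separated groups", {
  g <- gen_clustered_confs(k = 3, separation_A = 20, spread_A = 0.5,
                           n_per_cluster = 10, seed = 13)
  cl <- cluster_ensemble(g$ensemble, cutoff = 2, max_exact = 10)
  expect_equal(cl$n_clusters, 3)
  expect_true(all(table(g$cluster_ids, cl$assignment) %in% c(0L, 10L)))
})

test_that("centroids minimise summed RMSD within their cluster", {
  g <- gen_clustered_confs(k = 2, separation_A = 20, spread_A = 0.8,
                           n_per_cluster = 7, seed = 14)
  cl <- cluster_ensemble(g$ensemble, cutoff = 3)
  natoms <- ncol(g$ensemble$xyz) / 3
  dm <- as.matrix(dist(g$ensemble$xyz) / sqrt(natoms))
  for (i in seq_along(cl$centroids)) {
    members <- which(cl$assignment == cl$assignment[cl$centroids[i]])
    sums <- rowSums(dm[members, members, drop = FALSE])
    expect_equal(sums[match(cl$centroids[i], members)], min(sums),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the six arrangements are enumerated and classified correctly", {
  labs <- enumerate_arrangements()
  expect_length(labs, 6)
  expect_false(any(duplicated(labs)))
  expect_setequal(labs, c("ABCD", "ADBC", "ACDB", "ABDC", "ACBD", "ADCB"))
  # worked corner examples (A top-left, clockwise from extracellular +z)
  expect_equal(classify_arrangement(rbind(c(-1, 1), c(1, 1), c(1, -1),
                                          c(-1, -1))), "ABCD")
  expect_equal(classify_arrangement(rbind(c(-1, 1), c(-1, -1), c(1, -1),
                                          c(1, 1))), "ADCB")
  # rotation about z never changes the label
  set.seed(2)
  for (k in 1:20) {
    mids <- matrix(rnorm(8, sd = 4), 4, 2)
    lab <- classify_arrangement(mids)
    if (lab == "unclassifiable") next
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(classify_arrangement(mids %*% t(R)), lab)
  }
  # degenerate geometry is flagged, not mislabelled
  expect_equal(classify_arrangement(rbind(c(0, 0), c(0, 0), c(1, 0),
                                          c(0, 1))), "unclassifiable")
  expect_equal(classify_arrangement(rbind(c(0, 0), c(1, 1), c(2, 2),
                                          c(3, 3)), tol = 1e-6),
               "unclassifiable")
})

test_that("arrangement tables count, rank and summarise correctly", {
  # uniform counts: any three types hold exactly half
  u <- arrangement_counts(setNames(rep(10L, 6), enumerate_arrangements()))
  expect_equal(attr(u, "top3_share_all"), 50.0)
  expect_equal(sum(u$n_all), 60)
  # via clustering of a labelled synthetic ensemble
  g <- gen_bundle_ensemble(40, jitter_A = 0.1, seed = 21)
  g$ensemble$scores <- seq_len(40)  # ascending scores, best first
  cl <- cluster_ensemble(g$ensemble, cutoff = 2)
  tab <- arrangement_table(cl, top_k = 10)
  expect_equal(sum(tab$n_all), cl$n_clusters)
  expect_equal(sum(tab$n_top), min(10, cl$n_clusters))
  share <- round(100 * sum(tab$n_all[1:3]) / sum(tab$n_all), 1)
  expect_equal(attr(tab, "top3_share_all"), share)
})

test_that("distance statistics match hand-computed values", {
  g <- gen_bundle_ensemble(3, jitter_A = 0.2, seed = 31)
  labs <- rep("X", 3)  # pool all three into one group
  ds <- distance_stats(g$ensemble, labs, interval = c(0, 100))
  map <- g$ensemble$map
  i1 <- which(map$helix == "TM2" & map$resno == 85)
  i2 <- which(map$helix == "TM3" & map$resno == 231)
  d <- vapply(1:3, function(k) {
    m <- matrix(g$ensemble$xyz[k, ], ncol = 3, byrow = TRUE)
    sqrt(sum((m[i1, ] - m[i2, ])^2))
  }, numeric(1))
  expect_equal(ds$marker_mean, mean(d), tolerance = 1e-12)
  expect_equal(ds$marker_sd, sd(d), tolerance = 1e-12)
  expect_equal(ds$frac_in_interval, 1.0)
  # marker residues must exist
  expect_error(distance_stats(g$ensemble, labs, res_pair = c(1, 2)),
               "absent")
})

test_that("crossing angles follow the axis-line convention", {
  sp <- helix_spec("H", strrep("A", 20), 1, 20)
  h <- build_ideal_helix(sp)
  h2 <- h; h2[, 1] <- h2[, 1] + 9
  expect_equal(crossing_angle(h, h2), 0, tolerance = 1e-6)
  # one helix tilted 20 degrees: |angle| = 20
  t <- rigid_transform(tilt_polar = 20, tilt_azimuth = 90)
  h3 <- apply_transform(h, t) ; h3[, 1] <- h3[, 1] + 9
  expect_equal(abs(crossing_angle(h, h3)), 20, tolerance = 1e-6)
  # antiparallel untilted pair: angle between the axis lines is 0
  hf <- build_ideal_helix(helix_spec("H", strrep("A", 20), 1, 20,
                                     n_term = "cytoplasmic"))
  hf[, 1] <- hf[, 1] + 9
  expect_equal(abs(crossing_angle(h, hf)), 0, tolerance = 1e-6)
  # ensemble filter passes a parallel bundle at default 40 degrees
  g <- gen_bundle_ensemble(5, jitter_A = 0.1, seed = 41)
  expect_true(all(filter_crossing_angles(g$ensemble)))
})
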