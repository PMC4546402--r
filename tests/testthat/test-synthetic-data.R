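test_that("generators are deterministic and demand seeds", {
  expect_error(gen_bundle_ensemble(5), "seed")
  expect_error(gen_clustered_confs(2), "seed")
  expect_error(gen_relaxation(data.frame(residue = "r", S2 = 0.8,
                                         tau_e = 5e-11), 7e-9), "seed")
  expect_error(gen_titration(100), "seed")
  a <- gen_bundle_ensemble(10, jitter_A = 0.4, seed = 5)
  b <- gen_bundle_ensemble(10, jitter_A = 0.4, seed = 5)
  expect_identical(a$ensemble$xyz, b$ensemble$xyz)
  expect_identical(a$labels, b$labels)
  r1 <- gen_relaxation(data.frame(residue = "r", S2 = 0.8, tau_e = 5e-11),
                       7e-9, seed = 5)
  r2 <- gen_relaxation(data.frame(residue = "r", S2 = 0.8, tau_e = 5e-11),
                       7e-9, seed = 5)
  expect_identical(r1$data, r2$data)
  # truth records capture generator and seed
  expect_equal(a$truth$generator, "gen_bundle_ensemble")
  expect_equal(a$truth$seed, 5)
})

test_that("bundle generator plants recoverable labels with sane histogram", {
  g0 <- gen_bundle_ensemble(60, jitter_A = 0, seed = 6)
  expect_identical(classify_ensemble(g0$ensemble), g0$labels)
  expect_equal(nrow(gen_bundle_ensemble(0, seed = 1)$ensemble$xyz), 0)
  # label histogram within binomial bounds under uniform probabilities
  n <- 1200
  g <- gen_bundle_ensemble(n, jitter_A = 0, seed = 7)
  tab <- table(factor(g$labels, levels = enumerate_arrangements()))
  expected <- n / 6
  sd_bin <- sqrt(n * (1 / 6) * (5 / 6))
  expect_true(all(abs(tab - expected) <= 4 * sd_bin))
})

test_that("clustered generator controls spread and separation", {
  g <- gen_clustered_confs(k = 1, separation_A = 20, spread_A = 0,
                           n_per_cluster = 4, seed = 8)
  expect_equal(cluster_ensemble(g$ensemble)$n_clusters, 1)
  natoms <- ncol(g$ensemble$xyz) / 3
  expect_equal(max(dist(g$ensemble$xyz)), 0)
  g2 <- gen_clustered_confs(k = 3, separation_A = 20, spread_A = 0,
                            n_per_cluster = 2, seed = 8)
  # references differ by exactly the planted separation
  d12 <- pairwise_rmsd(matrix(g2$ensemble$xyz[1, ], ncol = 3, byrow = TRUE),
                       matrix(g2$ensemble$xyz[3, ], ncol = 3, byrow = TRUE))
  expect_equal(d12, 20, tolerance = 1e-12)
})

test_that("relaxation generator reproduces rates and nominal noise", {
  p <- data.frame(residue = c("a", "b"), S2 = c(0.6, 0.9), tau_e = 5e-11)
  g0 <- gen_relaxation(p, 6e-9, noise_frac = 0, seed = 9)
  for (i in 1:2) {
    exact <- predict_rates(p$S2[i], p$tau_e[i], 6e-9)
    expect_equal(c(g0$data$R1[i], g0$data$R2[i], g0$data$NOE[i]),
                 unname(exact), tolerance = 1e-12)
  }
  # empirical sd over replicates close to the nominal 2%
  set.seed(123)
  r1 <- replicate(1000, {
    gen_relaxation(p[1, ], 6e-9, noise_frac = 0.02,
                   seed = sample.int(1e6, 1))$data$R1
  })
  exact <- predict_rates(0.6, 5e-11, 6e-9)[["R1"]]
  expect_equal(sd(r1) / exact, 0.02, tolerance = 0.1)
})

test_that("titration generator honours endpoints and monotonicity", {
  g <- gen_titration(190.6, noise_frac = 0, seed = 10)
  expect_equal(g$data$ratio[1], 1.0)  # zero-acceptor point is r_free
  expect_true(all(diff(g$data$ratio) < 0))  # toward r_bound = 0.3 < 1
  expect_identical(gen_titration(100, seed = 3)$data,
                   gen_titration(100, seed = 3)$data)
})

test_that("truth sidecars serialise next to their data files", {
  g <- gen_titration(100, seed = 4)
  f <- file.path(tempdir(), "titr.csv")
  write.csv(g$data, f, row.names = FALSE)
  side <- write_truth_sidecar(g$truth, f)
  expect_true(file.exists(side))
  back <- jsonlite::read_json(side, simplifyVector = TRUE)
  expect_equal(back$generator, "gen_titration")
  expect_equal(back$params$Kd, 100)
  unlink(c(f, side))
})
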