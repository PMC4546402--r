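test_that("diameter score penalises only over-target assemblies", {
  conf <- perfect_bundle()  # 9 A square, diagonal 12.7 + 4.6 well under 26
  expect_equal(diameter_score(conf), 0)
  # two helices with xy midpoints 30 A apart: (30 + 4.6 - 26)^2
  sp <- perfect_specs()[1:2]
  conf2 <- build_bundle(sp, centers = rbind(c(0, 0), c(30, 0)))
  expect_equal(diameter_score(conf2), (30 + 4.6 - 26)^2)
  # monotone: moving the farthest helices apart never lowers the score
  d_prev <- -Inf
  for (sep in seq(26, 40, by = 2)) {
    d <- diameter_score(build_bundle(sp, centers = rbind(c(0, 0), c(sep, 0))))
    expect_gte(d, d_prev)
    d_prev <- d
  }
})

test_that("excluded volume penalises sub-clash CA pairs quadratically", {
  sp <- list(A = helix_spec("A", "A", 1, 1), B = helix_spec("B", "A", 2, 2))
  apart <- build_bundle(sp, centers = rbind(c(0, 0), c(20, 0)))
  expect_equal(excluded_volume_score(apart), 0)
  # single CA pair at 3.0 A: (4 - 3)^2 = 1. Each 1-residue helix sits at
  # 2.3 A from its own axis, both at angle 0, so CA separation equals the
  # axis separation.
  close <- build_bundle(sp, centers = rbind(c(0, 0), c(3, 0)))
  expect_equal(excluded_volume_score(close), 1)
  ontop <- build_bundle(sp, centers = rbind(c(0, 0), c(0, 0)))
  expect_gt(excluded_volume_score(ontop), 0)
})

test_that("packing counts window contacts, verified by brute force", {
  sp <- list(A = helix_spec("A", strrep("A", 5), 1, 5),
             B = helix_spec("B", strrep("A", 5), 11, 15))
  conf <- build_bundle(sp, centers = rbind(c(0, 0), c(5.5, 0)))
  A <- conf$helices$A$xyz; B <- conf$helices$B$xyz
  n_ref <- 0
  for (i in 1:5) for (j in 1:5) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d >= 4.0 && d <= 6.5) n_ref <- n_ref + 1
  }
  expect_gt(n_ref, 0)
  expect_equal(packing_score(conf), -n_ref)
  far <- build_bundle(sp, centers = rbind(c(0, 0), c(30, 0)))
  expect_equal(packing_score(far), 0)
})

test_that("tilt/depth allows tilt only for membrane-exceeding helices", {
  rs <- restraint_set()
  # 20-residue helix (28.5 A < 30 A): untilted and centred leaves a
  # 0.75 A shortfall at each face
  sp <- list(H = helix_spec("H", strrep("A", 20), 1, 20))
  conf <- build_bundle(sp, centers = rbind(c(0, 0)))
  expect_equal(tilt_depth_score(conf, rs), 2 * 0.75^2)
  # 31-residue helix (45 A): tilt_max = acos(30/45); at exactly tilt_max
  # the z-extent still spans the slab -> no penalty
  spL <- list(H = helix_spec("H", strrep("A", 31), 1, 31))
  tilt_max <- acos(30 / 45) * 180 / pi
  confL <- build_bundle(spL, centers = rbind(c(0, 0)),
                        transforms = list(H = rigid_transform(tilt_polar = tilt_max)))
  expect_equal(tilt_depth_score(confL, rs), 0, tolerance = 1e-6)
  # beyond tilt_max the penalty is positive
  conf_over <- build_bundle(spL, centers = rbind(c(0, 0)),
                            transforms = list(H = rigid_transform(tilt_polar = tilt_max + 10)))
  expect_gt(tilt_depth_score(conf_over, rs), 0)
})

test_that("interaction restraints: flat bottom on axes, certainty-weighted contacts", {
  specs <- perfect_specs()
  rs <- geometric_restraints()
  # adjacent TM2/TM3 axes 9 A apart: inside the 10.4 A flat bottom
  expect_equal(interaction_score(perfect_bundle(), rs), 0)
  # stretch the square until TM2-TM3 axes are 12 A apart: (12 - 10.4)^2
  # (TM1-TM4 stays within bound on the other side)
  centers <- rbind(c(-4.5, 4.5), c(4.5, 6), c(4.5, -6), c(-4.5, -4.5))
  conf <- build_bundle(specs, centers = centers)
  expect_equal(interaction_score(conf, rs), (12 - 10.4)^2, tolerance = 1e-9)
  # violated contact scales linearly with certainty
  mk <- function(cert) restraint_set(
    interaction_pairs = data.frame(i = character(), j = character(),
                                   upper = numeric(), weight = numeric()),
    contact_restraints = data.frame(resi = 101, resj = 201, upper = 8,
                                    certainty = cert))
  far <- build_bundle(specs, centers = rbind(c(0, 0), c(20, 0), c(40, 0), c(60, 0)))
  s1 <- interaction_score(far, mk(1))
  expect_gt(s1, 0)
  expect_equal(interaction_score(far, mk(0.5)), 0.5 * s1)
  expect_error(mk(1.5), "certaint")
})

test_that("pair potential sums table energies over window contacts", {
  sp <- list(A = helix_spec("A", "LLL", 1, 3), B = helix_spec("B", "LLL", 11, 13))
  tab0 <- matrix(0, 20, 20, dimnames = dimnames(default_pair_potential()))
  conf <- build_bundle(sp, centers = rbind(c(0, 0), c(5, 0)))
  expect_equal(pair_potential_score(conf, restraint_set(pair_potential_table = tab0)), 0)
  tabL <- tab0; tabL["L", "L"] <- -1
  # brute-force contact count oracle
  A <- conf$helices$A$xyz; B <- conf$helices$B$xyz
  n_ref <- 0
  for (i in 1:3) for (j in 1:3) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d >= 4.0 && d <= 6.5) n_ref <- n_ref + 1
  }
  expect_equal(
    pair_potential_score(conf, restraint_set(pair_potential_table = tabL)),
    -n_ref)
})

test_that("total score decomposes exactly and respects zero weights", {
  conf <- build_bundle(btl_helix_specs())
  rs <- restraint_set()
  tot <- total_score(conf, rs)
  br <- attr(tot, "breakdown")
  expect_equal(sum(br), as.numeric(tot), tolerance = 1e-9)
  manual <- diameter_score(conf, rs) + tilt_depth_score(conf, rs) +
    excluded_volume_score(conf, rs) + packing_score(conf, rs) +
    interaction_score(conf, rs) + pair_potential_score(conf, rs)
  expect_equal(as.numeric(tot), manual, tolerance = 1e-9)
  w0 <- restraint_set(weights = c(diameter = 0, tilt_depth = 0,
                                  excluded_volume = 0, packing = 0,
                                  interaction = 0, pair_potential = 0))
  expect_equal(as.numeric(total_score(conf, w0)), 0)
  expect_error(restraint_set(weights = c(bogus = 1)), "unknown weight")
})

test_that("every term is invariant under membrane-frame symmetry", {
  conf <- build_bundle(btl_helix_specs())
  rs <- restraint_set()
  ref <- attr(total_score(conf, rs), "breakdown")
  # global rotation about z plus global xy translation
  th <- 143 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(7.3, -2.1, 0)
  moved <- conf
  for (nm in names(moved$helices))
    moved$helices[[nm]]$xyz <-
      sweep(moved$helices[[nm]]$xyz %*% t(R), 2, shift, "+")
  got <- attr(total_score(moved, rs), "breakdown")
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("geometric penalties vanish on the reference bundle", {
  conf <- perfect_bundle()
  rs <- geometric_restraints()
  expect_equal(diameter_score(conf, rs), 0)
  expect_equal(tilt_depth_score(conf, rs), 0)
  expect_equal(excluded_volume_score(conf, rs), 0)
  expect_equal(interaction_score(conf, rs), 0)
})
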