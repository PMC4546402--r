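test_that("helix specs validate sequences, ranges and axes", {
  expect_error(helix_spec("H", "", 1, 0), "non-empty")
  expect_error(helix_spec("H", "ALX", 1, 3), "non-standard")
  expect_error(helix_spec("H", "ALA", 1, 4), "spans")
  sp <- helix_spec("H", "ALAGLY", 10, 15, allowed_axes = c("y", "z"))
  expect_identical(helix_resnums(sp), 10:15)
  expect_equal(helix_length(sp), 7.5)
})

test_that("built-in helix definitions carry the predicted ranges and moves", {
  specs <- btl_helix_specs()
  ranges <- t(vapply(specs, function(s) c(s$start_resnum, s$end_resnum),
                     integer(2)))
  expect_equal(unname(ranges),
               rbind(c(24L, 48L), c(75L, 94L), c(220L, 238L), c(254L, 276L)))
  expect_identical(specs$TM1$allowed_axes, "z")
  expect_identical(specs$TM2$allowed_axes, c("y", "z"))
  expect_identical(specs$TM3$allowed_axes, c("x", "y", "z"))
  # printed-peptide TM3 variant is one residue shorter, ending Thr237
  alt <- btl_helix_specs(tm3_variant = "peptide")$TM3
  expect_equal(alt$end_resnum, 237)
  expect_equal(nchar(alt$sequence), 18)
})

test_that("ideal helix geometry: span, radius, consecutive CA distance", {
  sp <- helix_spec("H", strrep("A", 20), 1, 20)
  h <- build_ideal_helix(sp)
  expect_equal(nrow(h), 20)
  expect_equal(diff(range(h[, "z"])), 19 * 1.5)
  # every point on the 2.3 A cylinder
  expect_equal(sqrt(h[, 1]^2 + h[, 2]^2), rep(2.3, 20), ignore_attr = TRUE)
  # consecutive CA-CA distance: chord of 100 deg at r = 2.3 plus 1.5 rise
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  d <- sqrt(rowSums(diff(h)^2))
  expect_equal(d, rep(chord, 19), tolerance = 1e-12, ignore_attr = TRUE)
  # single residue: one point at the axial radius
  h1 <- build_ideal_helix(helix_spec("H", "A", 5, 5))
  expect_equal(sqrt(sum(h1[1, 1:2]^2)), 2.3)
  # N-terminus at highest z for extracellular topology, flipped otherwise
  expect_equal(unname(which.max(h[, "z"])), 1)
  hf <- build_ideal_helix(helix_spec("H", strrep("A", 20), 1, 20,
                                     n_term = "cytoplasmic"))
  expect_equal(unname(which.min(hf[, "z"])), 1)
  # fitted axis aligned with +z to well under half a degree
  ax <- tmbundler:::helix_axis(h)
  expect_lt(acos(min(1, ax[3])) * 180 / pi, 0.5)
})

test_that("rigid transforms preserve intra-helix geometry and invert", {
  sp <- helix_spec("H", strrep("G", 15), 1, 15)
  h <- build_ideal_helix(sp)
  expect_equal(apply_transform(h, rigid_transform(), sp), h)
  tz <- rigid_transform(translation = c(0, 0, 3))
  expect_equal(apply_transform(h, tz, sp)[, "z"], h[, "z"] + 3,
               ignore_attr = TRUE)
  set.seed(1)
  for (k in 1:5) {
    t <- rigid_transform(axial_rotation = runif(1, 0, 360),
                         tilt_polar = runif(1, 0, 40),
                         tilt_azimuth = runif(1, 0, 360),
                         translation = rnorm(3))
    ht <- apply_transform(h, t)
    expect_equal(as.matrix(dist(ht)), as.matrix(dist(h)),
                 tolerance = 1e-9)
    # undo: -translation, opposite tilt, -axial rotation
    back <- apply_transform(ht, rigid_transform(translation = -t$translation))
    back <- apply_transform(back, rigid_transform(
      tilt_polar = t$tilt_polar, tilt_azimuth = t$tilt_azimuth + 180))
    back <- apply_transform(back, rigid_transform(
      axial_rotation = -t$axial_rotation))
    expect_equal(back, h, tolerance = 1e-9)
  }
})

test_that("translations on forbidden axes are rejected", {
  sp <- helix_spec("H", strrep("A", 10), 1, 10, allowed_axes = "z")
  h <- build_ideal_helix(sp)
  expect_error(
    apply_transform(h, rigid_transform(translation = c(1, 0, 0)), sp),
    "forbidden axis")
  expect_silent(
    apply_transform(h, rigid_transform(translation = c(0, 0, 2)), sp))
})

test_that("motif scan finds the dimerization motifs at the right residues", {
  specs <- btl_helix_specs()
  m2 <- scan_motif(specs$TM2, "AxxxG")
  expect_equal(m2$start_resnum, 88)
  expect_equal(m2$end_resnum, 92)
  m3 <- scan_motif(specs$TM3, "GxxxxxxA")
  expect_equal(m3$start_resnum, 226)
  expect_equal(m3$end_resnum, 233)
  expect_equal(nrow(scan_motif("AAAA", "AxxxG", 1)), 0)
  # overlapping matches are all reported
  ov <- scan_motif("GAAAGAAAG", "GxxxG")
  expect_equal(ov$start_resnum, c(1, 5))
  # pattern longer than the sequence can never match
  expect_equal(nrow(scan_motif("AG", "AxxxG")), 0)
  expect_error(scan_motif("AAAA", "AxQxG"), "wildcard")
})

test_that("helix pair enumeration gives all unordered pairs", {
  p <- enumerate_helix_pairs(btl_helix_specs())
  expect_equal(nrow(p), choose(4, 2))
  expect_false(any(duplicated(paste(p$i, p$j))))
})
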