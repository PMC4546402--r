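# Scoring terms guiding bundle sampling. All penalty terms are >= 0 and
# vanish on a well-packed reference bundle; the packing and pair-potential
# terms are the (negative) favourable contributions.

# Kyte-Doolittle hydropathy, used for the default residue-contact potential
KD_HYDRO <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Default residue-pair contact potential
#'
#' A transparent stand-in for a knowledge-based statistical contact
#' potential: the energy of a residue-residue contact is the negated,
#' scaled sum of the two Kyte-Doolittle hydropathies, so that burying
#' hydrophobic pairs at helix interfaces is favourable. Fully replaceable
#' by any 20 x 20 matrix with one-letter row/column names.
#'
#' @param scale Multiplier applied to `-(h_i + h_j)`.
#' @return 20 x 20 numeric matrix, dimnames the one-letter amino acids.
#' @export
default_pair_potential <- function(scale = 0.1) {
  -scale * outer(KD_HYDRO, KD_HYDRO, "+")
}

#' Restraint set for bundle sampling
#'
#' Collects every scoring term used to guide and rank bundle
#' conformations: assembly diameter, per-helix tilt and membrane depth,
#' excluded volume, contact packing, predicted helix-helix interaction and
#' residue-contact restraints, and a residue-type contact potential.
#'
#' Default interaction pairs are TM2-TM3 and TM1-TM4; default contact
#' restraints are the five predicted contacts with certainty > 0.75:
#' Thr81-Gln223 (1.00), Thr81-Cys224 (0.96), Pro85-Val222 (0.82),
#' Cys76-Ala225 (0.81), His43-Pro258 (0.79).
#'
#' @param diameter_target Target assembly diameter, Angstrom.
#' @param membrane_thickness Hydrophobic slab thickness, Angstrom.
#' @param clash_distance Inter-helix CA clash threshold, Angstrom.
#' @param contact_window Two-element numeric: CA-CA distance window
#'   counted as a packing contact, Angstrom.
#' @param interaction_pairs `data.frame(i, j, upper, weight)`: flat-bottom
#'   restraints on the inter-axis distance of predicted interacting pairs.
#' @param contact_restraints `data.frame(resi, resj, upper, certainty)`:
#'   certainty-weighted flat-bottom restraints on residue CA-CA distances.
#' @param pair_potential_table 20 x 20 residue-type contact energy matrix.
#' @param weights Named numeric: per-term multipliers (`diameter`,
#'   `tilt_depth`, `excluded_volume`, `packing`, `interaction`,
#'   `pair_potential`). All default to 1.
#' @param crossing_angle_max Analysis-time hard filter on the absolute
#'   inter-helix crossing angle, degrees.
#' @return Object of class `restraint_set`.
#' @export
restraint_set <- function(diameter_target = 26,
                          membrane_thickness = 30,
                          clash_distance = 4.0,
                          contact_window = c(4.0, 6.5),
                          interaction_pairs = data.frame(
                            i = c("TM2", "TM1"), j = c("TM3", "TM4"),
                            upper = 10.4, weight = 1,
                            stringsAsFactors = FALSE),
                          contact_restraints = data.frame(
                            resi = c(81, 81, 85, 76, 43),
                            resj = c(223, 224, 222, 225, 258),
                            upper = 8,
                            certainty = c(1.00, 0.96, 0.82, 0.81, 0.79)),
                          pair_potential_table = default_pair_potential(),
                          weights = NULL,
                          crossing_angle_max = 40) {
  w <- c(diameter = 1, tilt_depth = 1, excluded_volume = 1, packing = 1,
         interaction = 1, pair_potential = 1)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), names(w))
    if (length(bad)) stop("unknown weight(s): ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  if (any(w < 0)) stop("weights must be >= 0")
  if (!is.null(contact_restraints) && nrow(contact_restraints) &&
      (any(contact_restraints$certainty <= 0) ||
       any(contact_restraints$certainty > 1)))
    stop("contact certainties must lie in (0, 1]")
  stopifnot(length(contact_window) == 2, contact_window[1] < contact_window[2])
  structure(list(diameter_target = diameter_target,
                 membrane_thickness = membrane_thickness,
                 clash_distance = clash_distance,
                 contact_window = contact_window,
                 interaction_pairs = interaction_pairs,
                 contact_restraints = contact_restraints,
                 pair_potential_table = pair_potential_table,
                 weights = w,
                 crossing_angle_max = crossing_angle_max,
                 helix_radius = 2.3),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf(paste0("<restraint_set> diameter %g A, membrane %g A, clash %g A,",
                     " contact window [%g, %g] A\n"),
              x$diameter_target, x$membrane_thickness, x$clash_distance,
              x$contact_window[1], x$contact_window[2]))
  cat(sprintf("  %d interaction pair(s), %d contact restraint(s)\n",
              NROW(x$interaction_pairs), NROW(x$contact_restraints)))
  invisible(x)
}

#' Assembly diameter penalty
#'
#' The assembly diameter is the largest xy-distance between helix
#' midpoints plus two helix radii; diameters beyond the target are
#' penalised harmonically.
#'
#' @param conf A `bundle_conformation`.
#' @param rs A [restraint_set()].
#' @return Non-negative penalty (before the term weight).
#' @export
diameter_score <- function(conf, rs = restraint_set()) {
  mids <- helix_midpoints(conf)[, 1:2, drop = FALSE]
  if (nrow(mids) < 2) stop("diameter_score needs at least 2 helices")
  D <- max(stats::dist(mids)) + 2 * rs$helix_radius
  max(0, D - rs$diameter_target)^2
}

# inter-helix CA pair distances, as a list of matrices per helix pair
inter_helix_pairs <- function(conf) {
  nh <- length(conf$helices)
  out <- list()
  for (a in seq_len(nh - 1)) for (b in seq((a + 1), nh)) {
    out[[length(out) + 1]] <- list(
      a = a, b = b,
      d = cross_dist(conf$helices[[a]]$xyz, conf$helices[[b]]$xyz))
  }
  out
}

#' Excluded-volume (clash) penalty
#'
#' Harmonic penalty on every inter-helix CA pair closer than the clash
#' distance.
#' @inheritParams diameter_score
#' @return Non-negative penalty.
#' @export
excluded_volume_score <- function(conf, rs = restraint_set()) {
  s <- 0
  for (p in inter_helix_pairs(conf)) {
    v <- rs$clash_distance - p$d
    s <- s + sum(pmax(0, v)^2)
  }
  s
}

#' Packing reward
#'
#' Minus the number of inter-helix CA pairs whose distance falls inside
#' the contact window; tighter (well-packed) bundles score lower.
#' @inheritParams diameter_score
#' @return Non-positive value.
#' @export
packing_score <- function(conf, rs = restraint_set()) {
  n <- 0
  for (p in inter_helix_pairs(conf))
    n <- n + sum(p$d >= rs$contact_window[1] & p$d <= rs$contact_window[2])
  -n
}

#' Tilt and membrane-depth penalty
#'
#' Per helix, the maximum tilt is `acos(min(1, thickness / L))`, so only
#' helices longer than the membrane is thick may tilt (to bury their
#' excess length); tilts beyond the maximum are penalised harmonically.
#' The depth term penalises failure of the helix's axial z-span
#' (`z_mid +/- (L/2) cos(theta)`) to cover the hydrophobic slab
#' `[-thickness/2, +thickness/2]`: shortfall at either face is penalised
#' harmonically, which also leaves exactly `L cos(theta) - thickness` of
#' slack for z-translation of a longer helix before any penalty.
#'
#' @inheritParams diameter_score
#' @return Non-negative penalty.
#' @export
tilt_depth_score <- function(conf, rs = restraint_set()) {
  s <- 0
  half <- rs$membrane_thickness / 2
  for (h in conf$helices) {
    L <- helix_axial_length(h$xyz)
    ax <- helix_axis(h$xyz)
    cos_tilt <- min(1, max(-1, ax[3]))
    tilt <- acos(cos_tilt) * 180 / pi
    tilt_max <- acos(min(1, rs$membrane_thickness / L)) * 180 / pi
    if (tilt > tilt_max) s <- s + (tilt - tilt_max)^2
    mid_z <- mean(h$xyz[, 3])
    z_top <- mid_z + L / 2 * cos_tilt
    z_bot <- mid_z - L / 2 * cos_tilt
    s <- s + max(0, half - z_top)^2 + max(0, z_bot + half)^2
  }
  s
}

# distance between two helix axes, as the xy distance of their midpoints
# (membrane helices are near-vertical, so the midpoint projection is the
# axis position in the membrane plane)
axis_distance <- function(conf, i, j) {
  m <- helix_midpoints(conf)
  sqrt(sum((m[i, 1:2] - m[j, 1:2])^2))
}

#' Helix-helix interaction and residue-contact restraint penalty
#'
#' Flat-bottom harmonic penalties: each predicted interacting helix pair
#' is restrained to an inter-axis distance below its upper bound, and
#' each predicted residue contact to a CA-CA distance below its bound,
#' weighted by the prediction certainty.
#'
#' @inheritParams diameter_score
#' @return Non-negative penalty.
#' @export
interaction_score <- function(conf, rs = restraint_set()) {
  s <- 0
  ip <- rs$interaction_pairs
  for (k in seq_len(NROW(ip))) {
    if (!(ip$i[k] %in% names(conf$helices)) ||
        !(ip$j[k] %in% names(conf$helices))) next
    d <- axis_distance(conf, ip$i[k], ip$j[k])
    s <- s + ip$weight[k] * max(0, d - ip$upper[k])^2
  }
  cr <- rs$contact_restraints
  for (k in seq_len(NROW(cr))) {
    ci <- tryCatch(residue_coord(conf, cr$resi[k]), error = function(e) NULL)
    cj <- tryCatch(residue_coord(conf, cr$resj[k]), error = function(e) NULL)
    if (is.null(ci) || is.null(cj)) next
    d <- sqrt(sum((ci - cj)^2))
    s <- s + cr$certainty[k] * max(0, d - cr$upper[k])^2
  }
  s
}

#' Residue-type contact potential
#'
#' Sums the contact-energy table over all inter-helix residue pairs whose
#' CA-CA distance falls inside the contact window.
#'
#' @inheritParams diameter_score
#' @return Sum of table energies (sign set by the table).
#' @export
pair_potential_score <- function(conf, rs = restraint_set()) {
  tab <- rs$pair_potential_table
  s <- 0
  seqs <- lapply(conf$helices, function(h) strsplit(
    conf$specs[[h$name]]$sequence, "")[[1]])
  nh <- length(conf$helices)
  for (p in inter_helix_pairs(conf)) {
    hit <- which(p$d >= rs$contact_window[1] & p$d <= rs$contact_window[2],
                 arr.ind = TRUE)
    if (nrow(hit))
      s <- s + sum(tab[cbind(seqs[[p$a]][hit[, 1]], seqs[[p$b]][hit[, 2]])])
  }
  s
}

#' Total restraint score with per-term breakdown
#'
#' Weighted sum of all restraint terms. The unweighted per-term values and
#' the weights used are attached as attributes `"breakdown"` and
#' `"weights"`.
#'
#' @inheritParams diameter_score
#' @return Numeric scalar with attributes `breakdown` (named numeric of
#'   weighted per-term contributions) and `weights`.
#' @export
total_score <- function(conf, rs = restraint_set()) {
  terms <- c(diameter = diameter_score(conf, rs),
             tilt_depth = tilt_depth_score(conf, rs),
             excluded_volume = excluded_volume_score(conf, rs),
             packing = packing_score(conf, rs),
             interaction = interaction_score(conf, rs),
             pair_potential = pair_potential_score(conf, rs))
  wterms <- terms * rs$weights[names(terms)]
  structure(sum(wterms), breakdown = wterms, weights = rs$weights)
}
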