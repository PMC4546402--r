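# Seeded generators with known ground truth for every pipeline input.

synthetic_truth <- function(generator, seed, ...) {
  list(generator = generator, seed = seed, params = list(...),
       package = "tmbundler",
       version = as.character(utils::packageVersion("tmbundler")))
}

# corner sets for a label: A at top-left, then clockwise
corners_for_label <- function(label, side) {
  letters4 <- strsplit(label, "")[[1]]
  pos <- default_corners(side)  # TL, TR, BR, BL clockwise
  ord <- match(c("A", "B", "C", "D"), letters4)
  pos[ord, , drop = FALSE]  # row k = xy of helix k (TM1..TM4)
}

#' Generate a synthetic bundle ensemble with planted arrangement labels
#'
#' Draws an arrangement label per conformation, places the four ideal
#' helices on the corners of a square (side drawn uniformly in
#' `side_range`) in the clockwise order the label dictates, and adds
#' isotropic Gaussian jitter to every coordinate. With zero jitter the
#' arrangement classifier recovers every planted label by construction.
#'
#' @param n Number of conformations.
#' @param label_probs Named numeric of sampling probabilities over the
#'   six arrangement labels (default uniform).
#' @param jitter_A Gaussian jitter standard deviation per coordinate,
#'   Angstrom.
#' @param seed Integer seed (mandatory).
#' @param specs Helix definitions.
#' @param side_range Range of the placement-square side, Angstrom.
#' @return List with `ensemble` (a `bundle_ensemble`), `labels`
#'   (character vector of planted labels), `truth` (provenance record).
#' @export
gen_bundle_ensemble <- function(n, label_probs = NULL, jitter_A = 0.3,
                                seed, specs = btl_helix_specs(),
                                side_range = c(9, 11)) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  lv <- enumerate_arrangements()
  if (is.null(label_probs)) label_probs <- stats::setNames(rep(1 / 6, 6), lv)
  stopifnot(all(names(label_probs) %in% lv))
  template <- build_bundle(specs)
  natoms <- nrow(bundle_map(template))
  xyz <- matrix(NA_real_, n, 3 * natoms)
  labels <- character(n)
  if (n > 0) {
    labels <- sample(names(label_probs), n, replace = TRUE,
                     prob = label_probs)
    for (i in seq_len(n)) {
      side <- stats::runif(1, side_range[1], side_range[2])
      # random axial spin per helix so residue-level distances track the
      # axis separations on average rather than a fixed radial phase
      spins <- lapply(seq_along(specs), function(k)
        rigid_transform(axial_rotation = stats::runif(1, 0, 360)))
      names(spins) <- names(specs)
      conf <- build_bundle(specs, centers = corners_for_label(labels[i], side),
                           transforms = spins)
      co <- bundle_coords(conf)
      co <- co + stats::rnorm(length(co), 0, jitter_A)
      xyz[i, ] <- as.vector(t(co))
    }
  }
  ens <- structure(list(xyz = xyz, scores = numeric(n),
                        transforms = vector("list", n),
                        map = bundle_map(template), specs = specs,
                        template = template,
                        acceptance_rate = NA_real_, config = NULL),
                   class = "bundle_ensemble")
  list(ensemble = ens, labels = labels,
       truth = synthetic_truth("gen_bundle_ensemble", seed, n = n,
                               jitter_A = jitter_A,
                               label_probs = as.list(label_probs)))
}

#' Generate a synthetic ensemble with planted cluster structure
#'
#' Builds `k` reference conformations separated by rigid global
#' translations of `separation_A` Angstrom (which is exactly their
#' pairwise RMSD), then surrounds each with Gaussian-jittered copies.
#'
#' @param k Number of planted clusters.
#' @param separation_A RMSD between reference conformations, Angstrom.
#' @param spread_A Per-coordinate Gaussian jitter inside a cluster,
#'   Angstrom (two copies then differ by about `sqrt(6) * spread_A`
#'   RMSD).
#' @param n_per_cluster Copies per cluster.
#' @param seed Integer seed (mandatory).
#' @param specs Helix definitions.
#' @return List with `ensemble`, `cluster_ids` (integer vector of
#'   planted ids), `truth`.
#' @export
gen_clustered_confs <- function(k, separation_A = 20, spread_A = 0.5,
                                n_per_cluster = 10, seed,
                                specs = btl_helix_specs()) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  template <- build_bundle(specs)
  base <- as.vector(t(bundle_coords(template)))
  natoms <- length(base) / 3
  n <- k * n_per_cluster
  xyz <- matrix(NA_real_, n, length(base))
  ids <- rep(seq_len(k), each = n_per_cluster)
  for (i in seq_len(n)) {
    ref <- base
    # translate cluster c by (c-1)*separation along x: RMSD = separation
    ref[seq(1, length(ref), by = 3)] <-
      ref[seq(1, length(ref), by = 3)] + (ids[i] - 1) * separation_A
    xyz[i, ] <- ref + stats::rnorm(length(ref), 0, spread_A)
  }
  ens <- structure(list(xyz = xyz, scores = numeric(n),
                        transforms = vector("list", n),
                        map = bundle_map(template), specs = specs,
                        template = template,
                        acceptance_rate = NA_real_, config = NULL),
                   class = "bundle_ensemble")
  list(ensemble = ens, cluster_ids = ids,
       truth = synthetic_truth("gen_clustered_confs", seed, k = k,
                               separation_A = separation_A,
                               spread_A = spread_A,
                               n_per_cluster = n_per_cluster))
}

#' Generate a synthetic 15N relaxation dataset
#'
#' Computes R1, R2 and NOE for each residue from the isotropic
#' model-free spectral density at the given ground-truth parameters and
#' applies multiplicative Gaussian noise
#' (`rate * (1 + noise_frac * rnorm)`), the form in which relaxation
#' uncertainties are usually reported.
#'
#' @param params `data.frame` with columns `residue`, `S2`, `tau_e`
#'   (seconds).
#' @param tau_m Shared overall correlation time, seconds.
#' @param field Magnetic field, Tesla.
#' @param noise_frac Relative noise level (0 = exact rates).
#' @param seed Integer seed (mandatory).
#' @return List with `data` (`data.frame(residue, R1, R1_err, R2,
#'   R2_err, NOE, NOE_err)`), `truth`.
#' @export
gen_relaxation <- function(params, tau_m, field = 18.8, noise_frac = 0.02,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(all(c("residue", "S2", "tau_e") %in% names(params)))
  set.seed(seed)
  const <- nmr_constants(field)
  rates <- t(vapply(seq_len(nrow(params)), function(i)
    predict_rates(params$S2[i], params$tau_e[i], tau_m, const = const),
    numeric(3)))
  noisy <- rates * (1 + noise_frac * stats::rnorm(length(rates)))
  data <- data.frame(residue = params$residue,
                     R1 = noisy[, 1], R1_err = abs(noise_frac * rates[, 1]),
                     R2 = noisy[, 2], R2_err = abs(noise_frac * rates[, 2]),
                     NOE = noisy[, 3], NOE_err = abs(noise_frac * rates[, 3]),
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = synthetic_truth("gen_relaxation", seed,
                               params = params, tau_m = tau_m,
                               field = field, noise_frac = noise_frac))
}

#' Generate a synthetic FRET emission-ratio titration
#'
#' Ratios from the exact 1:1 binding isotherm ([binding_model()]) with
#' multiplicative Gaussian noise.
#'
#' @param Kd Ground-truth dissociation constant, uM.
#' @param D_total Fixed partner concentration, uM.
#' @param conc_grid Titrant concentrations, uM (strictly increasing).
#' @param r_free,r_bound Ratio endpoints.
#' @param noise_frac Relative noise level.
#' @param seed Integer seed (mandatory).
#' @return List with `data` (`data.frame(conc_uM, ratio, err)`),
#'   `truth`.
#' @export
gen_titration <- function(Kd, D_total = 50,
                          conc_grid = seq(0, 1000, length.out = 12),
                          r_free = 1.0, r_bound = 0.3, noise_frac = 0.03,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  r <- binding_model(Kd, D_total, conc_grid, r_free, r_bound)
  noisy <- r * (1 + noise_frac * stats::rnorm(length(r)))
  data <- data.frame(conc_uM = conc_grid, ratio = noisy,
                     err = pmax(abs(noise_frac * r), 1e-12))
  list(data = data,
       truth = synthetic_truth("gen_titration", seed, Kd = Kd,
                               D_total = D_total, r_free = r_free,
                               r_bound = r_bound, noise_frac = noise_frac))
}

#' Write a synthetic-truth sidecar next to a data file
#'
#' Every generator returns a `truth` record; this helper serialises it
#' as JSON alongside the file it describes (`<file>.truth.json`).
#'
#' @param truth A truth record from one of the generators.
#' @param data_file Path of the data file the record describes.
#' @return The sidecar path, invisibly.
#' @export
write_truth_sidecar <- function(truth, data_file) {
  path <- paste0(data_file, ".truth.json")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
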