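# Metropolis Monte Carlo over rigid-body bundle configurations.

#' Monte Carlo sampling configuration
#'
#' @param n_steps Total number of MC steps per restart. When
#'   `temperatures` is supplied as a schedule data.frame its `n_steps`
#'   column takes precedence and the total is their sum.
#' @param record_stride Record every `record_stride`-th visited
#'   conformation.
#' @param temperatures Either `NULL` (default: a geometric annealing
#'   ladder from `t_hi` to `t_lo` over `n_rungs` rungs splitting
#'   `n_steps` evenly), a numeric vector of temperatures (steps split
#'   evenly), or a `data.frame(temperature, n_steps)`.
#' @param t_hi,t_lo,n_rungs Parameters of the default geometric ladder.
#' @param axial_rotation_max Move amplitude: axial rotation, degrees.
#' @param tilt_step_max Move amplitude: tilt-vector perturbation, degrees.
#' @param translation_step_max Move amplitude: translation, Angstrom.
#' @param n_restarts Number of independent restarts; each re-randomises
#'   the initial transforms from the same seeded stream.
#' @param seed Integer seed; mandatory, there are no unseeded runs.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_steps = 10000, record_stride = 10,
                      temperatures = NULL, t_hi = 5, t_lo = 0.2,
                      n_rungs = 10,
                      axial_rotation_max = 30, tilt_step_max = 5,
                      translation_step_max = 2,
                      n_restarts = 1, seed) {
  if (missing(seed) || is.null(seed))
    stop("mc_config: a seed is mandatory; unseeded runs are not supported")
  if (is.null(temperatures)) {
    temps <- exp(seq(log(t_hi), log(t_lo), length.out = n_rungs))
    schedule <- data.frame(temperature = temps,
                           n_steps = diff(floor(seq(0, n_steps,
                                                    length.out = n_rungs + 1))))
  } else if (is.data.frame(temperatures)) {
    stopifnot(all(c("temperature", "n_steps") %in% names(temperatures)))
    schedule <- temperatures[c("temperature", "n_steps")]
  } else {
    schedule <- data.frame(temperature = temperatures,
                           n_steps = diff(floor(seq(0, n_steps,
                                                    length.out = length(temperatures) + 1))))
  }
  if (any(schedule$temperature <= 0)) stop("temperatures must be > 0")
  if (any(c(axial_rotation_max, tilt_step_max, translation_step_max) < 0))
    stop("move amplitudes must be >= 0")
  structure(list(schedule = schedule,
                 n_steps = sum(schedule$n_steps),
                 record_stride = as.integer(record_stride),
                 axial_rotation_max = axial_rotation_max,
                 tilt_step_max = tilt_step_max,
                 translation_step_max = translation_step_max,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "mc_config")
}

runif1 <- function(a) stats::runif(1, -a, a)

#' Propose a single Monte Carlo move
#'
#' Picks one helix uniformly at random and one move type uniformly from
#' axial rotation, tilt, and translation along one of the helix's allowed
#' axes, then perturbs the corresponding transform component by a uniform
#' draw within the configured amplitude. Tilt is perturbed as a 2-D tilt
#' vector `polar * (cos az, sin az)`, which keeps the polar angle
#' non-negative and treats all tilt directions symmetrically. Axes outside
#' the helix's `allowed_axes` are never perturbed.
#'
#' @param conf A `bundle_conformation` (carrying its base coordinates and
#'   current transforms).
#' @param config An [mc_config()]; only the amplitudes are used.
#' @return The perturbed `bundle_conformation`.
#' @export
propose_move <- function(conf, config) {
  k <- sample.int(length(conf$helices), 1)
  nm <- names(conf$helices)[k]
  sp <- conf$specs[[nm]]
  t <- conf$transforms[[nm]]
  type <- sample.int(3, 1)  # 1 axial, 2 tilt, 3 translation
  if (type == 1) {
    t$axial_rotation <- (t$axial_rotation +
                           runif1(config$axial_rotation_max)) %% 360
  } else if (type == 2) {
    az <- t$tilt_azimuth * pi / 180
    v <- t$tilt_polar * c(cos(az), sin(az)) +
      c(runif1(config$tilt_step_max), runif1(config$tilt_step_max))
    t$tilt_polar <- sqrt(sum(v^2))
    t$tilt_azimuth <- if (t$tilt_polar > 0) atan2(v[2], v[1]) * 180 / pi else 0
  } else {
    ax <- sp$allowed_axes[sample.int(length(sp$allowed_axes), 1)]
    i <- match(ax, c("x", "y", "z"))
    t$translation[i] <- t$translation[i] + runif1(config$translation_step_max)
  }
  set_helix_transform(conf, nm, t)
}

#' Run Metropolis Monte Carlo sampling of a helix bundle
#'
#' Samples bundle configurations under a restraint score with a
#' varying-temperature (annealing) schedule. Moves are accepted with the
#' Metropolis criterion `min(1, exp(-dE/T))`. Every
#' `record_stride`-th visited conformation is recorded. Restarts
#' re-randomise the initial per-helix transforms (axial rotation uniform
#' over the full circle, tilt polar uniform up to 10 degrees, azimuth
#' uniform, translations zero) from the same seeded RNG stream, so a run is fully
#' reproducible from `(seed, config)`.
#'
#' @param initial A `bundle_conformation` from [build_bundle()].
#' @param restraints A [restraint_set()] scored via [total_score()], or a
#'   `function(conf) -> numeric` custom score.
#' @param config An [mc_config()].
#' @param randomize_start Logical: draw randomized initial transforms at
#'   the start of every restart (default `TRUE`; set `FALSE` to start
#'   from `initial` as given, still re-used at each restart).
#' @return Object of class `bundle_ensemble`: list with `xyz` (matrix,
#'   one row per recorded conformation, flattened x,y,z triplets),
#'   `scores`, `transforms` (list of per-record transform lists), `map`
#'   (atom map: helix, resno), `specs`, `template` (the initial
#'   conformation), `acceptance_rate`, `config`.
#' @export
run_mc <- function(initial, restraints, config, randomize_start = TRUE) {
  stopifnot(inherits(initial, "bundle_conformation"),
            inherits(config, "mc_config"))
  score_fn <- if (is.function(restraints)) restraints
  else function(conf) as.numeric(total_score(conf, restraints))
  set.seed(config$seed)
  n_rec_per <- config$n_steps %/% config$record_stride
  n_rec <- n_rec_per * config$n_restarts
  natoms <- sum(vapply(initial$helices, function(h) nrow(h$xyz), integer(1)))
  xyz <- matrix(NA_real_, n_rec, 3 * natoms)
  scores <- numeric(n_rec)
  transforms <- vector("list", n_rec)
  n_acc <- 0L; n_tot <- 0L; rec <- 0L
  for (restart in seq_len(config$n_restarts)) {
    conf <- initial
    if (randomize_start) {
      for (nm in names(conf$helices)) {
        t <- rigid_transform(
          axial_rotation = stats::runif(1, 0, 360),
          tilt_polar = stats::runif(1, 0, 10),
          tilt_azimuth = stats::runif(1, 0, 360))
        conf <- set_helix_transform(conf, nm, t)
      }
    }
    e <- score_fn(conf)
    if (!is.finite(e))
      stop("run_mc: non-finite score for the initial conformation")
    step_in_run <- 0L
    for (r in seq_len(nrow(config$schedule))) {
      temp <- config$schedule$temperature[r]
      for (s in seq_len(config$schedule$n_steps[r])) {
        cand <- propose_move(conf, config)
        e_new <- score_fn(cand)
        if (!is.finite(e_new))
          stop("run_mc: non-finite score at restart ", restart,
               ", step ", step_in_run + 1L)
        n_tot <- n_tot + 1L
        if (e_new <= e || stats::runif(1) < exp(-(e_new - e) / temp)) {
          conf <- cand; e <- e_new; n_acc <- n_acc + 1L
        }
        step_in_run <- step_in_run + 1L
        if (step_in_run %% config$record_stride == 0L && rec < n_rec) {
          rec <- rec + 1L
          xyz[rec, ] <- as.vector(t(bundle_coords(conf)))
          scores[rec] <- e
          transforms[[rec]] <- conf$transforms
        }
      }
    }
  }
  structure(list(xyz = xyz[seq_len(rec), , drop = FALSE],
                 scores = scores[seq_len(rec)],
                 transforms = transforms[seq_len(rec)],
                 map = bundle_map(initial),
                 specs = initial$specs,
                 template = initial,
                 acceptance_rate = if (n_tot) n_acc / n_tot else NA_real_,
                 config = config),
            class = "bundle_ensemble")
}

#' @export
print.bundle_ensemble <- function(x, ...) {
  cat(sprintf("<bundle_ensemble> %d conformations x %d atoms, score range [%.3g, %.3g]\n",
              nrow(x$xyz), nrow(x$map),
              if (length(x$scores)) min(x$scores) else NA,
              if (length(x$scores)) max(x$scores) else NA))
  invisible(x)
}

#' Number of conformations in an ensemble
#' @param x A `bundle_ensemble`.
#' @export
length.bundle_ensemble <- function(x) nrow(x$xyz)

#' Extract one conformation of an ensemble as a bundle
#'
#' @param ens A `bundle_ensemble`.
#' @param i Conformation index.
#' @return A `bundle_conformation` with the recorded coordinates.
#' @export
ensemble_conformation <- function(ens, i) {
  stopifnot(i >= 1, i <= nrow(ens$xyz))
  conf <- ens$template
  m <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
  off <- 0L
  for (nm in names(conf$helices)) {
    n <- nrow(conf$helices[[nm]]$xyz)
    block <- m[off + seq_len(n), , drop = FALSE]
    dimnames(block) <- dimnames(conf$helices[[nm]]$xyz)
    conf$helices[[nm]]$xyz <- block
    off <- off + n
  }
  if (length(ens$transforms) >= i && !is.null(ens$transforms[[i]]))
    conf$transforms <- ens$transforms[[i]]
  conf$score <- if (length(ens$scores) >= i) ens$scores[i] else NULL
  conf
}
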