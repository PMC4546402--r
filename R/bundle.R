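# Bundle conformations: a named list of helices, each carrying current
# coordinates, the base (untransformed) coordinates it was built from, the
# residue numbers, and the rigid transform that produced the current state.
# The membrane frame is fixed: z = membrane normal, +z = extracellular.

default_corners <- function(side = 10) {
  s <- side / 2
  rbind(c(-s, s), c(s, s), c(s, -s), c(-s, -s))  # TL, TR, BR, BL (clockwise)
}

#' Build a four-helix bundle conformation
#'
#' Constructs ideal helices from `specs`, orients each according to its
#' membrane topology, centres each at z = 0 and places the helix axes
#' vertically at the given xy positions. Optional per-helix transforms are
#' then applied.
#'
#' @param specs Named list of [helix_spec()] objects.
#' @param centers `n x 2` matrix of xy axis positions (Angstrom), one row
#'   per helix in the order of `specs`. Default: corners of a square of
#'   side `side`, clockwise from top-left as seen from +z, in spec order.
#' @param side Side of the default placement square (Angstrom).
#' @param transforms Optional named list of [rigid_transform()]s.
#' @return Object of class `bundle_conformation`: list with elements
#'   `helices` (per helix: `name`, `xyz`, `base`, `resno`), `transforms`,
#'   `specs`, `score` (NULL until scored).
#' @export
build_bundle <- function(specs = btl_helix_specs(), centers = NULL,
                         side = 10, transforms = NULL) {
  if (is.null(centers)) centers <- default_corners(side)
  stopifnot(nrow(centers) == length(specs))
  helices <- vector("list", length(specs))
  names(helices) <- names(specs)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    base <- build_ideal_helix(sp)
    # centre the trace so the helix midpoint sits exactly on the given
    # xy position (the raw trace mean is slightly off-axis when the
    # helix does not close an integer number of turns)
    m <- colMeans(base)
    base[, 1] <- base[, 1] - m[1] + centers[k, 1]
    base[, 2] <- base[, 2] - m[2] + centers[k, 2]
    helices[[k]] <- list(name = sp$name, xyz = base, base = base,
                         resno = helix_resnums(sp))
  }
  if (is.null(transforms)) {
    transforms <- lapply(specs, function(s) rigid_transform())
    names(transforms) <- names(specs)
  }
  conf <- structure(list(helices = helices, transforms = transforms,
                         specs = specs, score = NULL),
                    class = "bundle_conformation")
  for (nm in names(transforms)) conf <- set_helix_transform(conf, nm, transforms[[nm]])
  conf
}

# replace one helix's transform and rebuild its coordinates from base
set_helix_transform <- function(conf, helix, t) {
  sp <- conf$specs[[helix]]
  conf$helices[[helix]]$xyz <- apply_transform(conf$helices[[helix]]$base, t, sp)
  conf$transforms[[helix]] <- t
  conf$score <- NULL
  conf
}

#' @export
print.bundle_conformation <- function(x, ...) {
  cat(sprintf("<bundle_conformation> %d helices (%s), %d CA atoms%s\n",
              length(x$helices), paste(names(x$helices), collapse = ", "),
              sum(vapply(x$helices, function(h) nrow(h$xyz), integer(1))),
              if (is.null(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' Stack all C-alpha coordinates of a bundle
#' @param conf A `bundle_conformation`.
#' @return `N x 3` matrix, helices concatenated in list order.
#' @export
bundle_coords <- function(conf) {
  do.call(rbind, lapply(conf$helices, function(h) h$xyz))
}

# atom map: helix name + residue number per stacked row
bundle_map <- function(conf) {
  data.frame(
    helix = rep(names(conf$helices),
                vapply(conf$helices, function(h) nrow(h$xyz), integer(1))),
    resno = unlist(lapply(conf$helices, function(h) h$resno), use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Helix midpoints of a bundle
#' @param conf A `bundle_conformation`.
#' @return `n x 3` matrix of helix centroid coordinates.
#' @export
helix_midpoints <- function(conf) {
  t(vapply(conf$helices, function(h) colMeans(h$xyz), numeric(3)))
}

# Axis of one helix trace (unit vector, oriented toward +z when possible).
# For n >= 5 the axis is the smallest principal component of the
# second-difference vectors: for a helical trace the second differences
# lie in the plane perpendicular to the axis (the axial coordinate is
# linear in residue index), so their null direction is the axis exactly,
# free of the wobble that biases a direct PCA of the points when the
# trace does not close an integer number of turns.
helix_axis <- function(xyz) {
  n <- nrow(xyz)
  v <- if (n >= 5) {
    d2 <- diff(xyz, differences = 2)
    e <- eigen(crossprod(scale(d2, scale = FALSE)), symmetric = TRUE)
    e$vectors[, 3]
  } else if (n >= 2) {
    u <- xyz[n, ] - xyz[1, ]
    u / sqrt(sum(u^2))
  } else c(0, 0, 1)
  if (v[3] < 0) v <- -v
  v
}

# axial extent of the trace along its own principal axis
helix_axial_length <- function(xyz) {
  v <- helix_axis(xyz)
  p <- xyz %*% v
  diff(range(p))
}

#' Look up the C-alpha coordinate of one residue in a bundle
#' @param conf A `bundle_conformation`.
#' @param resno Residue number (UniProt numbering).
#' @param helix Optional helix name to disambiguate.
#' @return Length-3 numeric vector.
#' @export
residue_coord <- function(conf, resno, helix = NULL) {
  hs <- if (is.null(helix)) conf$helices else conf$helices[helix]
  for (h in hs) {
    i <- match(resno, h$resno)
    if (!is.na(i)) return(h$xyz[i, ])
  }
  stop("residue ", resno, " not found",
       if (!is.null(helix)) paste0(" in helix ", helix))
}

# Euclidean cross-distance matrix between two coordinate sets
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
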