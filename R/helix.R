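#' @keywords internal
"_PACKAGE"

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Define a transmembrane helix
#'
#' A `helix_spec` bundles everything the sampler needs to know about one
#' transmembrane (TM) helix: its sequence, its residue numbering, which
#' rigid-body translations it is allowed during sampling, and on which side
#' of the membrane its N-terminus sits.
#'
#' @param name Helix label, e.g. `"TM1"`.
#' @param sequence One-letter amino-acid string (standard 20 letters only).
#' @param start_resnum,end_resnum First and last residue number (1-based,
#'   UniProt numbering). Must satisfy
#'   `end_resnum - start_resnum + 1 == nchar(sequence)`.
#' @param allowed_axes Character vector, subset of `c("x","y","z")`: the
#'   translation axes this helix may move along during Monte Carlo sampling.
#' @param n_term Side of the membrane carrying the N-terminus:
#'   `"extracellular"` (+z) or `"cytoplasmic"` (-z).
#' @return An object of class `helix_spec`.
#' @seealso [btl_helix_specs()] for the built-in four-helix definition,
#'   [build_ideal_helix()] to realise the spec as coordinates.
#' @export
helix_spec <- function(name, sequence, start_resnum, end_resnum,
                       allowed_axes = c("x", "y", "z"),
                       n_term = c("extracellular", "cytoplasmic")) {
  n_term <- match.arg(n_term)
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("helix '", name, "': sequence must be non-empty")
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad))
    stop("helix '", name, "': non-standard amino-acid letter(s): ",
         paste(unique(bad), collapse = ", "))
  if (end_resnum - start_resnum + 1L != nchar(sequence))
    stop("helix '", name, "': residue range ", start_resnum, "-", end_resnum,
         " spans ", end_resnum - start_resnum + 1L, " residues but sequence has ",
         nchar(sequence))
  allowed_axes <- match.arg(allowed_axes, c("x", "y", "z"), several.ok = TRUE)
  structure(
    list(name = name, sequence = sequence,
         start_resnum = as.integer(start_resnum),
         end_resnum = as.integer(end_resnum),
         allowed_axes = allowed_axes, n_term = n_term),
    class = "helix_spec")
}

#' @export
print.helix_spec <- function(x, ...) {
  cat(sprintf("<helix_spec> %s: %s (%d-%d), translations {%s}, N-term %s\n",
              x$name, x$sequence, x$start_resnum, x$end_resnum,
              paste(x$allowed_axes, collapse = ","), x$n_term))
  invisible(x)
}

#' Residue numbers covered by a helix spec
#' @param spec A [helix_spec()].
#' @return Integer vector of residue numbers.
#' @export
helix_resnums <- function(spec) seq.int(spec$start_resnum, spec$end_resnum)

#' Nominal length of an ideal helix in Angstrom
#'
#' `(n_res - 1) * rise`, the axial extent of the C-alpha trace.
#' @param spec A [helix_spec()].
#' @param rise Helical rise per residue in Angstrom.
#' @return Length in Angstrom.
#' @export
helix_length <- function(spec, rise = 1.5) (nchar(spec$sequence) - 1) * rise

#' Built-in helix definitions for the bilitranslocase TM bundle
#'
#' The four predicted transmembrane helices of bilitranslocase (BTL,
#' UniProt O88750): TM1 Phe24-Asp48, TM2 Phe75-Cys94, TM3 Gly220-Tyr238,
#' TM4 Pro254-Ser276. The TM2 and TM3 sequences are those of the
#' experimentally characterised synthetic peptides. TM3 is ambiguous: the
#' characterised 18-mer peptide ends at Thr237 while the stated helix range
#' extends to Tyr238; `tm3_variant` selects between the 19-residue range
#' (default, Tyr appended at 238) and the 18-residue peptide.
#'
#' No experimentally determined sequence is bundled for TM1 and TM4: their
#' sequences here are synthetic placeholders with the functionally
#' constrained residues pinned (His43 in TM1; Pro254, Pro258 and Ser276 in
#' TM4). Replace them via a helix config file for real-sequence work.
#'
#' Allowed translations follow the sampling protocol for this bundle:
#' TM1 only z, TM2 y and z, TM3 and TM4 all three axes. Topology
#' alternates, TM1/TM3 N-terminus extracellular, TM2/TM4 cytoplasmic.
#'
#' @param tm3_variant `"range"` (19 residues, 220-238) or `"peptide"`
#'   (18 residues, 220-237).
#' @return Named list of four [helix_spec()] objects (TM1..TM4).
#' @export
btl_helix_specs <- function(tm3_variant = c("range", "peptide")) {
  tm3_variant <- match.arg(tm3_variant)
  tm3 <- if (tm3_variant == "range")
    helix_spec("TM3", "GSVQCAGLISLPIAIEFTY", 220, 238,
               allowed_axes = c("x", "y", "z"), n_term = "extracellular")
  else
    helix_spec("TM3", "GSVQCAGLISLPIAIEFT", 220, 237,
               allowed_axes = c("x", "y", "z"), n_term = "extracellular")
  list(
    TM1 = helix_spec("TM1", "FLAGVLIASVLGALIGASLHWLIAD", 24, 48,
                     allowed_axes = "z", n_term = "extracellular"),
    TM2 = helix_spec("TM2", "FCLFVATLQSPFSAGVSGLC", 75, 94,
                     allowed_axes = c("y", "z"), n_term = "cytoplasmic"),
    TM3 = tm3,
    TM4 = helix_spec("TM4", "PLIVPGAVLGLIAFSLVGAILWS", 254, 276,
                     allowed_axes = c("x", "y", "z"), n_term = "cytoplasmic"))
}

#' Build an ideal alpha-helix C-alpha trace
#'
#' Places one C-alpha per residue on an ideal alpha-helix: rise 1.5 A per
#' residue, 100 degrees twist per residue, 2.3 A axial radius. The helix
#' axis is +z through the origin and the trace is centred at z = 0. The
#' N-terminus sits at the highest z; if `spec$n_term == "cytoplasmic"` the
#' trace is then flipped by a rigid 180-degree rotation about the x axis
#' (chirality preserved) so the N-terminus points down.
#'
#' @param spec A [helix_spec()].
#' @param rise,twist,radius Helical geometry: rise per residue (A), twist
#'   per residue (degrees), axial radius (A).
#' @return Numeric matrix `n x 3` (columns x, y, z, Angstrom) with
#'   `rownames` the residue numbers.
#' @examples
#' h <- build_ideal_helix(helix_spec("H", "ALAALAALAALAALAALAAL", 1, 20))
#' diff(range(h[, "z"]))  # 19 * 1.5 = 28.5
#' @export
build_ideal_helix <- function(spec, rise = 1.5, twist = 100, radius = 2.3) {
  n <- nchar(spec$sequence)
  i <- seq_len(n) - 1
  # right-handed helix traversed N->C in the -z direction
  theta <- -i * twist * pi / 180
  xyz <- cbind(x = radius * cos(theta),
               y = radius * sin(theta),
               z = ((n - 1) / 2 - i) * rise)
  if (spec$n_term == "cytoplasmic") {
    xyz[, "y"] <- -xyz[, "y"]
    xyz[, "z"] <- -xyz[, "z"]
  }
  rownames(xyz) <- helix_resnums(spec)
  xyz
}

#' Rigid-body transform for one helix
#'
#' @param axial_rotation Rotation about the helix's own (vertical) axis,
#'   degrees.
#' @param tilt_polar Tilt away from the membrane normal, degrees (>= 0).
#' @param tilt_azimuth Direction of the tilt in the membrane plane, degrees.
#' @param translation Length-3 numeric, Angstrom (x, y, z).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(axial_rotation = 0, tilt_polar = 0,
                            tilt_azimuth = 0, translation = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, is.finite(translation),
            is.finite(axial_rotation), is.finite(tilt_polar),
            is.finite(tilt_azimuth), tilt_polar >= 0)
  structure(list(axial_rotation = axial_rotation, tilt_polar = tilt_polar,
                 tilt_azimuth = tilt_azimuth,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# rotation by `deg` about unit axis u (Rodrigues)
rot_axis <- function(u, deg) {
  a <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply a rigid-body transform to a helix trace
#'
#' The transform is applied about the helix midpoint in a fixed order:
#' axial rotation (about the vertical axis through the midpoint), then
#' tilt (rotation by `tilt_polar` away from +z, in the direction given by
#' `tilt_azimuth`), then translation. The operation is rigid: all
#' intra-helix distances are preserved exactly.
#'
#' @param xyz `n x 3` coordinate matrix as from [build_ideal_helix()].
#' @param t A [rigid_transform()].
#' @param spec Optional [helix_spec()]; when given, translation components
#'   on axes outside `spec$allowed_axes` are rejected with an error.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, t, spec = NULL) {
  stopifnot(inherits(t, "rigid_transform"), is.matrix(xyz), ncol(xyz) == 3)
  if (!is.null(spec)) {
    forbidden <- setdiff(c("x", "y", "z"), spec$allowed_axes)
    idx <- match(forbidden, c("x", "y", "z"))
    if (any(t$translation[idx] != 0))
      stop("helix '", spec$name, "': translation on forbidden axis (",
           paste(forbidden[t$translation[idx] != 0], collapse = ","),
           ") not allowed")
  }
  mid <- colMeans(xyz)
  X <- sweep(xyz, 2, mid)
  R <- rot_z(t$axial_rotation)
  if (t$tilt_polar != 0) {
    az <- t$tilt_azimuth * pi / 180
    # tilt toward direction (cos az, sin az): rotate about z x d
    u <- c(-sin(az), cos(az), 0)
    R <- rot_axis(u, t$tilt_polar) %*% R
  }
  out <- X %*% t(R)
  out <- sweep(out, 2, mid + t$translation, "+")
  dimnames(out) <- dimnames(xyz)
  out
}

#' Scan a sequence for a small-residue dimerization motif
#'
#' Searches for GxxxG-type transmembrane dimerization motifs, where fixed
#' positions are small residues (G, A or S) and `x` matches any residue.
#' The helices forming the experimentally supported TM2:TM3 pair carry
#' AxxxG (TM2) and GxxxxxxA (TM3) instances of this family. Matches may
#' overlap.
#'
#' @param sequence One-letter amino-acid string, or a [helix_spec()].
#' @param pattern Motif string over `{A,G,S,x}`, e.g. `"AxxxG"`.
#' @param start_resnum Residue number of the first sequence position
#'   (ignored when `sequence` is a `helix_spec`).
#' @return `data.frame` with columns `start_resnum`, `end_resnum`, `match`;
#'   zero rows when there is no match.
#' @examples
#' tm2 <- btl_helix_specs()$TM2
#' scan_motif(tm2, "AxxxG")  # A88-G92
#' @export
scan_motif <- function(sequence, pattern, start_resnum = 1L) {
  if (inherits(sequence, "helix_spec")) {
    start_resnum <- sequence$start_resnum
    sequence <- sequence$sequence
  }
  pat_chars <- strsplit(pattern, "")[[1]]
  if (!all(pat_chars %in% c("A", "G", "S", "x")))
    stop("pattern may only contain A, G, S and the wildcard x")
  rx <- paste0("(?=", gsub("x", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start_resnum = integer(), end_resnum = integer(),
                      match = character(), stringsAsFactors = FALSE))
  pos <- as.integer(m)
  data.frame(
    start_resnum = start_resnum + pos - 1L,
    end_resnum = start_resnum + pos + nchar(pattern) - 2L,
    match = substring(sequence, pos, pos + nchar(pattern) - 1L),
    stringsAsFactors = FALSE)
}

#' Enumerate the distinct helix pairs of a bundle
#'
#' @param specs List of [helix_spec()] objects.
#' @return `data.frame` with columns `i`, `j` (helix names), one row per
#'   unordered pair; `choose(n, 2)` rows.
#' @export
enumerate_helix_pairs <- function(specs = btl_helix_specs()) {
  nm <- vapply(specs, function(s) s$name, character(1))
  cb <- utils::combn(nm, 2)
  data.frame(i = cb[1, ], j = cb[2, ], stringsAsFactors = FALSE)
}
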