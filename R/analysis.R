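# Ensemble analysis: RMSD clustering, arrangement classification and
# distance summaries for four-helix bundles.

#' Pairwise C-alpha RMSD between two conformations
#'
#' By default the RMSD is computed *without* superposition: the membrane
#' frame is physically fixed (z is the membrane normal) and the relative
#' placement of helices in that frame is exactly what distinguishes
#' bundle arrangements, so superposing would erase the signal. Set
#' `superpose = TRUE` for conventional best-fit RMSD.
#'
#' @param a,b `N x 3` coordinate matrices (same atoms, same order), or
#'   `bundle_conformation` objects.
#' @param superpose Logical; superpose `b` onto `a` (Kabsch) first.
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, superpose = FALSE) {
  if (inherits(a, "bundle_conformation")) a <- bundle_coords(a)
  if (inherits(b, "bundle_conformation")) b <- bundle_coords(b)
  if (nrow(a) != nrow(b))
    stop("atom-count mismatch: ", nrow(a), " vs ", nrow(b))
  if (superpose) {
    ca <- colMeans(a); cb <- colMeans(b)
    A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
    s <- svd(crossprod(B, A))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    B <- B %*% t(R)
    return(sqrt(mean(rowSums((A - B)^2))))
  }
  sqrt(mean(rowSums((a - b)^2)))
}

# all-vs-all RMSD of flattened ensemble rows as a stats::dist object;
# without superposition RMSD is Euclidean distance / sqrt(natoms)
ensemble_rmsd_dist <- function(xyz, natoms, superpose = FALSE) {
  if (!superpose) return(stats::dist(xyz) / sqrt(natoms))
  n <- nrow(xyz)
  m <- matrix(0, n, n)
  confs <- lapply(seq_len(n), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- pairwise_rmsd(confs[[i]], confs[[j]],
                                        superpose = TRUE)
  stats::as.dist(m)
}

#' Cluster a bundle ensemble by pairwise C-alpha RMSD
#'
#' Complete-linkage hierarchical clustering cut at `cutoff` Angstrom, so
#' every intra-cluster pair is within `cutoff` RMSD. The centroid of each
#' cluster is the member minimising the summed RMSD to its co-members
#' (ties broken by lowest index). For ensembles larger than `max_exact` a
#' two-stage scheme is used: greedy leader pre-clustering at `cutoff / 2`
#' followed by exact hierarchical clustering of the leaders (the
#' intra-cluster bound then holds only approximately).
#'
#' @param ens A `bundle_ensemble`, or a plain numeric matrix of flattened
#'   conformations (rows = conformations, columns = x,y,z triplets).
#' @param cutoff RMSD cutoff in Angstrom (default 2).
#' @param superpose Logical; superpose before computing RMSDs (default
#'   `FALSE`, see [pairwise_rmsd()]).
#' @param max_exact Ensemble size above which the two-stage scheme is
#'   used.
#' @return Object of class `clustered_ensemble`: list with `assignment`
#'   (integer vector, cluster id per member), `centroids` (member index
#'   of each cluster's centroid), `n_clusters`, `centroid_scores`,
#'   `centroid_labels` (arrangement label per centroid, when the
#'   ensemble carries four helices), `cutoff`, `ensemble`.
#' @export
cluster_ensemble <- function(ens, cutoff = 2, superpose = FALSE,
                             max_exact = 20000) {
  xyz <- if (inherits(ens, "bundle_ensemble")) ens$xyz else as.matrix(ens)
  n <- nrow(xyz)
  if (n == 0) stop("cannot cluster an empty ensemble")
  natoms <- ncol(xyz) / 3
  if (n <= max_exact) {
    d <- ensemble_rmsd_dist(xyz, natoms, superpose)
    assignment <- if (n == 1) 1L else
      stats::cutree(stats::hclust(d, method = "complete"), h = cutoff)
    dm <- as.matrix(d)
  } else {
    # two-stage: greedy leaders at cutoff/2, then exact on leaders
    leaders <- 1L
    lead_of <- integer(n); lead_of[1] <- 1L
    for (i in 2:n) {
      dl <- sqrt(colMeans((t(xyz[leaders, , drop = FALSE]) - xyz[i, ])^2) * 3)
      j <- which(dl <= cutoff / 2)
      if (length(j)) lead_of[i] <- leaders[j[1]]
      else { leaders <- c(leaders, i); lead_of[i] <- i }
    }
    dL <- ensemble_rmsd_dist(xyz[leaders, , drop = FALSE], natoms, superpose)
    aL <- if (length(leaders) == 1) 1L else
      stats::cutree(stats::hclust(dL, method = "complete"), h = cutoff)
    assignment <- aL[match(lead_of, leaders)]
    dm <- NULL
  }
  ids <- sort(unique(assignment))
  centroids <- vapply(ids, function(cl) {
    members <- which(assignment == cl)
    if (length(members) == 1) return(members)
    if (!is.null(dm)) {
      members[which.min(rowSums(dm[members, members, drop = FALSE]))]
    } else {
      sub <- xyz[members, , drop = FALSE]
      dsub <- as.matrix(ensemble_rmsd_dist(sub, natoms, superpose))
      members[which.min(rowSums(dsub))]
    }
  }, integer(1))
  scores <- if (inherits(ens, "bundle_ensemble") && length(ens$scores))
    ens$scores[centroids] else rep(NA_real_, length(centroids))
  labels <- if (inherits(ens, "bundle_ensemble") &&
                length(ens$specs) == 4) {
    vapply(centroids, function(i)
      classify_arrangement(ensemble_conformation(ens, i)), character(1))
  } else rep(NA_character_, length(centroids))
  structure(list(assignment = as.integer(assignment),
                 centroids = centroids,
                 n_clusters = length(ids),
                 centroid_scores = scores,
                 centroid_labels = labels,
                 cutoff = cutoff, superpose = superpose,
                 ensemble = if (inherits(ens, "bundle_ensemble")) ens else NULL),
            class = "clustered_ensemble")
}

#' @export
print.clustered_ensemble <- function(x, ...) {
  cat(sprintf("<clustered_ensemble> %d members -> %d clusters at %.2g A RMSD cutoff\n",
              length(x$assignment), x$n_clusters, x$cutoff))
  invisible(x)
}

#' Enumerate the six arrangements of a four-helix bundle
#'
#' The cyclic clockwise orders of helices A = TM1, B = TM2, C = TM3,
#' D = TM4 around the bundle axis, read from the extracellular side
#' starting at A. There are `3! = 6` of them.
#'
#' @return Character vector of the six labels.
#' @export
enumerate_arrangements <- function() {
  perms <- list(c("B", "C", "D"), c("B", "D", "C"), c("C", "B", "D"),
                c("C", "D", "B"), c("D", "B", "C"), c("D", "C", "B"))
  sort(vapply(perms, function(p) paste0(c("A", p), collapse = ""), character(1)))
}

#' Classify the arrangement of a four-helix bundle
#'
#' Projects the four helix midpoints onto the membrane (xy) plane and
#' reads their cyclic order clockwise around the midpoint centroid as
#' seen from +z (the extracellular side, looking down with y up),
#' starting at helix A (= TM1, the first helix).
#'
#' @param conf A `bundle_conformation` with four helices, or a `4 x 2`
#'   matrix of xy midpoints (rows in helix order TM1..TM4).
#' @param tol Degeneracy tolerance in Angstrom: midpoints closer than
#'   `tol` to each other or to the centroid are unclassifiable.
#' @return One of the six labels from [enumerate_arrangements()], or
#'   `"unclassifiable"` for degenerate geometry.
#' @export
classify_arrangement <- function(conf, tol = 1e-6) {
  mids <- if (is.matrix(conf)) conf
  else helix_midpoints(conf)[, 1:2, drop = FALSE]
  if (nrow(mids) != 4) stop("classification needs exactly four helices")
  if (min(stats::dist(mids)) < tol) return("unclassifiable")
  ctr <- colMeans(mids)
  rel <- sweep(mids, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  if (any(r < tol)) return("unclassifiable")
  ang <- atan2(rel[, 2], rel[, 1])
  # collinear/coincident-angle midpoints have no defined cyclic order
  if (min(diff(sort(ang)), 2 * pi - diff(range(ang))) < 1e-9)
    return("unclassifiable")
  # clockwise from +z = decreasing counter-clockwise angle; start at A
  ord <- order((ang[1] - ang) %% (2 * pi))
  paste0(c("A", "B", "C", "D")[ord], collapse = "")
}

#' Classify every conformation of an ensemble
#' @param ens A `bundle_ensemble` with four helices.
#' @param tol Passed to [classify_arrangement()].
#' @return Character vector of labels.
#' @export
classify_ensemble <- function(ens, tol = 1e-6) {
  idx <- helix_block_index(ens)
  vapply(seq_len(nrow(ens$xyz)), function(i) {
    m <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
    mids <- t(vapply(idx, function(rows) colMeans(m[rows, , drop = FALSE]),
                     numeric(3)))
    classify_arrangement(mids[, 1:2, drop = FALSE], tol = tol)
  }, character(1))
}

# row indices of each helix block in the stacked atom map
helix_block_index <- function(ens) {
  split(seq_len(nrow(ens$map)), factor(ens$map$helix, unique(ens$map$helix)))
}

#' Tabulate arrangement types over cluster centroids
#'
#' Counts the six arrangement types over all cluster centroids and over
#' the `top_k` best-scoring (lowest-energy) centroids, with the share of
#' the three most populated types in each column.
#'
#' @param clustered A `clustered_ensemble` whose centroids carry labels
#'   and scores.
#' @param top_k Number of top-scoring centroids for the second column.
#' @return Object of class `arrangement_table`: `data.frame` with columns
#'   `arrangement`, `n_all`, `n_top`, ordered by decreasing `n_all`, with
#'   attributes `top3_share_all` (percent of all centroids in the three
#'   most populated types, 1 decimal), `top3_count_top` and
#'   `top3_share_top`.
#' @export
arrangement_table <- function(clustered, top_k = 100) {
  stopifnot(inherits(clustered, "clustered_ensemble"))
  labs <- clustered$centroid_labels
  scores <- clustered$centroid_scores
  keep <- !is.na(labs) & labs != "unclassifiable"
  labs <- labs[keep]; scores <- scores[keep]
  top_k <- min(top_k, length(labs))
  top <- labs[order(scores)][seq_len(top_k)]
  arrangement_counts(table_all = count_labels(labs),
                     table_top = count_labels(top))
}

count_labels <- function(labs) {
  lv <- enumerate_arrangements()
  tab <- table(factor(labs, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' Summarise arrangement counts
#'
#' Builds the ranked arrangement table and top-3 shares directly from
#' per-type counts, e.g. from a previously published run or from
#' [arrangement_table()] internals.
#'
#' @param table_all Named integer vector: conformations per arrangement
#'   type over all centroids.
#' @param table_top Optional named integer vector: counts over the
#'   top-scoring subset.
#' @return An `arrangement_table` (see [arrangement_table()]).
#' @examples
#' counts <- c(ABDC = 1330, ACBD = 862, ADCB = 778, ABCD = 281,
#'             ADBC = 213, ACDB = 56)
#' attr(arrangement_counts(counts), "top3_share_all")  # 84.4
#' @export
arrangement_counts <- function(table_all, table_top = NULL) {
  lv <- enumerate_arrangements()
  n_all <- stats::setNames(integer(6), lv)
  n_all[names(table_all)] <- as.integer(table_all)
  n_top <- stats::setNames(integer(6), lv)
  if (!is.null(table_top)) n_top[names(table_top)] <- as.integer(table_top)
  ord <- order(n_all, decreasing = TRUE)
  df <- data.frame(arrangement = lv[ord], n_all = n_all[ord],
                   n_top = n_top[ord], row.names = NULL,
                   stringsAsFactors = FALSE)
  top3 <- seq_len(min(3, nrow(df)))
  structure(df,
            top3_share_all = round(100 * sum(df$n_all[top3]) /
                                     max(1, sum(df$n_all)), 1),
            top3_count_top = sum(df$n_top[top3]),
            top3_share_top = round(100 * sum(df$n_top[top3]) /
                                     max(1, sum(df$n_top)), 1),
            class = c("arrangement_table", "data.frame"))
}

#' @export
print.arrangement_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("top-3 share: %.1f%% of all; %d of the top-scoring subset\n",
              attr(x, "top3_share_all"), attr(x, "top3_count_top")))
  invisible(x)
}

#' Inter-helix distance statistics per arrangement type
#'
#' For each arrangement label: mean and standard deviation of (i) the
#' CA-CA distance between a marker residue pair (default the central
#' prolines Pro85 in TM2 and Pro231 in TM3) and (ii) the distance between
#' the TM2 and TM3 N-terminal CA atoms, plus the fraction of
#' conformations whose marker distance falls inside `interval`.
#'
#' @param ens A `bundle_ensemble`.
#' @param labels Character vector of arrangement labels, one per
#'   conformation (default: computed via [classify_ensemble()]).
#' @param res_pair Length-2 integer: marker residue numbers in TM2 and
#'   TM3.
#' @param helices Length-2 character: the helices carrying the marker
#'   residues and whose N-termini are measured.
#' @param interval Length-2 numeric: the queried distance interval in
#'   Angstrom.
#' @return `data.frame` with one row per label present: `arrangement`,
#'   `n`, `marker_mean`, `marker_sd`, `nterm_mean`, `nterm_sd`,
#'   `frac_in_interval`.
#' @export
distance_stats <- function(ens, labels = NULL, res_pair = c(85, 231),
                           helices = c("TM2", "TM3"),
                           interval = c(16, 20)) {
  map <- ens$map
  i1 <- which(map$helix == helices[1] & map$resno == res_pair[1])
  i2 <- which(map$helix == helices[2] & map$resno == res_pair[2])
  if (length(i1) != 1 || length(i2) != 1)
    stop("marker residue ", res_pair[1], " (", helices[1], ") or ",
         res_pair[2], " (", helices[2], ") absent from the helix specs")
  h1 <- which(map$helix == helices[1]); h2 <- which(map$helix == helices[2])
  sp1 <- ens$specs[[helices[1]]]; sp2 <- ens$specs[[helices[2]]]
  n1 <- h1[match(sp1$start_resnum, map$resno[h1])]
  n2 <- h2[match(sp2$start_resnum, map$resno[h2])]
  col3 <- function(i) ens$xyz[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  dvec <- function(i, j) sqrt(rowSums((col3(i) - col3(j))^2))
  marker <- dvec(i1, i2)
  nterm <- dvec(n1, n2)
  if (is.null(labels)) labels <- classify_ensemble(ens)
  stopifnot(length(labels) == length(marker))
  out <- lapply(split(seq_along(labels), labels), function(ix) {
    data.frame(n = length(ix),
               marker_mean = mean(marker[ix]), marker_sd = stats::sd(marker[ix]),
               nterm_mean = mean(nterm[ix]), nterm_sd = stats::sd(nterm[ix]),
               frac_in_interval = mean(marker[ix] >= interval[1] &
                                         marker[ix] <= interval[2]))
  })
  res <- do.call(rbind, out)
  data.frame(arrangement = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Signed crossing angle between two helices
#'
#' Fits each helix axis by its first principal component and returns the
#' signed inter-axis crossing angle. The magnitude is the angle between
#' the axis *lines* (in `[0, 90]` degrees; fitted axes are unsigned, so
#' an exactly antiparallel untilted pair has crossing angle 0). The sign
#' is the sign of the triple product of the two axis vectors (both
#' oriented toward +z) with the inter-midpoint vector; it is 0 when the
#' axes are coplanar with the connecting vector.
#'
#' @param xyz_i,xyz_j `n x 3` coordinate matrices of the two helices, or
#'   two helix entries of a `bundle_conformation` (`conf$helices[[k]]`).
#' @return Signed angle in degrees, in `(-90, 90]`.
#' @export
crossing_angle <- function(xyz_i, xyz_j) {
  if (is.list(xyz_i) && !is.null(xyz_i$xyz)) xyz_i <- xyz_i$xyz
  if (is.list(xyz_j) && !is.null(xyz_j$xyz)) xyz_j <- xyz_j$xyz
  u <- helix_axis(xyz_i); v <- helix_axis(xyz_j)
  mag <- acos(min(1, abs(sum(u * v)))) * 180 / pi
  w <- colMeans(xyz_j) - colMeans(xyz_i)
  s <- sign(sum(crossprod_vec(u, v) * w))
  if (s == 0) s <- 1
  s * mag
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Filter ensemble conformations by inter-helix crossing angles
#'
#' Hard analysis-time filter: keeps conformations whose predicted
#' interacting helix pairs all have absolute crossing angles within
#' `max_abs` degrees.
#'
#' @param ens A `bundle_ensemble`.
#' @param pairs `data.frame(i, j)` of helix-name pairs to check (default:
#'   all pairs).
#' @param max_abs Maximum absolute crossing angle, degrees.
#' @return Logical vector: `TRUE` for conformations that pass.
#' @export
filter_crossing_angles <- function(ens, pairs = NULL, max_abs = 40) {
  idx <- helix_block_index(ens)
  if (is.null(pairs)) pairs <- enumerate_helix_pairs(ens$specs)
  vapply(seq_len(nrow(ens$xyz)), function(k) {
    m <- matrix(ens$xyz[k, ], ncol = 3, byrow = TRUE)
    for (r in seq_len(nrow(pairs))) {
      om <- crossing_angle(m[idx[[pairs$i[r]]], , drop = FALSE],
                           m[idx[[pairs$j[r]]], , drop = FALSE])
      if (abs(om) > max_abs) return(FALSE)
    }
    TRUE
  }, logical(1))
}
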