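# Receptive-field estimation from skeleton-to-column proximity: covered
# columns, spherical convex hulls, threshold calibration, and synapse-
# weighted effective fields of downstream neurons.

#' Columns covered by a skeleton
#'
#' A column is covered if any skeleton point lies within `threshold_nm` of
#' its columnar marker in the chosen neuropil layer. Coverage is monotone
#' non-decreasing in the threshold.
#'
#' @param skeleton_points numeric matrix (n x 3) of skeleton node positions
#'   in nm (an SWC point set).
#' @param eye an `eyemap`.
#' @param layer marker layer name (e.g. `"Me"` for medulla dendrites).
#' @param threshold_nm proximity threshold in nm (>= 0).
#' @return character vector of covered column ids (sorted).
#' @export
covered_columns <- function(skeleton_points, eye, layer = "Me",
                            threshold_nm) {
  stopifnot(inherits(eye, "eyemap"), threshold_nm >= 0)
  if (!layer %in% names(eye$markers)) stop("unknown marker layer")
  pts <- as.matrix(skeleton_points)
  if (nrow(pts) == 0) {
    warning("empty skeleton: no columns covered")
    return(character(0))
  }
  stopifnot(ncol(pts) == 3)
  mk <- eye$markers[[layer]]
  # min squared distance marker -> skeleton, via the expanded product
  d2 <- outer(rowSums(mk^2), rowSums(pts^2), `+`) - 2 * tcrossprod(mk, pts)
  mind2 <- apply(d2, 1, min)
  sort(rownames(mk)[mind2 <= threshold_nm^2 + 1e-9])
}

#' Receptive field from a covered-column set
#'
#' Builds the receptive field implied by a set of covered columns: the
#' spherical convex hull of their viewing directions, computed by gnomonic
#' projection of the sphere onto the tangent plane at the covered-set
#' centroid (great circles map to straight lines, so the planar hull is the
#' spherical hull). All eye columns whose directions fall inside the hull
#' belong to the field; its size is their count (units: ommatidial
#' columns), and the centroid is the normalized mean direction.
#'
#' @param covered character vector of covered column ids (non-empty).
#' @param eye an `eyemap`.
#' @return an object of class `receptive_field`: list with `covered`,
#'   `hull_columns` (superset of `covered`), `size`, and `centroid` (unit
#'   3-vector). Errors if the covered set spans more than 150 degrees of
#'   visual angle (gnomonic projection undefined).
#' @export
rf_from_columns <- function(covered, eye) {
  stopifnot(inherits(eye, "eyemap"), length(covered) >= 1)
  covered <- sort(unique(as.character(covered)))
  if (!all(covered %in% eye$column_ids)) stop("unknown column ids")
  dirs <- eye$directions
  cdirs <- dirs[covered, , drop = FALSE]
  centroid <- colMeans(cdirs)
  cn <- sqrt(sum(centroid^2))
  if (cn < 1e-9) stop("covered columns are antipodally balanced; no centroid")
  centroid <- centroid / cn

  cosang <- as.vector(cdirs %*% centroid)
  if (any(acos(pmin(1, cosang)) > 75 * pi / 180)) {
    stop("covered set spans more than 150 degrees: spherical hull undefined")
  }
  if (length(covered) < 3) {
    return(structure(
      list(covered = covered, hull_columns = covered,
           size = length(covered), centroid = centroid),
      class = "receptive_field"
    ))
  }
  # gnomonic projection about the centroid
  basis <- tangent_basis(centroid)
  proj <- function(D) {
    w <- as.vector(D %*% centroid)
    cbind(as.vector(D %*% basis$e1) / w, as.vector(D %*% basis$e2) / w)
  }
  P <- proj(cdirs)
  hull_idx <- chull(P)
  poly <- P[hull_idx, , drop = FALSE]

  allcos <- as.vector(dirs %*% centroid)
  front <- allcos > cos(80 * pi / 180)   # only the visible cap can be inside
  Pall <- proj(dirs[front, , drop = FALSE])
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), Pall)
  hull_columns <- sort(unique(c(covered, rownames(dirs)[front][inside])))
  structure(
    list(covered = covered, hull_columns = hull_columns,
         size = length(hull_columns), centroid = centroid),
    class = "receptive_field"
  )
}

# Orthonormal basis of the tangent plane at a unit vector.
tangent_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf(
    "<receptive_field> %d covered columns, hull size %d\n",
    length(x$covered), x$size
  ))
  invisible(x)
}

#' Calibrate the skeleton-to-column proximity threshold
#'
#' Chooses the proximity threshold maximizing the mean Jaccard overlap
#' between hand-annotated column sets and the covered sets computed at that
#' threshold, over a grid of candidate thresholds. Thresholds are
#' calibrated per neuropil layer (lobula and medulla arbors sit at
#' different distances from their markers). Ties take the smallest
#' threshold.
#'
#' @param ground_truth non-empty list; each element a list with `points`
#'   (skeleton matrix, nm) and `columns` (annotated column ids).
#' @param eye an `eyemap`.
#' @param layer marker layer.
#' @param grid numeric vector of candidate thresholds (nm).
#' @return list with `threshold_nm`, `mean_jaccard` (at the selected
#'   threshold), and `grid_jaccard` (named vector over the grid).
#' @export
calibrate_rf_threshold <- function(ground_truth, eye, layer = "Me",
                                   grid = seq(500, 10000, by = 500)) {
  stopifnot(length(ground_truth) >= 1, length(grid) >= 1, all(grid >= 0))
  grid <- sort(unique(grid))
  jac <- function(a, b) {
    if (length(a) == 0 && length(b) == 0) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }
  mean_j <- vapply(grid, function(thr) {
    mean(vapply(ground_truth, function(g) {
      jac(covered_columns(g$points, eye, layer, thr), g$columns)
    }, numeric(1)))
  }, numeric(1))
  names(mean_j) <- as.character(grid)
  best <- which.max(mean_j)   # which.max takes the first (smallest) on ties
  list(
    threshold_nm = grid[best],
    mean_jaccard = mean_j[[best]],
    grid_jaccard = mean_j
  )
}

#' Effective receptive field of a downstream neuron
#'
#' Composes the receptive field a Kenyon cell inherits from its visual
#' inputs by linearly combining the indicator fields of incident VPN and
#' LVIN receptive fields, weighted by synaptic count. The direct component
#' sums, over VPNs presynaptic to the cell, synapse count times the VPN's
#' hull indicator over columns. The indirect component sums, over incident
#' LVINs, synapse count times the LVIN's own field, where an LVIN's field
#' is the synapse-weighted sum of its VPN inputs' indicators normalized to
#' unit mass (so direct and indirect components are on comparable scales).
#'
#' @param kc_id output neuron id (a column of `direct_matrix` /
#'   `lvin_matrix`).
#' @param direct_matrix `connectivity_matrix`, VPNs x outputs.
#' @param lvin_matrix `connectivity_matrix`, LVINs x outputs (or NULL for
#'   direct-only circuits).
#' @param vpn_to_lvin_matrix `connectivity_matrix`, VPNs x LVINs (or NULL).
#' @param rfs named list of `receptive_field` objects for every
#'   contributing VPN.
#' @param eye an `eyemap` (defines the column axis of the field).
#' @param normalize logical; if `TRUE`, each returned component is scaled
#'   to sum to 1 over columns (when its total mass is positive).
#' @return list with `direct` and `indirect`: named numeric vectors over
#'   all eye columns. A cell with no visual inputs yields all-zero fields
#'   with a message.
#' @export
effective_rf <- function(kc_id, direct_matrix, lvin_matrix = NULL,
                         vpn_to_lvin_matrix = NULL, rfs, eye,
                         normalize = FALSE) {
  stopifnot(inherits(direct_matrix, "connectivity_matrix"),
            inherits(eye, "eyemap"))
  cols <- eye$column_ids
  zero <- setNames(numeric(length(cols)), cols)
  indicator <- function(rf) {
    f <- zero
    f[rf$hull_columns] <- 1
    f
  }

  direct <- zero
  if (kc_id %in% output_ids(direct_matrix)) {
    w <- setNames(direct_matrix$W[, kc_id], rownames(direct_matrix$W))
    for (vpn in names(w)[w > 0]) {
      if (is.null(rfs[[vpn]])) stop("missing receptive field for input ", vpn)
      direct <- direct + w[vpn] * indicator(rfs[[vpn]])
    }
  }

  indirect <- zero
  if (!is.null(lvin_matrix) && kc_id %in% output_ids(lvin_matrix)) {
    stopifnot(inherits(lvin_matrix, "connectivity_matrix"),
              inherits(vpn_to_lvin_matrix, "connectivity_matrix"))
    wl <- setNames(lvin_matrix$W[, kc_id], rownames(lvin_matrix$W))
    for (lvin in names(wl)[wl > 0]) {
      if (!lvin %in% output_ids(vpn_to_lvin_matrix)) next
      wv <- setNames(vpn_to_lvin_matrix$W[, lvin],
                     rownames(vpn_to_lvin_matrix$W))
      field <- zero
      for (vpn in names(wv)[wv > 0]) {
        if (is.null(rfs[[vpn]])) stop("missing receptive field for input ", vpn)
        field <- field + wv[vpn] * indicator(rfs[[vpn]])
      }
      if (sum(field) > 0) field <- field / sum(field)
      indirect <- indirect + wl[lvin] * field
    }
  }

  if (sum(direct) == 0 && sum(indirect) == 0) {
    message("neuron ", kc_id, " has no visual inputs: empty fields")
  }
  if (normalize) {
    if (sum(direct) > 0) direct <- direct / sum(direct)
    if (sum(indirect) > 0) indirect <- indirect / sum(indirect)
  }
  list(direct = direct, indirect = indirect)
}
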