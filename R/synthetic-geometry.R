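# Synthetic geometry: synapse-location clouds for the two morphological
# connection classes, hex-grid eyemaps, and skeletons with planted
# receptive fields.

#' Generate a synthetic synapse-location cloud
#'
#' Emulates the 3-D synapse-location geometry of one pre/post connection:
#'
#' * `"bouton_claw"` — synapses concentrated in a compact bouton wrapped by
#'   a dendritic claw: isotropic Gaussian with sd `scale` (nm) around a
#'   random centre;
#' * `"en_passant"` — synapses strung along an axon: uniform positions along
#'   a straight segment of length `scale` (nm) in a random orientation,
#'   plus a small isotropic jitter (sd `jitter_sd`, default `scale / 100`).
#'
#' For a pure uniform segment of length L, the population variance of the
#' point-to-centroid distances converges to L^2/48, an order of magnitude
#' above a bouton with sd L/20 — the separation the dispersion classifier
#' exploits.
#'
#' @param class `"bouton_claw"` or `"en_passant"`.
#' @param n_synapses number of synapse locations (>= 1).
#' @param scale bouton sd sigma or segment length L, nm (> 0).
#' @param jitter_sd en-passant transverse jitter sd, nm.
#' @param center 3-vector, cloud centre (nm); random within a 1e5 nm box by
#'   default.
#' @param seed integer seed.
#' @return numeric matrix (n_synapses x 3) of locations in nm.
#' @export
generate_synapse_cloud <- function(class = c("bouton_claw", "en_passant"),
                                   n_synapses = 20L, scale = 1000,
                                   jitter_sd = NULL, center = NULL,
                                   seed = 1L) {
  class <- match.arg(class)
  stopifnot(n_synapses >= 1, scale > 0)
  if (is.null(jitter_sd)) jitter_sd <- if (class == "en_passant") scale / 100 else 0
  with_seed(seed, {
    if (is.null(center)) center <- runif(3, 0, 1e5)
    pts <- if (class == "bouton_claw") {
      matrix(rnorm(3 * n_synapses, sd = scale), n_synapses, 3)
    } else {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      t_pos <- runif(n_synapses, -scale / 2, scale / 2)
      outer(t_pos, u) + matrix(rnorm(3 * n_synapses, sd = jitter_sd),
                               n_synapses, 3)
    }
    sweep(pts, 2, center, `+`)
  })
}

# Hex lattice axial coordinates of the n sites closest to the origin
# (deterministic: sorted by radius, then by axial coordinates).
hex_sites <- function(n) {
  r <- 0L
  while (3 * r * (r + 1) + 1 < n * 2) r <- r + 1L  # generous bound
  qs <- -r:r
  grid <- expand.grid(q = qs, s = qs)
  grid$u <- grid$q + grid$s / 2
  grid$v <- grid$s * sqrt(3) / 2
  grid$rad <- sqrt(grid$u^2 + grid$v^2)
  grid <- grid[order(grid$rad, grid$q, grid$s), ]
  grid[seq_len(n), c("u", "v")]
}

#' Build a synthetic hex-grid eyemap
#'
#' A patch of ommatidial columns on a hexagonal lattice: each column has a
#' unit viewing-direction vector on the sphere (azimuthal-equidistant
#' placement around the patch centre, which points at longitude 0 on the
#' equator) and a 3-D columnar-marker position (nm) per neuropil layer.
#' Defaults give 759 columns, mirroring the size of the measured columnar
#' marker set, at a 4 degree inter-ommatidial angle.
#'
#' @param n_columns number of columns (default 759).
#' @param pitch_deg angular spacing between neighbouring columns (degrees).
#' @param marker_pitch_nm spatial spacing of neighbouring markers in the
#'   neuropil (nm).
#' @param layers character vector of layer names; each layer's markers are
#'   offset 30 um in z from the previous one.
#' @return an object of class `eyemap`: list with `column_ids`,
#'   `directions` (n x 3 unit vectors, rownames = column ids), and
#'   `markers` (named list of n x 3 nm matrices, one per layer).
#' @export
make_hex_eyemap <- function(n_columns = 759L, pitch_deg = 4,
                            marker_pitch_nm = 5000,
                            layers = c("Me", "Lo")) {
  stopifnot(n_columns >= 1, pitch_deg > 0, marker_pitch_nm > 0,
            length(layers) >= 1)
  sites <- hex_sites(n_columns)
  ids <- sprintf("C%04d", seq_len(n_columns))
  theta <- sqrt(sites$u^2 + sites$v^2) * pitch_deg * pi / 180
  if (max(theta) >= pi / 2) {
    stop("patch exceeds a hemisphere; reduce n_columns or pitch_deg")
  }
  phi <- atan2(sites$v, sites$u)
  # patch centre at +x (equator, longitude 0); u grows along longitude,
  # v along latitude
  dirs <- cbind(
    x = cos(theta),
    y = sin(theta) * cos(phi),
    z = sin(theta) * sin(phi)
  )
  rownames(dirs) <- ids
  markers <- lapply(seq_along(layers), function(li) {
    mk <- cbind(
      x = sites$u * marker_pitch_nm,
      y = sites$v * marker_pitch_nm,
      z = rep(30000 * (li - 1), n_columns)
    )
    rownames(mk) <- ids
    mk
  })
  names(markers) <- layers
  structure(
    list(column_ids = ids, directions = dirs, markers = markers,
         pitch_deg = pitch_deg, marker_pitch_nm = marker_pitch_nm),
    class = "eyemap"
  )
}

#' @export
print.eyemap <- function(x, ...) {
  cat(sprintf(
    "<eyemap> %d columns, %.1f deg pitch, layers: %s\n",
    length(x$column_ids), x$pitch_deg, paste(names(x$markers), collapse = ", ")
  ))
  invisible(x)
}

#' Generate a synthetic visual system with planted receptive fields
#'
#' For each requested neuron, plants a ground-truth receptive field (a
#' contiguous set of columns around a centre column) and lays skeleton
#' points near the columnar markers of exactly those columns, within a
#' known distance threshold. Running [covered_columns()] at that threshold
#' on the generated skeleton recovers the planted set, which is the basis
#' of the threshold-calibration recovery tests.
#'
#' @param eye an [make_hex_eyemap()] eyemap.
#' @param rf_specs list of per-neuron specs: each a list with `neuron_id`,
#'   `center` (a column id in the eye), and `n_columns` (planted RF size:
#'   the `n_columns` columns angularly closest to the centre).
#' @param layer marker layer used for skeleton placement.
#' @param threshold_nm the true proximity threshold the skeletons are built
#'   to (default `0.45 * marker_pitch_nm`, safely below half the marker
#'   spacing so neighbouring columns are not accidentally covered).
#' @param points_per_column skeleton points per planted column (default 3).
#' @param seed integer seed.
#' @return list with `skeletons` (named list of point matrices, nm),
#'   `planted_rfs` (named list of column-id sets), `threshold_nm`, `layer`,
#'   and `eye`.
#' @export
generate_visual_system <- function(eye, rf_specs, layer = "Me",
                                   threshold_nm = NULL,
                                   points_per_column = 3L, seed = 1L) {
  stopifnot(inherits(eye, "eyemap"), length(rf_specs) >= 1)
  if (!layer %in% names(eye$markers)) stop("unknown marker layer")
  if (is.null(threshold_nm)) threshold_nm <- 0.45 * eye$marker_pitch_nm
  stopifnot(threshold_nm > 0)
  mk <- eye$markers[[layer]]
  dirs <- eye$directions
  with_seed(seed, {
    skeletons <- list()
    planted <- list()
    for (spec in rf_specs) {
      if (!spec$center %in% eye$column_ids) {
        stop("planted receptive-field centre outside the eye patch")
      }
      if (spec$n_columns > length(eye$column_ids)) {
        stop("planted receptive field larger than the eye patch")
      }
      cosang <- as.vector(dirs %*% dirs[spec$center, ])
      ord <- order(-cosang, eye$column_ids)
      cols <- sort(eye$column_ids[ord[seq_len(spec$n_columns)]])
      pts <- do.call(rbind, lapply(cols, function(cid) {
        # uniform in a ball of radius < threshold around the marker
        p <- matrix(rnorm(3 * points_per_column), points_per_column, 3)
        p <- p / sqrt(rowSums(p^2)) *
          (runif(points_per_column)^(1 / 3) * 0.8 * threshold_nm)
        sweep(p, 2, mk[cid, ], `+`)
      }))
      skeletons[[spec$neuron_id]] <- pts
      planted[[spec$neuron_id]] <- cols
    }
    list(skeletons = skeletons, planted_rfs = planted,
         threshold_nm = threshold_nm, layer = layer, eye = eye)
  })
}
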