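# Readers and writers for the plain-text formats the pipeline consumes:
# synapse edge lists, neuron annotations, score tables, SWC skeletons, and
# eyemap tables. Synapse locations are kept in nanometres as exported; no
# voxel conversion is performed.

#' Read a synapse edge list
#'
#' CSV or Parquet with columns `pre_id`, `post_id`, `count` (one row per
#' connected pair; Parquet needs the `arrow` package). An optional
#' companion long-format file carries per-synapse locations (`pre_id`,
#' `post_id`, `x`, `y`, `z` in nm, one row per synapse); when given,
#' locations are attached as a named list keyed by `pre_id|post_id`, after
#' checking that each pair's location count matches its edge count.
#'
#' @param path edge-list path (`.csv` or `.parquet`).
#' @param locations_path optional synapse-location CSV path.
#' @return data.frame of edges, optionally with a `locations` attribute.
#' @export
read_edges <- function(path, locations_path = NULL) {
  edges <- if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet edge lists needs the 'arrow' package")
    }
    df <- as.data.frame(arrow::read_parquet(path))
    df$pre_id <- as.character(df$pre_id)
    df$post_id <- as.character(df$post_id)
    df
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(pre_id = "character",
                                   post_id = "character"))
  }
  need <- c("pre_id", "post_id", "count")
  if (!all(need %in% names(edges))) {
    stop("edge list must have columns pre_id, post_id, count")
  }
  if (!is.null(locations_path)) {
    loc <- utils::read.csv(locations_path, stringsAsFactors = FALSE,
                           colClasses = c(pre_id = "character",
                                          post_id = "character"))
    key <- paste(loc$pre_id, loc$post_id, sep = "|")
    locs <- lapply(split(seq_len(nrow(loc)), key), function(i) {
      as.matrix(loc[i, c("x", "y", "z")])
    })
    ekey <- paste(edges$pre_id, edges$post_id, sep = "|")
    n_loc <- vapply(locs, nrow, integer(1))
    shared <- intersect(ekey, names(locs))
    bad <- shared[edges$count[match(shared, ekey)] != n_loc[shared]]
    if (length(bad) > 0) {
      stop("synapse-location count disagrees with edge count for ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
    attr(edges, "locations") <- locs
  }
  edges
}

#' Read neuron annotations
#'
#' CSV with columns `neuron_id`, `side` (left/right), `super_class`
#' (KC/VPN/LVIN/OPN/ORN/other), `subtype`, `neuropil_origin`
#' (Me/Lo/aMe/LoP/ocellar/none), and optional `nt_prediction`. Enforces id
#' uniqueness and the convention that only VPNs carry a neuropil of origin.
#'
#' @param path annotation CSV path.
#' @return data.frame of neuron records.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(neuron_id = "character"))
  need <- c("neuron_id", "side", "super_class", "subtype", "neuropil_origin")
  if (!all(need %in% names(ann))) {
    stop("annotations must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$neuron_id)) stop("neuron_id must be unique")
  bad <- ann$super_class != "VPN" & ann$neuropil_origin != "none"
  if (any(bad)) {
    stop("neuropil_origin must be 'none' for non-VPN neurons")
  }
  ann
}

#' Read a morphology score table
#'
#' CSV with columns `query_id`, `target_id`, `score` (in [0, 1], e.g. mean
#' forward/reverse NBLAST similarity).
#'
#' @param path score CSV path.
#' @return data.frame ready for [greedy_one_to_one_matching()].
#' @export
read_score_table <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(query_id = "character",
                                      target_id = "character"))
  if (!all(c("query_id", "target_id", "score") %in% names(s))) {
    stop("score table must have columns query_id, target_id, score")
  }
  if (any(!is.finite(s$score)) || any(s$score < 0 | s$score > 1)) {
    stop("scores must be finite and in [0, 1]")
  }
  s
}

#' Read an SWC skeleton as a point set
#'
#' Standard whitespace-separated SWC (columns: id, type, x, y, z, radius,
#' parent; `#` comments). Only node positions are used downstream — the
#' proximity geometry needs a labelled point set, not the tree topology —
#' but the full table is returned.
#'
#' @param path SWC file path.
#' @param unit_nm multiplier taking file coordinates to nm (default 1:
#'   coordinates already in nm).
#' @return data.frame with SWC columns; use `as.matrix(swc[, c("x","y","z")])`
#'   for the point set.
#' @export
read_swc <- function(path, unit_nm = 1) {
  swc <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  swc[, c("x", "y", "z")] <- swc[, c("x", "y", "z")] * unit_nm
  swc
}

#' Write a point set as a minimal SWC skeleton
#'
#' Nodes are written as a path (each node parented to the previous one),
#' which is sufficient for the point-proximity analyses that read it back.
#'
#' @param points n x 3 matrix, nm.
#' @param path output path.
#' @param radius node radius written to the file.
#' @return invisibly, the path.
#' @export
write_swc <- function(points, path, radius = 100) {
  points <- as.matrix(points)
  n <- nrow(points)
  df <- data.frame(
    id = seq_len(n), type = 3L,
    x = points[, 1], y = points[, 2], z = points[, 3],
    radius = radius, parent = c(-1L, seq_len(n - 1))
  )
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write eyemap tables
#'
#' CSV with one row per column per layer: `column_id`, `layer`, unit view
#' direction `dx`, `dy`, `dz`, and marker position `mx`, `my`, `mz` (nm).
#'
#' @param path CSV path.
#' @return an `eyemap`.
#' @export
read_eyemap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(column_id = "character"))
  need <- c("column_id", "layer", "dx", "dy", "dz", "mx", "my", "mz")
  if (!all(need %in% names(df))) {
    stop("eyemap must have columns ", paste(need, collapse = ", "))
  }
  layers <- unique(df$layer)
  first <- df[df$layer == layers[1], ]
  first <- first[order(first$column_id), ]
  dirs <- as.matrix(first[, c("dx", "dy", "dz")])
  rownames(dirs) <- first$column_id
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("view directions must be unit vectors")
  dirs <- dirs / nrm
  colnames(dirs) <- c("x", "y", "z")
  markers <- lapply(layers, function(l) {
    sub <- df[df$layer == l, ]
    sub <- sub[order(sub$column_id), ]
    if (!identical(sub$column_id, first$column_id)) {
      stop("each layer must mark exactly the same columns")
    }
    mk <- as.matrix(sub[, c("mx", "my", "mz")])
    rownames(mk) <- sub$column_id
    colnames(mk) <- c("x", "y", "z")
    mk
  })
  names(markers) <- layers
  structure(
    list(column_ids = first$column_id, directions = dirs, markers = markers,
         pitch_deg = NA_real_, marker_pitch_nm = NA_real_),
    class = "eyemap"
  )
}

#' @param eye an `eyemap` to write.
#' @rdname read_eyemap
#' @export
write_eyemap <- function(eye, path) {
  stopifnot(inherits(eye, "eyemap"))
  rows <- do.call(rbind, lapply(names(eye$markers), function(l) {
    data.frame(
      column_id = eye$column_ids, layer = l,
      dx = eye$directions[, 1], dy = eye$directions[, 2],
      dz = eye$directions[, 3],
      mx = eye$markers[[l]][, 1], my = eye$markers[[l]][, 2],
      mz = eye$markers[[l]][, 3],
      row.names = NULL
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as an edge-list CSV
#'
#' Inverse of [build_matrix()] up to ordering: one row per retained
#' connection.
#'
#' @param m a `connectivity_matrix`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_edges <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  idx <- which(m$W > 0, arr.ind = TRUE)
  df <- data.frame(
    pre_id = rownames(m$W)[idx[, 1]],
    post_id = colnames(m$W)[idx[, 2]],
    count = m$W[idx]
  )
  df <- df[order(df$pre_id, df$post_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
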