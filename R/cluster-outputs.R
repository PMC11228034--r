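# Clustering outputs by input composition: spectral clustering with
# silhouette-based model selection, plus hierarchical co-clustering orders
# for heatmap display.

# Spectral embedding of binary output profiles. Affinity is the cosine
# similarity of input vectors (the normalized shared-input count), which is
# exactly block-structured for community wiring; the embedding is the
# row-normalized top-k eigenvector basis of the symmetrically normalized
# affinity (Ng-Jordan-Weiss).
spectral_embedding <- function(X, k) {
  profiles <- t(X)                        # outputs x inputs
  nrm <- sqrt(rowSums(profiles^2))
  U <- profiles / nrm
  A <- tcrossprod(U)
  diag(A) <- 0
  d <- rowSums(A)
  d[d == 0] <- 1
  dn <- 1 / sqrt(d)
  L <- A * outer(dn, dn)
  E <- eigen(L, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(E^2))
  rn[rn == 0] <- 1
  E / rn
}

#' Cluster outputs by their input composition
#'
#' Spectral clustering of outputs (e.g. Kenyon cells) on binarized
#' connectivity, run for each candidate number of clusters; the reported
#' clustering is the one maximizing the mean silhouette width computed on
#' the spectral embedding with Euclidean distance. Whether any clustering
#' is meaningful at all is judged on the data rather than the embedding:
#' the silhouette of the selected labels on the binary input profiles
#' (`profile_silhouette`) below `structure_cutoff` flags the matrix as
#' showing no clear cluster structure — the expected outcome for randomly
#' sampled wiring, whose spectral embeddings still produce compact but
#' meaningless K-means partitions. Hierarchical co-clustering orders of
#' rows and columns (complete linkage on Euclidean distance of binary
#' profiles) are returned for heatmap display.
#'
#' Outputs with zero retained inputs are excluded with a message; their
#' labels are `NA` in the returned vector.
#'
#' @param m a `connectivity_matrix` (binarized internally).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param seed integer seed for the K-means step inside spectral clustering.
#' @param structure_cutoff profile-silhouette level below which the result
#'   is flagged structureless (default 0.25).
#' @return an object of class `output_clustering`: list with `labels`
#'   (named integer vector over all outputs, `NA` for excluded ones),
#'   `selected_k`, `silhouette` (named vector of mean embedding-silhouette
#'   widths per k), `profile_silhouette` (silhouette of the selected
#'   clustering on the binary profiles), `no_clear_structure` flag, and
#'   `row_order` / `col_order` for heatmaps.
#' @export
cluster_outputs <- function(m, k_range = 2:10, seed = 1L,
                            structure_cutoff = 0.25) {
  stopifnot(inherits(m, "connectivity_matrix"))
  mb <- binarize(m)
  X <- mb$W
  keep <- colSums(X) > 0
  if (!all(keep)) {
    message(sprintf("excluding %d outputs with zero inputs", sum(!keep)))
  }
  Xk <- X[, keep, drop = FALSE]
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) + 1 > ncol(Xk)) {
    stop("need at least max(k_range) + 1 connected outputs")
  }
  res <- with_seed(seed, {
    sil <- setNames(numeric(length(k_range)), paste0("k", k_range))
    labs <- vector("list", length(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      E <- spectral_embedding(Xk, k)
      cl <- kmeans(E, centers = k, nstart = 20)$cluster
      sw <- cluster::silhouette(cl, dist(E))
      sil[i] <- mean(sw[, "sil_width"])
      labs[[i]] <- cl
    }
    list(sil = sil, labs = labs)
  })
  best <- which.max(res$sil)
  labels <- setNames(rep(NA_integer_, ncol(X)), colnames(X))
  labels[colnames(Xk)] <- res$labs[[best]]
  psil <- mean(
    cluster::silhouette(res$labs[[best]], dist(t(Xk)))[, "sil_width"]
  )

  row_order <- hclust(dist(X), method = "complete")$order
  col_order <- hclust(dist(t(X)), method = "complete")$order

  structure(
    list(
      labels = labels, selected_k = k_range[best], silhouette = res$sil,
      profile_silhouette = psil,
      no_clear_structure = psil < structure_cutoff,
      row_order = row_order, col_order = col_order
    ),
    class = "output_clustering"
  )
}

#' @export
print.output_clustering <- function(x, ...) {
  cat(sprintf(
    "<output_clustering> selected k = %d (profile silhouette %.3f)%s\n",
    x$selected_k, x$profile_silhouette,
    if (x$no_clear_structure) " [no clear structure]" else ""
  ))
  invisible(x)
}
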