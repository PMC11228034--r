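# Synapse-type classification: bouton-claw vs en-passant connections from
# the spatial dispersion of their synapse locations.

#' Dispersion statistic of a synapse point cloud
#'
#' Centroid of the 3-D synapse locations of one pre/post connection, and the
#' population variance of the Euclidean distances of each synapse from that
#' centroid (nm^2). Compact multisynaptic boutons wrapped by a dendritic
#' claw give low dispersion; synapses strung along an axon (en passant) give
#' high dispersion. Any two-point cloud has dispersion identically 0 (both
#' points sit at distance d/2 from the centroid), which is why connections
#' with fewer than 3 synapses are left unclassified downstream.
#'
#' @param points numeric matrix (n x 3) of synapse locations in nm.
#' @return non-negative scalar (nm^2); invariant to rigid motions, scales
#'   as s^2 under spatial scaling by s.
#' @examples
#' pts <- cbind(seq(0, 1000, length.out = 50), 0, 0)
#' dispersion_statistic(pts)  # ~ 1000^2 / 48 for a uniform segment
#' @export
dispersion_statistic <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1, all(is.finite(points)))
  centroid <- colMeans(points)
  d <- sqrt(rowSums(sweep(points, 2, centroid)^2))
  mean((d - mean(d))^2)   # population variance
}

#' Calibrate a dispersion threshold and classify connections
#'
#' Reproduces the two-stage synapse-type workflow: a labelled ground-truth
#' set of connections is split into a training and a held-out test set; the
#' dispersion cutoff maximizing training accuracy is placed at the midpoint
#' between the two order statistics that best separate the classes; test
#' accuracy is reported on the held-out set; and the calibrated threshold is
#' then applied to unlabelled connections (dispersion below the threshold
#' gives bouton-claw, above gives en-passant; fewer than 3 synapses gives
#' unclassified).
#'
#' @param labeled list of ground-truth connections; each element a list with
#'   `points` (n x 3 matrix) and `label` (`"bouton_claw"` or
#'   `"en_passant"`). Both classes must be present.
#' @param unlabeled optional list of connections to classify; each element a
#'   list with `points` and optionally `pre_id`, `post_id`.
#' @param split fraction of the labelled set used for training (default
#'   0.5), stratified by class.
#' @param seed integer seed for the train/test split.
#' @return list with `calibration` (list: `threshold` in nm^2,
#'   `train_accuracy`, `test_accuracy`, `n_train`, `n_test`) and `calls`
#'   (data.frame: pre_id, post_id, n_synapses, dispersion, label).
#' @export
calibrate_and_classify <- function(labeled, unlabeled = list(), split = 0.5,
                                   seed = 1L) {
  stopifnot(length(labeled) >= 2, split > 0, split < 1)
  labs <- vapply(labeled, function(x) x$label, character(1))
  if (!all(labs %in% c("bouton_claw", "en_passant"))) {
    stop("labels must be 'bouton_claw' or 'en_passant'")
  }
  if (length(unique(labs)) < 2) {
    stop("ground truth must contain both synapse classes")
  }
  disp <- vapply(labeled, function(x) dispersion_statistic(x$points), numeric(1))

  idx_train <- with_seed(seed, {
    unlist(lapply(unique(labs), function(l) {
      ii <- which(labs == l)
      sample(ii, max(1L, round(split * length(ii))))
    }))
  })
  idx_test <- setdiff(seq_along(labeled), idx_train)
  if (length(unique(labs[idx_train])) < 2) {
    stop("training split lost a class; increase the labelled set")
  }

  thr <- dispersion_threshold(disp[idx_train], labs[idx_train])
  acc <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    pred <- ifelse(disp[idx] < thr, "bouton_claw", "en_passant")
    mean(pred == labs[idx])
  }
  calibration <- list(
    threshold = thr,
    train_accuracy = acc(idx_train),
    test_accuracy = acc(idx_test),
    n_train = length(idx_train),
    n_test = length(idx_test)
  )

  calls <- do.call(rbind, lapply(seq_along(unlabeled), function(i) {
    u <- unlabeled[[i]]
    pts <- as.matrix(u$points)
    d <- dispersion_statistic(pts)
    data.frame(
      pre_id = if (is.null(u$pre_id)) paste0("pre", i) else u$pre_id,
      post_id = if (is.null(u$post_id)) paste0("post", i) else u$post_id,
      n_synapses = nrow(pts),
      dispersion = d,
      label = if (nrow(pts) < 3) "unclassified"
              else if (d < thr) "bouton_claw" else "en_passant",
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(calls)) {
    calls <- data.frame(
      pre_id = character(), post_id = character(), n_synapses = integer(),
      dispersion = numeric(), label = character(), stringsAsFactors = FALSE
    )
  }
  list(calibration = calibration, calls = calls)
}

# Deterministic threshold placement: the accuracy-maximizing cutoff over all
# midpoints between adjacent sorted dispersions (plus open extremes); among
# ties the smallest cutoff is returned.
dispersion_threshold <- function(disp, labs) {
  o <- order(disp)
  d <- disp[o]
  l <- labs[o]
  cands <- c(d[1] - 1, (d[-length(d)] + d[-1]) / 2, d[length(d)] + 1)
  accs <- vapply(cands, function(thr) {
    mean(ifelse(disp < thr, "bouton_claw", "en_passant") == labs)
  }, numeric(1))
  cands[which.max(accs)]
}
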