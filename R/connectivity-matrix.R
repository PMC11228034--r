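# Connectivity-matrix data model: thresholded synapse-count matrices,
# type aggregation, and input summaries.

#' Construct a connectivity matrix object
#'
#' A `connectivity_matrix` wraps a non-negative input x output synapse-count
#' matrix together with the synapse threshold that was applied to it and a
#' flag recording whether it has been binarized. Rows are inputs (presynaptic
#' neurons), columns are outputs (postsynaptic neurons); dimnames carry the
#' neuron identifiers.
#'
#' @param W numeric matrix of non-negative counts with complete dimnames.
#' @param threshold integer synapse threshold already applied to `W`.
#' @param binarized logical; `TRUE` if entries are 0/1 connection indicators.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(W, threshold = 0L, binarized = FALSE) {
  stopifnot(is.matrix(W), is.numeric(W))
  if (is.null(rownames(W)) || is.null(colnames(W))) {
    stop("W must carry input ids as rownames and output ids as colnames")
  }
  if (anyDuplicated(rownames(W)) || anyDuplicated(colnames(W))) {
    stop("neuron ids must be unique within each axis")
  }
  if (any(W < 0) || any(!is.finite(W))) stop("entries must be finite and non-negative")
  if (isTRUE(binarized)) {
    if (!all(W %in% c(0, 1))) {
      stop("binarized matrix must contain only 0/1 entries")
    }
  } else if (any(W > 0 & W < threshold)) {
    stop("entries below the stated threshold must be zero")
  }
  structure(
    list(W = W, threshold = as.integer(threshold), binarized = isTRUE(binarized)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %d inputs x %d outputs, threshold >= %d, %s\n",
    nrow(x$W), ncol(x$W), x$threshold,
    if (x$binarized) "binarized" else "synapse-weighted"
  ))
  cat(sprintf(
    "  %d connections, %s synapses\n",
    sum(x$W > 0),
    format(sum(x$W))
  ))
  invisible(x)
}

#' @export
dim.connectivity_matrix <- function(x) dim(x$W)

#' Input and output identifiers of a connectivity matrix
#' @param m a `connectivity_matrix`.
#' @return character vector of ids.
#' @export
input_ids <- function(m) rownames(m$W)

#' @rdname input_ids
#' @export
output_ids <- function(m) colnames(m$W)

#' Binarize a connectivity matrix
#'
#' Converts retained synapse counts to 0/1 connection indicators. Most of the
#' shuffle-null machinery operates on binarized connectivity, where the
#' preserved marginals (input connection probabilities, per-output in-degree)
#' are defined.
#'
#' @param m a `connectivity_matrix`.
#' @return a binarized `connectivity_matrix` with the same threshold.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$binarized) return(m)
  W <- (m$W > 0) + 0
  dimnames(W) <- dimnames(m$W)
  connectivity_matrix(W, threshold = m$threshold, binarized = TRUE)
}

#' Build a thresholded connectivity matrix from a synapse edge list
#'
#' Assembles the input x output synapse-count matrix used by every downstream
#' statistic. The synapse threshold is applied per (pre, post) pair: a pair
#' with fewer than `threshold` synapses is recorded as unconnected, matching
#' the convention of counting a connection only at >= 5 synapses. Edges whose
#' endpoints are not in `inputs` x `outputs` are ignored, so a whole-brain
#' export can be passed directly.
#'
#' @param edges data.frame with columns `pre_id`, `post_id`, `count`
#'   (one row per pre/post pair; duplicates are an error since connectome
#'   exports provide one row per pair).
#' @param inputs,outputs character vectors of neuron ids defining the two
#'   axes. Ordering of the result is lexicographic regardless of input order.
#' @param threshold minimum synapse count for a retained connection
#'   (default 5).
#' @param binarize logical; if `TRUE`, retained connections are recorded as 1.
#' @return a `connectivity_matrix`.
#' @examples
#' edges <- data.frame(pre_id = c("A", "B"), post_id = "K1", count = c(6, 4))
#' build_matrix(edges, inputs = c("A", "B"), outputs = "K1", threshold = 5)
#' @export
build_matrix <- function(edges, inputs, outputs, threshold = 5L, binarize = FALSE) {
  stopifnot(is.data.frame(edges), threshold >= 0)
  need <- c("pre_id", "post_id", "count")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns pre_id, post_id, count")
  }
  inputs <- sort(unique(as.character(inputs)))
  outputs <- sort(unique(as.character(outputs)))
  if (length(intersect(inputs, outputs)) > 0) {
    stop("inputs and outputs must be disjoint id sets")
  }
  keep <- edges$pre_id %in% inputs & edges$post_id %in% outputs
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0) {
    if (any(edges$count < 1)) stop("edge counts must be >= 1")
    key <- paste(edges$pre_id, edges$post_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (pre_id, post_id) edges: malformed export")
    }
  }
  W <- matrix(0, length(inputs), length(outputs), dimnames = list(inputs, outputs))
  if (nrow(edges) > 0) {
    retained <- edges$count >= threshold
    e <- edges[retained, , drop = FALSE]
    W[cbind(match(e$pre_id, inputs), match(e$post_id, outputs))] <- e$count
  }
  if (binarize) W <- (W > 0) + 0
  connectivity_matrix(W, threshold = threshold, binarized = binarize)
}

#' Aggregate connectivity-matrix rows by cell type
#'
#' Condenses the input axis by a type map, combining rows that share a label
#' by summing or averaging — e.g. averaging connectivity over members of the
#' same morphological class before a bilateral comparison. Aggregation never
#' resurrects sub-threshold pairs: the threshold was applied per neuron pair
#' when the matrix was built.
#'
#' @param m a `connectivity_matrix`.
#' @param tmap named character vector mapping every input id to a type label.
#' @param mode `"sum"` or `"mean"`.
#' @return a `connectivity_matrix` with one row per label, labels in
#'   lexicographic order. The result is marked non-binarized unless the
#'   aggregated entries are all 0/1.
#' @export
aggregate_by_type <- function(m, tmap, mode = c("mean", "sum")) {
  stopifnot(inherits(m, "connectivity_matrix"))
  mode <- match.arg(mode)
  ids <- input_ids(m)
  if (!all(ids %in% names(tmap))) {
    stop("tmap must cover every input id of the matrix")
  }
  labels <- as.character(tmap[ids])
  agg <- rowsum(m$W, group = labels, reorder = TRUE)
  if (mode == "mean") {
    agg <- agg / as.vector(table(labels)[rownames(agg)])
  }
  connectivity_matrix(
    agg, threshold = m$threshold,
    binarized = m$binarized && all(agg %in% c(0, 1))
  )
}

#' Summarize inputs of a connectivity matrix by group
#'
#' Produces the descriptive tables used to characterize an input population:
#' per-group partner counts and synapse fractions (e.g. VPN vs LVIN share of
#' synapses), a per-input synapse-total ranking, per-output input-composition
#' fractions over groups, and the percentage of outputs each input contacts.
#'
#' @param m a `connectivity_matrix`.
#' @param groups named character vector mapping every input id to a group
#'   label (e.g. `"VPN"`, `"LVIN"`, or neuropil of origin).
#' @return a list with components:
#' \describe{
#'   \item{group_summary}{data.frame: group, n_partners (inputs with at least
#'     one retained connection), n_synapses, synapse_fraction.}
#'   \item{input_ranking}{data.frame: input_id, group, n_synapses, n_outputs,
#'     pct_outputs_contacted; ranked by synapse total descending, ties broken
#'     lexicographically by id.}
#'   \item{output_composition}{data.frame: one row per output with >= 1
#'     input; columns are the synapse fraction each group contributes.}
#'   \item{n_outputs_connected}{number of outputs with at least one input.}
#' }
#' @export
summarize_inputs <- function(m, groups) {
  stopifnot(inherits(m, "connectivity_matrix"))
  ids <- input_ids(m)
  if (!all(ids %in% names(groups))) stop("groups must cover every input id")
  W <- m$W
  if (sum(W) == 0) {
    warning("empty connectivity matrix: returning empty summary")
    return(list(
      group_summary = data.frame(
        group = character(), n_partners = integer(),
        n_synapses = numeric(), synapse_fraction = numeric()
      ),
      input_ranking = data.frame(
        input_id = character(), group = character(), n_synapses = numeric(),
        n_outputs = integer(), pct_outputs_contacted = numeric()
      ),
      output_composition = data.frame(),
      n_outputs_connected = 0L
    ))
  }
  grp <- as.character(groups[ids])
  in_syn <- rowSums(W)
  in_out <- rowSums(W > 0)
  total <- sum(in_syn)

  glev <- sort(unique(grp))
  g_syn <- vapply(glev, function(g) sum(in_syn[grp == g]), numeric(1))
  g_part <- vapply(glev, function(g) sum(in_syn > 0 & grp == g), integer(1))
  group_summary <- data.frame(
    group = glev, n_partners = g_part, n_synapses = g_syn,
    synapse_fraction = g_syn / total, row.names = NULL
  )

  ord <- order(-in_syn, ids)
  input_ranking <- data.frame(
    input_id = ids[ord], group = grp[ord], n_synapses = in_syn[ord],
    n_outputs = as.integer(in_out[ord]),
    pct_outputs_contacted = 100 * in_out[ord] / ncol(W),
    row.names = NULL
  )

  connected <- colSums(W) > 0
  gW <- rowsum(W[, connected, drop = FALSE], group = grp, reorder = TRUE)
  comp <- t(gW) / colSums(W)[connected]
  output_composition <- data.frame(
    output_id = colnames(W)[connected], comp,
    row.names = NULL, check.names = FALSE
  )

  list(
    group_summary = group_summary,
    input_ranking = input_ranking,
    output_composition = output_composition,
    n_outputs_connected = sum(connected)
  )
}
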