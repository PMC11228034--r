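# Greedy one-to-one matching of query neurons to target neurons by a
# precomputed morphology-similarity score table (e.g. mean forward/reverse
# NBLAST scores).

#' Greedy one-to-one matching from a score table
#'
#' Assigns each query neuron to its best-scoring target; when several queries
#' claim the same target, the strongest-scoring claim is retained and the
#' displaced queries fall back to their next-best unclaimed targets, repeated
#' until the mapping is one-to-one. Implemented by processing (query, target)
#' candidate pairs in globally descending score order, which realizes exactly
#' that reassignment cascade deterministically; ties are broken
#' lexicographically by query id then target id. A query that exhausts all
#' its candidate targets is mapped to `"unmatched"`.
#'
#' @param scores data.frame with columns `query_id`, `target_id`, `score`
#'   (finite, one row per candidate pair).
#' @return named character vector: `mapping[query_id] == target_id` (or
#'   `"unmatched"`), injective over matched targets.
#' @examples
#' s <- data.frame(
#'   query_id = c("q1", "q1", "q2", "q2"),
#'   target_id = c("t1", "t2", "t1", "t2"),
#'   score = c(0.9, 0.3, 0.8, 0.7)
#' )
#' greedy_one_to_one_matching(s)
#' @export
greedy_one_to_one_matching <- function(scores) {
  stopifnot(is.data.frame(scores))
  need <- c("query_id", "target_id", "score")
  if (!all(need %in% names(scores))) {
    stop("scores must have columns query_id, target_id, score")
  }
  if (any(!is.finite(scores$score))) stop("scores must be finite")
  key <- paste(scores$query_id, scores$target_id, sep = "\r")
  if (anyDuplicated(key)) stop("one row per (query, target) pair expected")

  queries <- sort(unique(as.character(scores$query_id)))
  mapping <- setNames(rep("unmatched", length(queries)), queries)
  ord <- order(-scores$score, as.character(scores$query_id),
               as.character(scores$target_id))
  used_targets <- character(0)
  assigned <- character(0)
  for (i in ord) {
    q <- as.character(scores$query_id[i])
    t <- as.character(scores$target_id[i])
    if (q %in% assigned || t %in% used_targets) next
    mapping[q] <- t
    assigned <- c(assigned, q)
    used_targets <- c(used_targets, t)
    if (length(assigned) == length(queries)) break
  }
  mapping
}
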