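# Synthetic bipartite wiring generator: the three wiring hypotheses
# (labelled line, biased mixture, random) with configurable input connection
# probabilities and per-output in-degree distribution.

#' Heavy-tailed ranked input connection probabilities
#'
#' Default input connection-probability profile of the wiring generator:
#' lognormal quantiles, normalized. Measured input populations are strongly
#' skewed — a few input types contribute an outsized share of connections,
#' with a long tail of weak partners — and ranked synaptic-contribution
#' curves are well described by a lognormal profile. `sdlog = 0` gives
#' uniform probabilities.
#'
#' @param n number of inputs.
#' @param sdlog lognormal shape (default 1; larger = more skew).
#' @return probability vector of length `n`, increasing, summing to 1.
#' @export
ranked_input_probs <- function(n, sdlog = 1) {
  stopifnot(n >= 1, sdlog >= 0)
  p <- stats::qlnorm((seq_len(n) - 0.5) / n, meanlog = 0, sdlog = sdlog)
  p / sum(p)
}

#' Specify a synthetic wiring model
#'
#' Defines the generative law for a bipartite input-to-output connectivity
#' matrix. Each output draws an in-degree from `indegree_dist` and then
#' samples that many distinct inputs:
#'
#' * `"random"` — inputs sampled with probability proportional to
#'   `input_probs`, irrespective of any community structure;
#' * `"labeled_line"` — inputs and outputs carry community assignments and
#'   each output samples only within its community, except that each draw is
#'   contaminated (redirected to a uniformly chosen off-community input) with
#'   probability `noise`;
#' * `"biased_mixture"` — as `"random"` but with `input_probs` multiplied by
#'   a `bias` vector and renormalized, concentrating connections on favoured
#'   channels.
#'
#' Retained synapse counts are drawn as `threshold + rgeom(count_prob)`,
#' a shifted geometric above the detection threshold; structural statistics
#' binarize them anyway.
#'
#' @param n_inputs,n_outputs numbers of input and output neurons.
#' @param input_probs probability vector over inputs (normalized
#'   internally). Defaults to the heavy-tailed [ranked_input_probs()]
#'   profile, emulating the overrepresentation of top input types.
#' @param indegree_dist either a single fixed in-degree or a vector to sample
#'   in-degrees from uniformly (an empirical in-degree list). Defaults to
#'   `c(1, 2, 3, 3, 4, 5, 7)`, a 1-7 range with median 3 mirroring the
#'   sparse sampling of visual Kenyon cells.
#' @param model `"random"`, `"labeled_line"`, or `"biased_mixture"`.
#' @param n_communities number of communities (labelled-line model).
#' @param noise per-draw off-community contamination rate (labelled-line).
#' @param bias multiplicative bias vector over inputs (biased mixture).
#' @param threshold synapse threshold of the generated matrix (default 5).
#' @param count_prob geometric success probability for counts above the
#'   threshold.
#' @return a `wiring_spec` list.
#' @export
wiring_spec <- function(n_inputs = 74L, n_outputs = 147L,
                        input_probs = NULL,
                        indegree_dist = c(1, 2, 3, 3, 4, 5, 7),
                        model = c("random", "labeled_line", "biased_mixture"),
                        n_communities = 4L, noise = 0,
                        bias = NULL, threshold = 5L, count_prob = 0.5) {
  model <- match.arg(model)
  stopifnot(n_inputs >= 1, n_outputs >= 1, all(indegree_dist >= 0),
            max(indegree_dist) <= n_inputs, noise >= 0, noise <= 1,
            threshold >= 0, count_prob > 0, count_prob <= 1)
  if (is.null(input_probs)) input_probs <- ranked_input_probs(n_inputs)
  stopifnot(length(input_probs) == n_inputs, all(input_probs >= 0))
  input_probs <- input_probs / sum(input_probs)
  if (!is.null(bias)) stopifnot(length(bias) == n_inputs, all(bias >= 0))
  structure(
    list(
      n_inputs = as.integer(n_inputs), n_outputs = as.integer(n_outputs),
      input_probs = input_probs, indegree_dist = indegree_dist,
      model = model, n_communities = as.integer(n_communities),
      noise = noise, bias = bias, threshold = as.integer(threshold),
      count_prob = count_prob
    ),
    class = "wiring_spec"
  )
}

# Sample k distinct inputs with probability proportional to prob.
sample_inputs <- function(n, k, prob) {
  if (k == 0) return(integer(0))
  sample.int(n, k, replace = FALSE, prob = prob)
}

#' Generate a synthetic connectivity matrix
#'
#' Draws one bipartite connectivity matrix from a [wiring_spec()], with
#' ground-truth community labels attached for recovery tests. Input ids are
#' `I001, I002, ...`, output ids `O001, ...` (zero-padded, so lexicographic
#' ordering is the natural ordering).
#'
#' @param spec a `wiring_spec`.
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return a `connectivity_matrix` with attributes `input_community` and
#'   `output_community` (integer vectors; all 1 for the non-community
#'   models) and `indegrees` (realized per-output in-degrees).
#' @examples
#' m <- generate_wiring(wiring_spec(n_inputs = 10, n_outputs = 20), seed = 1)
#' colSums(binarize(m)$W)  # realized in-degrees
#' @export
generate_wiring <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "wiring_spec"))
  with_seed(seed, {
    n_in <- spec$n_inputs
    n_out <- spec$n_outputs
    in_comm <- rep(1L, n_in)
    out_comm <- rep(1L, n_out)
    probs <- spec$input_probs
    if (spec$model == "labeled_line") {
      in_comm <- sort(rep_len(seq_len(spec$n_communities), n_in))
      out_comm <- sort(rep_len(seq_len(spec$n_communities), n_out))
    } else if (spec$model == "biased_mixture") {
      if (!is.null(spec$bias)) probs <- probs * spec$bias
      if (sum(probs) == 0) stop("bias annihilates every input probability")
      probs <- probs / sum(probs)
    }
    ks <- if (length(spec$indegree_dist) == 1) {
      rep(spec$indegree_dist, n_out)
    } else {
      sample(spec$indegree_dist, n_out, replace = TRUE)
    }
    ks <- as.integer(ks)
    W <- matrix(0, n_in, n_out)
    for (j in seq_len(n_out)) {
      k <- ks[j]
      if (k == 0) next
      if (spec$model == "labeled_line") {
        inside <- which(in_comm == out_comm[j])
        if (k > length(inside)) {
          stop("in-degree exceeds the number of inputs in the output's community")
        }
        chosen <- inside[sample_inputs(length(inside), k, probs[inside])]
        if (spec$noise > 0) {
          flip <- runif(k) < spec$noise
          if (any(flip)) {
            outside <- setdiff(seq_len(n_in), chosen)
            repl <- sample(outside, sum(flip), replace = FALSE)
            chosen[flip] <- repl
          }
        }
      } else {
        chosen <- sample_inputs(n_in, k, probs)
      }
      W[chosen, j] <- spec$threshold + rgeom(length(chosen), spec$count_prob)
    }
    dimnames(W) <- list(
      sprintf("I%03d", seq_len(n_in)),
      sprintf("O%03d", seq_len(n_out))
    )
    m <- connectivity_matrix(W, threshold = spec$threshold, binarized = FALSE)
    attr(m, "input_community") <- in_comm
    attr(m, "output_community") <- out_comm
    attr(m, "indegrees") <- ks
    m
  })
}

#' Generate a bilateral pair of connectivity matrices
#'
#' Emulates left/right hemisphere circuits. In `"mirrored"` mode the right
#' matrix is an identical copy of the left under the input type map (the
#' bilaterally stereotyped model: random but identical in each hemisphere);
#' in `"independent"` mode the two hemispheres are independent draws from
#' the same wiring law (identical marginal structure, no pairwise
#' stereotypy).
#'
#' Input ids carry hemisphere suffixes (`I001_L` / `I001_R`); the returned
#' type map sends both to the shared type label `I001`, which is how paired
#' inputs are identified across sides.
#'
#' @param spec a `wiring_spec`.
#' @param stereotypy `"independent"` or `"mirrored"`.
#' @param seed integer seed.
#' @return list with elements `left`, `right` (connectivity matrices) and
#'   `tmap` (named character vector over both sides' input ids).
#' @export
generate_bilateral_pair <- function(spec, stereotypy = c("independent", "mirrored"),
                                    seed = 1L) {
  stereotypy <- match.arg(stereotypy)
  stopifnot(inherits(spec, "wiring_spec"))
  left <- generate_wiring(spec, seed = derive_seed(seed, "bilateral_left"))
  right <- if (stereotypy == "mirrored") {
    left
  } else {
    generate_wiring(spec, seed = derive_seed(seed, "bilateral_right"))
  }
  relabel <- function(m, side) {
    W <- m$W
    rownames(W) <- paste0(rownames(W), "_", side)
    colnames(W) <- paste0(colnames(W), "_", side)
    out <- connectivity_matrix(W, threshold = m$threshold, binarized = m$binarized)
    attr(out, "input_community") <- attr(m, "input_community")
    attr(out, "output_community") <- attr(m, "output_community")
    out
  }
  left_m <- relabel(left, "L")
  right_m <- relabel(right, "R")
  base <- rownames(left$W)
  tmap <- setNames(
    c(base, base),
    c(rownames(left_m$W), rownames(right_m$W))
  )
  list(left = left_m, right = right_m, tmap = tmap)
}
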