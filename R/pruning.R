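#' Node weights of a variation graph
#'
#' \code{w(v)} is the expected number of reads covering node v: the plain
#' count of covering reads for FASTA inputs, or the sum of
#' \code{1 - p_{r,v}} over covering reads for FASTQ inputs, where
#' \code{p_{r,v}} is the base error probability derived from the Phred
#' profile. A read covers a node when its walk consumes it
#' (match/mismatch).
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @return data.frame with columns node, base, weight, coverage.
#' @export
nodeWeights <- function(graph) {
  st <- .cpp_graph_stats(.vg_to_list(graph), .window_len(graph))
  data.frame(node = seq_len(nodeCount(graph)), base = graph@bases,
             weight = st$node_weight, coverage = st$node_coverage)
}

.window_len <- function(graph) {
  if (nodeCount(graph) == 0) return(1)
  max(1, diff(range(graph@ranks)) + 1)
}

#' Edge weights, Support and Confidence of a variation graph
#'
#' Per edge e = (v_i, v_j): \code{w(e)} sums \code{1 - p_i/2 - p_j/2} over
#' reads traversing the edge (reducing to the plain traversal count for
#' FASTA inputs); \code{Support(e) = w(e)}; the forward confidence is
#' \code{w(e)} over the total weight of v_i's out-edges, the backward
#' confidence is \code{w(e)} over the total weight of v_j's in-edges, and
#' \code{Confidence(e)} is the larger of the two.
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @param window_len window length L used for the coverage normalisation
#'   \code{C = sum_v w(v) / L} (defaults to the node rank span).
#' @return data.frame with columns from, to, weight, coverage, support,
#'   conf_fwd, conf_bwd, confidence; attribute \code{mean_coverage} holds C.
#' @export
edgeWeights <- function(graph, window_len = NULL) {
  if (is.null(window_len)) window_len <- .window_len(graph)
  st <- .cpp_graph_stats(.vg_to_list(graph), window_len)
  out <- data.frame(from = graph@edgeFrom, to = graph@edgeTo,
                    weight = st$edge_weight, coverage = st$edge_coverage,
                    support = st$support, conf_fwd = st$conf_fwd,
                    conf_bwd = st$conf_bwd, confidence = st$confidence)
  attr(out, "mean_coverage") <- st$mean_coverage
  out
}

#' @describeIn edgeWeights Support only (equal to the edge weight).
#' @export
edgeSupport <- function(graph) edgeWeights(graph)$support

#' @describeIn edgeWeights Confidence components only.
#' @export
edgeConfidence <- function(graph)
  edgeWeights(graph)[, c("from", "to", "conf_fwd", "conf_bwd", "confidence")]

#' One pruning round
#'
#' Computes the support threshold \code{s = support_factor * C} with
#' \code{C = sum_v w(v) / L}, removes every edge with \code{Support < s}
#' or \code{Confidence < c} (edges exactly at a threshold are kept), then
#' removes nodes left without incident edges. Paths are remapped onto the
#' surviving nodes; realignment is the caller's business (see
#' \code{\link{pruneIterative}}).
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @param cfg a \code{\link{pruneConfig}}.
#' @param window_len window length L for coverage normalisation (defaults
#'   to the node rank span).
#' @return list with \code{graph} (pruned), \code{removed_edges}
#'   (data.frame from/to in the input numbering), \code{removed_nodes},
#'   \code{support_threshold} and \code{mean_coverage}.
#' @export
pruneOnce <- function(graph, cfg = pruneConfig(), window_len = NULL) {
  if (is.null(window_len)) window_len <- .window_len(graph)
  res <- .cpp_prune_once(.vg_to_list(graph), cfg$confidence,
                         cfg$support_factor, window_len)
  list(graph = .vg_from_list(res$graph),
       removed_edges = data.frame(from = res$removed_from,
                                  to = res$removed_to),
       removed_nodes = res$removed_nodes,
       support_threshold = res$support_threshold,
       mean_coverage = res$mean_coverage)
}

#' Iterative prune/realign cycle
#'
#' Repeats \{compute Support/Confidence, prune, realign every window read
#' to the pruned graph (without modifying it), recompute read paths\} for
#' at most \code{cfg$iterations} rounds, stopping early once a round
#' removes no edge. C is recomputed fresh at the start of every round.
#'
#' @param graph a \linkS4class{VariationGraph} built from
#'   \code{window_reads}.
#' @param window_reads named character vector of the window's sequences
#'   (the same ones the graph was built from).
#' @param scoring an \code{\link{alignScoring}}.
#' @param cfg a \code{\link{pruneConfig}}.
#' @param quals optional list of Phred vectors parallel to
#'   \code{window_reads}.
#' @param offsets optional window-coordinate offsets per read.
#' @param window_len window length L (defaults to the node rank span).
#' @param band initial alignment band half-width.
#' @return list with \code{graph} (final pruned graph with realigned
#'   paths), \code{removed_per_iter} and \code{empty} (TRUE if everything
#'   was pruned).
#' @export
pruneIterative <- function(graph, window_reads, scoring = alignScoring(),
                           cfg = pruneConfig(), quals = NULL,
                           offsets = NULL, window_len = NULL, band = 32L) {
  stopifnot(is(graph, "VariationGraph"))
  if (is.null(window_len)) window_len <- .window_len(graph)
  ids <- names(window_reads)
  if (is.null(ids)) stop("window_reads must be named")
  probs <- if (is.null(quals)) NULL else lapply(quals, phredToErrorProb)
  if (is.null(offsets)) offsets <- integer(length(window_reads))
  res <- .cpp_prune_iterative(.vg_to_list(graph), ids,
                              toupper(as.character(window_reads)), probs,
                              as.integer(offsets), scoring,
                              cfg$confidence, cfg$support_factor,
                              window_len, cfg$iterations, band)
  g <- .vg_from_list(res$graph)
  list(graph = g, removed_per_iter = res$removed_per_iter,
       empty = nodeCount(g) == 0)
}

#' Correct a target subread against a pruned variation graph
#'
#' Realigns the raw target subread to the (fully pruned) graph and spells
#' the sequence of the optimal alignment walk: the target's insertions are
#' dropped, its substitutions and deletions are replaced by the graph
#' bases along the walk. If the graph is empty the raw subread is returned
#' unchanged and flagged.
#'
#' @param graph a \linkS4class{VariationGraph} (typically the output of
#'   \code{\link{pruneIterative}}).
#' @param target_subread the raw target subread.
#' @param scoring an \code{\link{alignScoring}}.
#' @param band initial band half-width.
#' @param complete_window extend the walk to a graph source/sink along the
#'   heaviest edges, so deletions of the very first/last window bases are
#'   restored rather than absorbed by the alignment's free graph ends.
#' @return list with \code{seq} (corrected subread) and \code{flagged}
#'   (TRUE when the graph was empty and the subread passed through).
#' @export
correctSubread <- function(graph, target_subread,
                           scoring = alignScoring(), band = 32L,
                           complete_window = TRUE) {
  if (nodeCount(graph) == 0)
    return(list(seq = target_subread, flagged = TRUE))
  al <- alignToGraph(graph, target_subread, scoring, offset = 0L,
                     band = band)
  walk <- al$walk
  if (complete_window && length(walk) > 0) {
    ew <- edgeWeights(graph)
    for (i in 1:64) {
      inc <- ew[ew$to == walk[1], , drop = FALSE]
      if (nrow(inc) == 0) break
      inc <- inc[order(-inc$weight, inc$from), , drop = FALSE]
      walk <- c(inc$from[1], walk)
    }
    for (i in 1:64) {
      outg <- ew[ew$from == walk[length(walk)], , drop = FALSE]
      if (nrow(outg) == 0) break
      outg <- outg[order(-outg$weight, outg$to), , drop = FALSE]
      walk <- c(walk, outg$to[1])
    }
  }
  list(seq = extractPathSequence(graph, walk), flagged = FALSE)
}
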