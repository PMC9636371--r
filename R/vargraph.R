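#' Build a variation graph by partial order alignment
#'
#' The first sequence (the target subread, by pipeline convention) becomes
#' the linear backbone; each subsequent sequence is aligned to the current
#' graph semi-globally and fused: matches reuse existing nodes, mismatches
#' and insertions create new nodes, deletions induce skip edges. Every
#' sequence's walk is recorded as a path. Insertion order matters (the
#' pipeline inserts by decreasing overlap identity, ties by read id).
#'
#' @param seqs named character vector of sequences (first = backbone).
#' @param scoring an \code{\link{alignScoring}}.
#' @param quals optional list of integer Phred vectors parallel to
#'   \code{seqs}; when given, node/edge weights use FASTQ weighting
#'   (1 - error probability), otherwise plain read counts.
#' @param offsets optional integer vector of window-coordinate offsets per
#'   sequence (used to band the alignment; 0 for sequences spanning the
#'   window).
#' @param band initial band half-width of the sequence-to-graph alignment.
#' @return A \linkS4class{VariationGraph}.
#' @export
poaBuild <- function(seqs, scoring = alignScoring(), quals = NULL,
                     offsets = NULL, band = 32L) {
  stopifnot(length(seqs) >= 1)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  probs <- if (is.null(quals)) NULL else lapply(quals, phredToErrorProb)
  if (is.null(offsets)) offsets <- integer(length(seqs))
  gl <- .cpp_poa_build(ids, toupper(as.character(seqs)), probs, scoring,
                       as.integer(offsets), band)
  .vg_from_list(gl)
}

#' Align a sequence to a variation graph
#'
#' Optimal semi-global alignment (free leading/trailing graph nodes, the
#' sequence consumed end to end) by dynamic programming over the
#' topological order, with a rank-anchored band that doubles on failure.
#' The returned walk is a directed walk in the graph; \code{ops} labels
#' each walk step match/mismatch/deletion, and sequence positions aligned
#' as insertions are listed separately.
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @param seq sequence to align.
#' @param scoring an \code{\link{alignScoring}}.
#' @param offset window-coordinate offset of the sequence.
#' @param band initial band half-width.
#' @return list with \code{walk} (node indices), \code{qpos} (0-based
#'   sequence position consumed at each step, -1 for deletions),
#'   \code{ops} (per-step "M"/"X"/"D"), \code{ins_qpos}, \code{path}
#'   (consumed nodes only) and \code{score}.
#' @export
alignToGraph <- function(graph, seq, scoring = alignScoring(), offset = 0L,
                         band = 32L) {
  stopifnot(is(graph, "VariationGraph"), nodeCount(graph) > 0 || nchar(seq) == 0)
  al <- .cpp_align_to_graph(.vg_to_list(graph), toupper(as.character(seq)),
                            scoring, as.integer(offset), band)
  al$path <- al$walk[al$qpos >= 0]
  al
}

#' Spell the sequence of a walk in a variation graph
#'
#' Concatenates the node bases along a directed walk. Deletion-traversed
#' nodes contribute their graph base; insertions (which are not part of a
#' walk) contribute nothing — so the spelled sequence of an alignment walk
#' is the error-corrected sequence.
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @param path integer vector of node indices forming a directed walk.
#' @return The walk's sequence (character).
#' @export
extractPathSequence <- function(graph, path) {
  if (length(path) == 0) return("")
  if (any(path < 1 | path > nodeCount(graph)))
    stop("path refers to nodes outside the graph")
  if (length(path) > 1) {
    ekey <- paste(graph@edgeFrom, graph@edgeTo)
    pkey <- paste(path[-length(path)], path[-1])
    miss <- which(!(pkey %in% ekey))
    if (length(miss) > 0)
      stop("path uses missing edge ", path[miss[1]], "->", path[miss[1] + 1])
  }
  paste(graph@bases[path], collapse = "")
}

#' Heaviest-bundle consensus of a variation graph
#'
#' Returns the source-to-sink path maximising the total edge weight w(e)
#' (read counts for FASTA inputs, quality-discounted expected counts for
#' FASTQ), by dynamic programming over the topological order. This is the
#' cycle-2 consensus: with overlaps already restricted to one haplotype,
#' the heaviest bundle is the haplotype consensus.
#'
#' @param graph a \linkS4class{VariationGraph}.
#' @return list with \code{sequence}, \code{weight} (total edge weight of
#'   the returned path) and \code{path} (node indices).
#' @export
heaviestBundle <- function(graph) {
  stopifnot(is(graph, "VariationGraph"))
  if (nodeCount(graph) == 0)
    return(list(sequence = "", weight = 0, path = integer(0)))
  .cpp_heaviest_bundle(.vg_to_list(graph), 1)
}
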