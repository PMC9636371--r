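#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("DataFrameOrNull", c("DFrame", "NULL"))

#' ReadSet: a set of long reads with optional qualities and truth metadata
#'
#' Container for a collection of sequencing reads. Sequences are stored as a
#' named \link[Biostrings]{DNAStringSet}; per-base Phred qualities (integer
#' vectors) are kept when the input was FASTQ; simulation truth metadata
#' (haplotype of origin, interval, strand) travels in a
#' \link[S4Vectors]{DataFrame}.
#'
#' @slot seqs named \code{DNAStringSet} of read sequences (alphabet ACGT).
#' @slot quals list of integer Phred vectors parallel to \code{seqs}, or an
#'   empty list when qualities are absent.
#' @slot truth \code{DataFrame} of simulation metadata (zero rows when absent).
#' @exportClass ReadSet
setClass("ReadSet",
  representation(seqs = "DNAStringSet", quals = "list", truth = "DataFrameOrNull"))

setValidity("ReadSet", function(object) {
  if (length(object@seqs) == 0) return(TRUE)
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all reads must be named")
  if (anyDuplicated(ids))
    return("read ids must be unique")
  if (length(object@quals) > 0) {
    if (length(object@quals) != length(object@seqs))
      return("quals must parallel seqs")
    lens <- lengths(object@quals)
    if (any(lens != Biostrings::width(object@seqs)))
      return("quality length must equal sequence length")
    if (any(unlist(object@quals, use.names = FALSE) < 0))
      return("Phred scores must be non-negative")
  }
  if (!is.null(object@truth) && nrow(object@truth) > 0 &&
      nrow(object@truth) != length(object@seqs))
    return("truth metadata must have one row per read")
  TRUE
})

#' Construct a ReadSet
#'
#' Normalises sequences to the ACGT alphabet: any other letter (N, IUPAC
#' ambiguity codes) is replaced deterministically by A, with a message giving
#' the replacement count, because the variation-graph alphabet is exactly
#' \{A,C,G,T\}.
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param quals optional list of integer Phred vectors (one per read).
#' @param truth optional \code{DataFrame}/\code{data.frame} of truth metadata.
#' @return A \linkS4class{ReadSet}.
#' @export
ReadSet <- function(seqs, quals = NULL, truth = NULL) {
  s <- toupper(as.character(seqs))
  names(s) <- names(seqs)
  nbad <- sum(vapply(gregexpr("[^ACGT]", s), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1)))
  if (nbad > 0) {
    message(nbad, " non-ACGT base(s) replaced by A")
    s <- gsub("[^ACGT]", "A", s)
  }
  if (is.null(truth)) truth <- DataFrame()
  if (is.data.frame(truth)) truth <- DataFrame(truth)
  new("ReadSet", seqs = Biostrings::DNAStringSet(s),
      quals = if (is.null(quals)) list() else unname(quals), truth = truth)
}

#' @describeIn ReadSet read identifiers
#' @param x,object a \code{ReadSet}
#' @export
readIDs <- function(x) names(x@seqs)

#' @describeIn ReadSet sequences as a \code{DNAStringSet}
#' @export
readSeqs <- function(x) x@seqs

#' @describeIn ReadSet list of Phred integer vectors, or \code{NULL}
#' @export
readQuals <- function(x) if (length(x@quals)) x@quals else NULL

#' @describeIn ReadSet truth metadata \code{DataFrame}
#' @export
readTruth <- function(x) x@truth

#' @export
setMethod("length", "ReadSet", function(x) length(x@seqs))

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, readIDs(x))
  new("ReadSet", seqs = x@seqs[i],
      quals = if (length(x@quals)) x@quals[i] else list(),
      truth = if (!is.null(x@truth) && nrow(x@truth) > 0) x@truth[i, , drop = FALSE]
              else x@truth)
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet with", length(object), "reads;",
      if (length(object@quals)) "with" else "no", "qualities;",
      if (!is.null(object@truth) && nrow(object@truth) > 0) "with" else "no",
      "truth metadata\n")
  if (length(object) > 0)
    cat("  total bases:", sum(Biostrings::width(object@seqs)),
        " length range:", paste(range(Biostrings::width(object@seqs)),
                                collapse = "-"), "\n")
})

#' OverlapSet: pairwise read overlaps
#'
#' A set of pairwise overlap records in PAF-like form: 0-based half-open
#' coordinates on the forward strand of each read, relative strand, the
#' number of matching bases and the alignment block length, plus an optional
#' base-level identity (fraction in [0,1], \code{NA} until computed).
#'
#' @slot records data.frame with columns qid, qlen, qstart, qend, strand,
#'   tid, tlen, tstart, tend, nmatch, blocklen, identity.
#' @exportClass OverlapSet
setClass("OverlapSet", representation(records = "data.frame"))

.OVL_COLS <- c("qid", "qlen", "qstart", "qend", "strand", "tid", "tlen",
               "tstart", "tend", "nmatch", "blocklen", "identity")

setValidity("OverlapSet", function(object) {
  r <- object@records
  if (!all(.OVL_COLS %in% names(r))) return("missing overlap columns")
  if (nrow(r) == 0) return(TRUE)
  if (!all(r$strand %in% c("+", "-"))) return("strand must be + or -")
  if (any(r$qstart >= r$qend) || any(r$tstart >= r$tend))
    return("empty overlap interval")
  if (any(r$qend > r$qlen) || any(r$tend > r$tlen) ||
      any(r$qstart < 0) || any(r$tstart < 0))
    return("overlap coordinates outside read bounds")
  idok <- is.na(r$identity) | (r$identity >= 0 & r$identity <= 1)
  if (!all(idok)) return("identity must lie in [0,1]")
  TRUE
})

#' Construct an OverlapSet
#' @param records data.frame of overlap records (see class description).
#' @return An \linkS4class{OverlapSet}.
#' @export
OverlapSet <- function(records) {
  if (!"identity" %in% names(records)) records$identity <- NA_real_
  records <- records[, .OVL_COLS]
  rownames(records) <- NULL
  new("OverlapSet", records = records)
}

#' @describeIn OverlapSet records as a plain data.frame
#' @param x,object an \code{OverlapSet}
#' @export
overlapRecords <- function(x) x@records

#' @export
setMethod("length", "OverlapSet", function(x) nrow(x@records))

#' @export
setMethod("[", "OverlapSet", function(x, i, j, ..., drop = TRUE)
  new("OverlapSet", records = x@records[i, , drop = FALSE]))

setMethod("show", "OverlapSet", function(object) {
  cat("OverlapSet with", length(object), "overlaps")
  if (length(object) > 0)
    cat("; identity available for", sum(!is.na(object@records$identity)))
  cat("\n")
})

setAs("OverlapSet", "data.frame", function(from) from@records)

#' HaplotypeSet: a small set of related haplotype sequences
#'
#' @slot haplotypes named \code{DNAStringSet}.
#' @slot ani symmetric matrix of realized pairwise average nucleotide
#'   identities (diagonal 1).
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(haplotypes = "DNAStringSet", ani = "matrix"))

setValidity("HaplotypeSet", function(object) {
  k <- length(object@haplotypes)
  if (!all(dim(object@ani) == c(k, k))) return("ani must be k x k")
  if (k > 0 && any(abs(diag(object@ani) - 1) > 1e-12))
    return("ani diagonal must be 1")
  if (max(abs(object@ani - t(object@ani))) > 1e-9)
    return("ani must be symmetric")
  if (any(object@ani < 0 | object@ani > 1)) return("ani must lie in [0,1]")
  TRUE
})

#' @describeIn HaplotypeSet haplotype sequences
#' @param x,object a \code{HaplotypeSet}
#' @export
haplotypeSeqs <- function(x) x@haplotypes

#' @describeIn HaplotypeSet realized pairwise ANI matrix
#' @export
haplotypeANI <- function(x) x@ani

#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@haplotypes))

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet with", length(object), "haplotypes of length",
      paste(Biostrings::width(object@haplotypes), collapse = ", "), "\n")
  if (length(object) > 1)
    cat("  min pairwise ANI:",
        format(min(object@ani[upper.tri(object@ani)]), digits = 4), "\n")
})

#' VariationGraph: a base-labelled DAG with per-read walks
#'
#' Nodes carry single nucleotides; edges record adjacency observed in at
#' least one read; each read corresponds to a walk. Node \code{ranks} anchor
#' nodes to approximate window coordinates (used to band the
#' sequence-to-graph alignment). \code{pathConsumed} flags which walk steps
#' consume a read base (match/mismatch) as opposed to traversing a node the
#' read deletes; \code{pathProbs} carries the per-step base error
#' probabilities when the reads came with qualities (empty list = FASTA
#' weighting).
#'
#' @slot bases character vector of node bases.
#' @slot ranks integer vector of node window-coordinate anchors.
#' @slot edgeFrom,edgeTo integer vectors defining directed edges.
#' @slot pathIDs character vector of read ids.
#' @slot paths list of integer walks (node indices).
#' @slot pathConsumed list of logical vectors parallel to \code{paths}.
#' @slot pathProbs list of numeric vectors, or empty list.
#' @exportClass VariationGraph
setClass("VariationGraph",
  representation(bases = "character", ranks = "integer",
                 edgeFrom = "integer", edgeTo = "integer",
                 pathIDs = "character", paths = "list",
                 pathConsumed = "list", pathProbs = "list"))

setValidity("VariationGraph", function(object) {
  n <- length(object@bases)
  if (length(object@ranks) != n) return("ranks must parallel bases")
  if (n > 0 && !all(object@bases %in% c("A", "C", "G", "T")))
    return("node bases must be A/C/G/T")
  if (length(object@edgeFrom) != length(object@edgeTo))
    return("edge endpoint vectors differ in length")
  e <- c(object@edgeFrom, object@edgeTo)
  if (length(e) > 0 && (any(e < 1) || any(e > n)))
    return("edge endpoint out of range")
  if (length(object@paths) != length(object@pathIDs) ||
      length(object@pathConsumed) != length(object@pathIDs))
    return("paths/pathConsumed must parallel pathIDs")
  for (p in object@paths)
    if (length(p) > 0 && (any(p < 1) || any(p > n)))
      return("path node out of range")
  ok <- tryCatch({
    .cpp_topo_order(n, object@edgeFrom, object@edgeTo); TRUE
  }, error = function(e) FALSE)
  if (!ok) return("graph is not a DAG")
  TRUE
})

.vg_from_list <- function(gl) {
  new("VariationGraph",
      bases = as.character(gl$bases), ranks = as.integer(gl$ranks),
      edgeFrom = as.integer(gl$edge_from), edgeTo = as.integer(gl$edge_to),
      pathIDs = as.character(gl$path_ids), paths = gl$paths,
      pathConsumed = gl$path_consumed,
      pathProbs = if (is.null(gl$path_probs)) list() else gl$path_probs)
}

.vg_to_list <- function(g) {
  list(bases = g@bases, ranks = g@ranks,
       edge_from = g@edgeFrom, edge_to = g@edgeTo,
       path_ids = g@pathIDs, paths = g@paths,
       path_consumed = g@pathConsumed,
       path_probs = if (length(g@pathProbs)) g@pathProbs else NULL)
}

#' @describeIn VariationGraph number of nodes
#' @param x,object a \code{VariationGraph}
#' @export
nodeCount <- function(x) length(x@bases)

#' @describeIn VariationGraph number of edges
#' @export
edgeCount <- function(x) length(x@edgeFrom)

#' @describeIn VariationGraph node table (id, base, rank)
#' @export
graphNodes <- function(x)
  data.frame(node = seq_along(x@bases), base = x@bases, rank = x@ranks)

#' @describeIn VariationGraph edge table (from, to)
#' @export
graphEdges <- function(x)
  data.frame(from = x@edgeFrom, to = x@edgeTo)

#' @describeIn VariationGraph named list of read walks
#' @export
graphPaths <- function(x) stats::setNames(x@paths, x@pathIDs)

setMethod("show", "VariationGraph", function(object) {
  cat("VariationGraph:", nodeCount(object), "nodes,", edgeCount(object),
      "edges,", length(object@pathIDs), "read paths",
      if (length(object@pathProbs)) "(FASTQ weighting)\n" else "(FASTA weighting)\n")
})

#' EvalReport: accuracy of corrected reads against truth haplotypes
#'
#' @slot nReads number of evaluated reads.
#' @slot nUnaligned reads that could not be aligned to any haplotype.
#' @slot errorRate,mismatchRate,indelRate aggregate per-base rates (fractions).
#' @slot haplotypeCoverage fraction of truth haplotype bases covered.
#' @slot perRead per-read alignment table.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(nReads = "integer", nUnaligned = "integer",
                 errorRate = "numeric", mismatchRate = "numeric",
                 indelRate = "numeric", haplotypeCoverage = "numeric",
                 perRead = "data.frame"))

#' @describeIn EvalReport aggregate error rate (mismatch + indel fraction)
#' @param x,object an \code{EvalReport}
#' @export
errorRate <- function(x) x@errorRate

#' @describeIn EvalReport aggregate mismatch fraction
#' @export
mismatchRate <- function(x) x@mismatchRate

#' @describeIn EvalReport aggregate indel fraction
#' @export
indelRate <- function(x) x@indelRate

#' @describeIn EvalReport fraction of truth bases covered by aligned reads
#' @export
haplotypeCoverage <- function(x) x@haplotypeCoverage

#' @describeIn EvalReport per-read alignment table
#' @export
perRead <- function(x) x@perRead

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport on", object@nReads, "reads (",
      object@nUnaligned, "unaligned )\n")
  if (object@nReads > object@nUnaligned) {
    cat(sprintf("  error rate:    %.4f%% (mismatch %.4f%% + indel %.4f%%)\n",
                100 * object@errorRate, 100 * object@mismatchRate,
                100 * object@indelRate))
    cat(sprintf("  haplotype coverage: %.2f%%\n",
                100 * object@haplotypeCoverage))
  }
})

#' CorrectionResult: output of the two-cycle correction pipeline
#'
#' @slot corrected final corrected reads.
#' @slot cycle1 pre-corrected reads after the first cycle.
#' @slot stats list of per-stage counters.
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  representation(corrected = "ReadSet", cycle1 = "ReadSet", stats = "list"))

#' @describeIn CorrectionResult final corrected reads
#' @param x,object a \code{CorrectionResult}
#' @export
correctedReads <- function(x) x@corrected

#' @describeIn CorrectionResult pre-corrected reads from cycle 1
#' @export
cycle1Reads <- function(x) x@cycle1

#' @describeIn CorrectionResult per-stage counters
#' @export
correctionStats <- function(x) x@stats

setMethod("show", "CorrectionResult", function(object) {
  cat("CorrectionResult:", length(object@corrected), "corrected reads (from",
      object@stats$n_input, "input reads)\n")
})
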