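#' Compute all-vs-all read overlaps from minimizer anchors
#'
#' Canonical (w,k)-minimizers are indexed across all reads; anchor hits
#' between a read pair on a consistent relative strand are clustered by
#' diagonal, and a cluster of at least \code{min_chain} anchors yields one
#' overlap record spanning the chained anchors. Symmetric duplicates
#' (A-B and B-A) are collapsed to a single record. Coordinates are 0-based
#' half-open on the forward strand of each read; \code{nmatch} is the
#' approximate number of anchored matching bases and \code{blocklen} the
#' anchored span, so \code{nmatch/blocklen} is a (crude) identity proxy
#' until \code{\link{computeOverlapIdentity}} refines it.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param k minimizer k-mer size (2..28).
#' @param w minimizer window size.
#' @param min_chain minimum chained anchors per overlap.
#' @param max_occ ignore minimizers occurring more often than this.
#' @return An \linkS4class{OverlapSet}.
#' @export
computeOverlaps <- function(reads, k = 15L, w = 5L, min_chain = 4L,
                            max_occ = 500L) {
  stopifnot(is(reads, "ReadSet"), k >= 2, k <= 28, w >= 1)
  ids <- readIDs(reads)
  lens <- Biostrings::width(readSeqs(reads))
  df <- .cpp_all_overlaps(as.character(readSeqs(reads)), k, w, min_chain,
                          max_occ, 300L)
  if (length(df$qidx) == 0)
    return(OverlapSet(data.frame(qid = character(), qlen = integer(),
                                 qstart = integer(), qend = integer(),
                                 strand = character(), tid = character(),
                                 tlen = integer(), tstart = integer(),
                                 tend = integer(), nmatch = integer(),
                                 blocklen = integer(),
                                 identity = numeric())))
  rec <- data.frame(qid = ids[df$qidx], qlen = lens[df$qidx],
                    qstart = df$qstart, qend = df$qend, strand = df$strand,
                    tid = ids[df$tidx], tlen = lens[df$tidx],
                    tstart = df$tstart, tend = df$tend,
                    nmatch = df$nmatch, blocklen = df$blocklen,
                    identity = NA_real_, stringsAsFactors = FALSE)
  OverlapSet(rec)
}

.check_overlap_reads <- function(overlaps, reads) {
  r <- overlapRecords(overlaps)
  ids <- readIDs(reads)
  unknown <- setdiff(unique(c(r$qid, r$tid)), ids)
  if (length(unknown) > 0)
    stop("overlaps reference unknown read id(s): ",
         paste(head(unknown, 3), collapse = ", "))
  invisible(TRUE)
}

#' Cycle-1 overlap filters
#'
#' Removes (a) overlaps whose mapped length does not exceed
#' \code{min_len} on either read, (b) self-overlaps, (c) internal matches
#' (both overhangs on one read exceed
#' \code{min(internal_match_overhang, internal_match_ratio * mapped length)}),
#' and (d) overlaps with mapping-length-ratio error
#' \code{|1 - min(Lq,Lt)/max(Lq,Lt)| >= max_len_ratio_err}, where
#' \code{Lq = qend - qstart} and \code{Lt = tend - tstart}. The filter is
#' idempotent and order-independent.
#'
#' @param overlaps an \linkS4class{OverlapSet}.
#' @param reads the \linkS4class{ReadSet} the overlaps refer to.
#' @param cfg an \code{\link{overlapFilterConfig}}.
#' @return The filtered \linkS4class{OverlapSet}.
#' @export
filterOverlapsCycle1 <- function(overlaps, reads,
                                 cfg = overlapFilterConfig()) {
  .check_overlap_reads(overlaps, reads)
  r <- overlapRecords(overlaps)
  if (nrow(r) == 0) return(overlaps)
  lq <- r$qend - r$qstart
  lt <- r$tend - r$tstart
  minl <- pmin(lq, lt)
  keep_len <- if (cfg$strict_min_len) minl > cfg$min_len else
    minl >= cfg$min_len
  keep_self <- r$qid != r$tid
  thr_q <- pmin(cfg$internal_match_overhang, cfg$internal_match_ratio * lq)
  thr_t <- pmin(cfg$internal_match_overhang, cfg$internal_match_ratio * lt)
  internal_q <- r$qstart > thr_q & (r$qlen - r$qend) > thr_q
  internal_t <- r$tstart > thr_t & (r$tlen - r$tend) > thr_t
  ratio_err <- abs(1 - minl / pmax(lq, lt))
  keep_ratio <- ratio_err < cfg$max_len_ratio_err
  overlaps[keep_len & keep_self & !(internal_q | internal_t) & keep_ratio]
}

#' Base-level overlap identity
#'
#' Globally aligns the two mapped substrings of each overlap (reverse-
#' complementing the query side for minus-strand records) and sets
#' \code{identity = matches / alignment columns}; \code{nmatch} and
#' \code{blocklen} are refined to the alignment's values.
#'
#' @param overlaps an \linkS4class{OverlapSet}.
#' @param reads the \linkS4class{ReadSet} the overlaps refer to.
#' @param band initial alignment band half-width (doubles on failure, full
#'   dynamic programming as last resort).
#' @return The \linkS4class{OverlapSet} with identity filled in.
#' @export
computeOverlapIdentity <- function(overlaps, reads, band = 64L) {
  .check_overlap_reads(overlaps, reads)
  r <- overlapRecords(overlaps)
  if (nrow(r) == 0) return(overlaps)
  seqs <- as.character(readSeqs(reads))
  names(seqs) <- readIDs(reads)
  for (i in seq_len(nrow(r))) {
    qsub <- substr(seqs[r$qid[i]], r$qstart[i] + 1, r$qend[i])
    tsub <- substr(seqs[r$tid[i]], r$tstart[i] + 1, r$tend[i])
    if (nchar(qsub) == 0 || nchar(tsub) == 0)
      stop("empty mapped substring in overlap ", i)
    if (r$strand[i] == "-") qsub <- .revcomp(qsub)
    al <- .cpp_edit_align(tsub, qsub, band0 = band, band_frac = 0.15)
    r$identity[i] <- al$nmatch / al$ncols
    r$nmatch[i] <- al$nmatch
    r$blocklen[i] <- al$ncols
  }
  OverlapSet(r)
}

#' Cycle-2 overlap filter (same-haplotype restriction)
#'
#' Applies all cycle-1 filters, then keeps only overlaps with base-level
#' \code{identity >= delta}. The default delta = 0.99 follows from the
#' cycle-1 residual error of ~0.5% on simulated data: a same-haplotype
#' overlap of two pre-corrected reads carries at most ~2 x 0.5% = 1%
#' divergence, so identity >= 1 - 1% = 0.99.
#'
#' @param overlaps an \linkS4class{OverlapSet} with identity present.
#' @param reads the \linkS4class{ReadSet} the overlaps refer to.
#' @param delta minimum overlap identity (0.99 simulated, 0.98 real).
#' @param cfg an \code{\link{overlapFilterConfig}} for the cycle-1 part.
#' @return The filtered \linkS4class{OverlapSet}.
#' @export
filterOverlapsCycle2 <- function(overlaps, reads, delta = 0.99,
                                 cfg = overlapFilterConfig()) {
  r <- overlapRecords(overlaps)
  if (nrow(r) > 0 && anyNA(r$identity))
    stop("all overlaps must carry identity; run computeOverlapIdentity first")
  out <- filterOverlapsCycle1(overlaps, reads, cfg)
  out[overlapRecords(out)$identity >= delta]
}

#' Extend overlaps to dovetail ends
#'
#' Symmetrically extends each overlap towards the read ends by the smaller
#' of the two available slacks, so that the pile covers full dovetails
#' rather than only the anchored span. Internal-match classification must
#' happen before extension (the pipeline filters first).
#'
#' @param overlaps an \linkS4class{OverlapSet}.
#' @param reads the \linkS4class{ReadSet} the overlaps refer to.
#' @return The extended \linkS4class{OverlapSet}.
#' @export
extendOverlaps <- function(overlaps, reads) {
  .check_overlap_reads(overlaps, reads)
  r <- overlapRecords(overlaps)
  if (nrow(r) == 0) return(overlaps)
  plus <- r$strand == "+"
  extl <- ifelse(plus, pmin(r$qstart, r$tstart),
                 pmin(r$qlen - r$qend, r$tstart))
  extr <- ifelse(plus, pmin(r$qlen - r$qend, r$tlen - r$tend),
                 pmin(r$qstart, r$tlen - r$tend))
  r$tstart <- r$tstart - extl
  r$tend <- r$tend + extr
  r$qstart <- r$qstart - ifelse(plus, extl, extr)
  r$qend <- r$qend + ifelse(plus, extr, extl)
  r$blocklen <- pmax(r$qend - r$qstart, r$tend - r$tstart)
  OverlapSet(r)
}
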