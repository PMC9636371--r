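#' Build the read alignment pile for a target read
#'
#' Collects all surviving overlaps involving the target, orients each
#' overlapping read into target orientation (reverse-complementing
#' minus-strand records), restricts it to the overlap interval (dangling
#' ends outside the overlap are removed), and aligns the two mapped
#' substrings by banded global edit distance. The alignment traceback gives
#' each fragment a monotone column map from fragment positions to target
#' coordinates, which is what window segmentation cuts along. Fragments are
#' sorted canonically by read id so the pile does not depend on overlap
#' input order.
#'
#' @param target_id id of the target read.
#' @param overlaps a filtered \linkS4class{OverlapSet}.
#' @param reads the \linkS4class{ReadSet}.
#' @param band initial edit-alignment band half-width.
#' @return A list of pile fragments, each a list with elements
#'   \code{read_id}, \code{orient}, \code{target_interval} (0-based
#'   half-open), \code{frag_seq}, \code{frag_quals} (or NULL),
#'   \code{colmap} (integer, 0-based target position per fragment base,
#'   -1 for inserted bases) and \code{identity}.
#' @export
buildPile <- function(target_id, overlaps, reads, band = 64L) {
  .check_overlap_reads(overlaps, reads)
  r <- overlapRecords(overlaps)
  r <- r[(r$qid == target_id | r$tid == target_id) & r$qid != r$tid, ,
         drop = FALSE]
  if (nrow(r) == 0) return(list())
  seqs <- as.character(readSeqs(reads))
  names(seqs) <- readIDs(reads)
  quals <- readQuals(reads)
  if (!is.null(quals)) names(quals) <- readIDs(reads)
  tlen <- nchar(seqs[target_id])

  # normalise records so the target is always the anchor
  as_t <- r$tid == target_id
  norm <- data.frame(
    other = ifelse(as_t, r$qid, r$tid),
    os = ifelse(as_t, r$qstart, r$tstart),
    oe = ifelse(as_t, r$qend, r$tend),
    ts = ifelse(as_t, r$tstart, r$qstart),
    te = ifelse(as_t, r$tend, r$qend),
    strand = r$strand, stringsAsFactors = FALSE)
  norm <- norm[order(norm$other, norm$ts), , drop = FALSE]

  frags <- vector("list", nrow(norm))
  for (i in seq_len(nrow(norm))) {
    os <- norm$os[i]; oe <- norm$oe[i]
    ts <- max(0L, norm$ts[i]); te <- min(tlen, norm$te[i])
    if (os < 0 || oe > nchar(seqs[norm$other[i]]) || ts >= te)
      stop("overlap coordinates outside read bounds for ", norm$other[i])
    frag <- unname(substr(seqs[norm$other[i]], os + 1, oe))
    fq <- if (!is.null(quals)) quals[[norm$other[i]]][(os + 1):oe] else NULL
    if (norm$strand[i] == "-") {
      frag <- .revcomp(frag)
      if (!is.null(fq)) fq <- rev(fq)
    }
    tsub <- substr(seqs[target_id], ts + 1, te)
    al <- .cpp_edit_align(tsub, frag, band0 = band, band_frac = 0.15)
    cm <- al$colmap
    cm[cm >= 0] <- cm[cm >= 0] + ts
    frags[[i]] <- list(read_id = norm$other[i], orient = norm$strand[i],
                       target_interval = c(ts, te), frag_seq = frag,
                       frag_quals = fq, colmap = cm,
                       identity = al$nmatch / al$ncols)
  }
  frags
}

#' Segment an alignment pile into target-anchored windows
#'
#' Cuts the target read into \code{ceiling(len/window_len)} non-overlapping
#' windows (all of length \code{window_len} except possibly the last) and
#' clips every pile fragment at window boundaries along its column map.
#' Fragments contributing fewer than \code{min_frag} bases to a window are
#' dropped from that window; if more than \code{max_frags} remain, the
#' highest-identity fragments are kept. Within a window, fragments are
#' ordered by decreasing identity (ties by read id), the order in which the
#' variation graph will take them up.
#'
#' @param target_seq target read sequence (character).
#' @param target_quals optional integer Phred vector for the target.
#' @param pile output of \code{\link{buildPile}}.
#' @param window_len window length in bp.
#' @param min_frag minimum bases a fragment must contribute to a window.
#' @param max_frags per-window fragment cap.
#' @return A list of windows, each a list with \code{window_index},
#'   \code{target_interval}, \code{target_subread}, \code{target_quals} and
#'   \code{fragments} (list of \code{read_id}, \code{seq}, \code{quals},
#'   \code{offset} = start of the fragment in window coordinates,
#'   \code{identity}).
#' @export
segmentWindows <- function(target_seq, target_quals = NULL, pile = list(),
                           window_len = 500L, min_frag = 50L,
                           max_frags = 200L) {
  L <- nchar(target_seq)
  stopifnot(L > 0)
  nw <- ceiling(L / window_len)
  win_frags <- vector("list", nw)
  for (f in pile) {
    cons <- which(f$colmap >= 0L)
    if (length(cons) == 0) next
    cp <- f$colmap[cons]
    wi <- cp %/% window_len
    for (wid in unique(wi)) {
      sel <- cons[wi == wid]
      i1 <- sel[1]; i2 <- sel[length(sel)]
      if (i2 - i1 + 1 < min_frag) next
      ws <- wid * window_len
      win_frags[[wid + 1]] <- c(win_frags[[wid + 1]], list(list(
        read_id = f$read_id,
        seq = substr(f$frag_seq, i1, i2),
        quals = if (!is.null(f$frag_quals)) f$frag_quals[i1:i2] else NULL,
        offset = f$colmap[i1] - ws,
        identity = f$identity)))
    }
  }
  windows <- vector("list", nw)
  for (wid in seq_len(nw)) {
    ws <- (wid - 1L) * window_len
    we <- min(L, ws + window_len)
    fr <- win_frags[[wid]]
    if (!is.null(fr) && length(fr) > 0) {
      idn <- vapply(fr, `[[`, numeric(1), "identity")
      rid <- vapply(fr, `[[`, character(1), "read_id")
      ord <- order(-idn, rid)
      if (length(ord) > max_frags) ord <- ord[seq_len(max_frags)]
      fr <- fr[ord]
    } else fr <- list()
    windows[[wid]] <- list(
      window_index = wid,
      target_interval = c(ws, we),
      target_subread = substr(target_seq, ws + 1, we),
      target_quals = if (!is.null(target_quals)) target_quals[(ws + 1):we]
                     else NULL,
      fragments = fr)
  }
  windows
}
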