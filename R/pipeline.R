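#' First correction cycle: graph pruning
#'
#' For every target read: surviving overlaps are gathered, the alignment
#' pile is built and segmented into windows, and per window a variation
#' graph is constructed, pruned iteratively (Support/Confidence), and the
#' raw target subread realigned against the pruned graph. Pre-corrected
#' subreads are concatenated in window order. Reads without usable overlaps
#' pass through unchanged and are counted.
#'
#' @param reads a \linkS4class{ReadSet} (at least 2 reads).
#' @param cfg a \code{\link{runConfig}}.
#' @param overlaps optional precomputed \linkS4class{OverlapSet} (e.g. from
#'   an external PAF); when given, the internal overlapper is bypassed.
#' @param verbose print per-stage progress.
#' @return A \linkS4class{ReadSet} of pre-corrected reads (no qualities;
#'   truth metadata carried over). Attribute \code{stats} holds counters.
#' @export
runCycle1 <- function(reads, cfg = runConfig(), overlaps = NULL,
                      verbose = FALSE) {
  stopifnot(is(reads, "ReadSet"))
  if (length(reads) < 2) stop("need at least 2 reads")
  if (is.null(overlaps))
    overlaps <- computeOverlaps(reads, cfg$k, cfg$w, cfg$min_chain)
  filt <- filterOverlapsCycle1(overlaps, reads, cfg$overlap1)
  ext <- extendOverlaps(filt, reads)
  if (verbose)
    message("cycle 1: ", length(overlaps), " overlaps, ",
            length(filt), " after filters")
  .correct_all_targets(reads, ext, cfg, cycle = 1L, verbose = verbose)
}

#' Second correction cycle: haplotype-restricted consensus
#'
#' Overlaps of the pre-corrected reads are recomputed with base-level
#' identity; cycle-1 filters plus the identity filter (\code{identity >=
#' delta}) restrict piles to same-haplotype reads, and per window a single
#' heaviest-bundle consensus replaces the target subread (no pruning).
#' Windows with fewer than \code{min_window_reads} fragments pass the
#' target subread through unchanged.
#'
#' @param pre_corrected a \linkS4class{ReadSet} from \code{\link{runCycle1}}.
#' @param cfg a \code{\link{runConfig}}.
#' @param verbose print per-stage progress.
#' @return A \linkS4class{ReadSet} of corrected reads.
#' @export
runCycle2 <- function(pre_corrected, cfg = runConfig(), verbose = FALSE) {
  stopifnot(is(pre_corrected, "ReadSet"))
  if (length(pre_corrected) < 2) stop("need at least 2 reads")
  overlaps <- computeOverlaps(pre_corrected, cfg$k, cfg$w, cfg$min_chain)
  filt1 <- filterOverlapsCycle1(overlaps, pre_corrected, cfg$overlap1)
  withid <- computeOverlapIdentity(filt1, pre_corrected, band = cfg$band)
  filt2 <- filterOverlapsCycle2(withid, pre_corrected, cfg$delta,
                                cfg$overlap1)
  ext <- extendOverlaps(filt2, pre_corrected)
  if (verbose)
    message("cycle 2: ", length(filt1), " overlaps, ", length(filt2),
            " with identity >= ", cfg$delta)
  .correct_all_targets(pre_corrected, ext, cfg, cycle = 2L,
                       verbose = verbose)
}

.correct_all_targets <- function(reads, overlaps, cfg, cycle,
                                 verbose = FALSE) {
  ids <- readIDs(reads)
  seqs <- as.character(readSeqs(reads))
  quals <- readQuals(reads)
  rec <- overlapRecords(overlaps)
  n_pass <- 0L; n_win <- 0L; n_win_skip <- 0L; n_win_empty <- 0L
  out <- character(length(ids))
  for (ti in seq_along(ids)) {
    tid <- ids[ti]
    involved <- rec$qid == tid | rec$tid == tid
    if (!any(involved)) {
      out[ti] <- seqs[ti]
      n_pass <- n_pass + 1L
      next
    }
    pile <- buildPile(tid, overlaps[involved], reads, band = 2L * cfg$band)
    wins <- segmentWindows(seqs[ti], if (is.null(quals)) NULL else quals[[ti]],
                           pile, cfg$window_len, cfg$min_frag, cfg$max_frags)
    subs <- character(length(wins))
    for (wi in seq_along(wins)) {
      w <- wins[[wi]]
      n_win <- n_win + 1L
      if (length(w$fragments) < cfg$min_window_reads) {
        subs[wi] <- w$target_subread
        n_win_skip <- n_win_skip + 1L
        next
      }
      fids <- vapply(w$fragments, `[[`, character(1), "read_id")
      fseqs <- vapply(w$fragments, `[[`, character(1), "seq")
      foffs <- vapply(w$fragments, function(f) as.integer(f$offset),
                      integer(1))
      fprobs <- if (is.null(quals)) NULL else
        lapply(w$fragments, function(f) phredToErrorProb(f$quals))
      tprobs <- if (is.null(quals)) NULL else
        phredToErrorProb(w$target_quals)
      res <- .cpp_correct_window(w$target_subread, tprobs,
                                 fids, fseqs, fprobs, foffs, cfg$scoring,
                                 cfg$prune$confidence,
                                 cfg$prune$support_factor,
                                 cfg$prune$iterations, cycle, cfg$band)
      subs[wi] <- res$seq
      if (res$status == 2L) n_win_empty <- n_win_empty + 1L
    }
    out[ti] <- paste(subs, collapse = "")
    if (verbose && ti %% 50 == 0)
      message("  corrected ", ti, "/", length(ids), " reads")
  }
  names(out) <- ids
  rs <- ReadSet(out, truth = readTruth(reads))
  attr(rs, "stats") <- list(cycle = cycle, n_reads = length(ids),
                            n_passthrough = n_pass, n_windows = n_win,
                            n_windows_lowcov = n_win_skip,
                            n_windows_empty_graph = n_win_empty)
  rs
}

#' Two-cycle haplotype-aware read correction
#'
#' Runs cycle 1 (variation-graph pruning) then cycle 2
#' (haplotype-restricted heaviest-bundle consensus) and filters corrected
#' reads shorter than 500 bp from the output. Reads that no stage could
#' correct are kept (passed through) unless \code{cfg$keep_uncorrected}
#' is FALSE.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param cfg a \code{\link{runConfig}}.
#' @param overlaps optional precomputed cycle-1 \linkS4class{OverlapSet}.
#' @param verbose print progress.
#' @return A \linkS4class{CorrectionResult}.
#' @export
correctReads <- function(reads, cfg = runConfig(), overlaps = NULL,
                         verbose = FALSE) {
  stopifnot(is(reads, "ReadSet"))
  if (length(reads) == 0) {
    warning("empty input; nothing to correct")
    empty <- ReadSet(character(0))
    return(new("CorrectionResult", corrected = empty, cycle1 = empty,
               stats = list(n_input = 0L)))
  }
  c1 <- runCycle1(reads, cfg, overlaps = overlaps, verbose = verbose)
  s1 <- attr(c1, "stats")
  c2 <- runCycle2(c1, cfg, verbose = verbose)
  s2 <- attr(c2, "stats")
  keep <- Biostrings::width(readSeqs(c2)) >= 500L
  if (!cfg$keep_uncorrected) {
    # drop reads that passed through both cycles untouched
    untouched <- as.character(readSeqs(c2)) == as.character(readSeqs(reads))
    keep <- keep & !untouched
  }
  new("CorrectionResult", corrected = c2[keep], cycle1 = c1,
      stats = list(n_input = length(reads), n_output = sum(keep),
                   n_dropped_short = sum(!keep), cycle1 = s1, cycle2 = s2))
}
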