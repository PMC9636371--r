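#' Evaluate corrected reads against truth haplotypes
#'
#' Each read is aligned end-to-end (free ends on the haplotype) to every
#' haplotype on both strands; the best-scoring alignment is kept. The error
#' rate is the fraction of alignment columns that are mismatches,
#' insertions or deletions, aggregated over all reads (so
#' \code{errorRate == mismatchRate + indelRate}). Haplotype coverage is the
#' fraction of truth haplotype bases covered by at least one aligned read.
#' Reads that cannot be aligned to any haplotype are counted separately.
#'
#' @param corrected a \linkS4class{ReadSet}.
#' @param truth a \linkS4class{HaplotypeSet}.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateCorrected <- function(corrected, truth) {
  stopifnot(is(corrected, "ReadSet"), is(truth, "HaplotypeSet"))
  hs <- as.character(haplotypeSeqs(truth))
  n <- length(corrected)
  if (n == 0)
    return(new("EvalReport", nReads = 0L, nUnaligned = 0L,
               errorRate = NA_real_, mismatchRate = NA_real_,
               indelRate = NA_real_, haplotypeCoverage = 0,
               perRead = data.frame()))
  ids <- readIDs(corrected)
  seqs <- as.character(readSeqs(corrected))
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    best <- NULL
    for (h in names(hs)) for (strand in c("+", "-")) {
      qs <- if (strand == "+") seqs[r] else .revcomp(seqs[r])
      al <- .cpp_map_align(hs[[h]], qs, k = 13L, band0 = 64L)
      if (!isTRUE(al$ok)) next
      if (is.null(best) || al$dist < best$dist)
        best <- c(al, list(hap = h, strand = strand))
    }
    rows[[r]] <- if (is.null(best)) {
      data.frame(id = ids[r], hap = NA_character_, strand = NA_character_,
                 aligned_len = 0L, nmatch = 0L, mismatches = 0L,
                 insertions = 0L, deletions = 0L,
                 ref_start = NA_integer_, ref_end = NA_integer_)
    } else {
      data.frame(id = ids[r], hap = best$hap, strand = best$strand,
                 aligned_len = best$ncols, nmatch = best$nmatch,
                 mismatches = best$nmismatch, insertions = best$nins,
                 deletions = best$ndel, ref_start = best$ref_start,
                 ref_end = best$ref_end)
    }
  }
  per <- do.call(rbind, rows)
  aligned <- !is.na(per$hap)
  cols <- sum(per$aligned_len[aligned])
  mm <- sum(per$mismatches[aligned])
  ind <- sum(per$insertions[aligned] + per$deletions[aligned])
  covered <- 0
  for (h in names(hs)) {
    sel <- aligned & per$hap == h
    if (!any(sel)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = per$ref_start[sel] + 1L,
                                           end = per$ref_end[sel]))
    covered <- covered + sum(IRanges::width(ir))
  }
  new("EvalReport", nReads = as.integer(n),
      nUnaligned = as.integer(sum(!aligned)),
      errorRate = if (cols > 0) (mm + ind) / cols else NA_real_,
      mismatchRate = if (cols > 0) mm / cols else NA_real_,
      indelRate = if (cols > 0) ind / cols else NA_real_,
      haplotypeCoverage = covered / sum(nchar(hs)),
      perRead = per)
}

#' Haplotype preservation at truth SNP loci
#'
#' For reads carrying truth metadata (haplotype of origin), aligns each read
#' to its origin haplotype and checks the read base at every truth SNP locus
#' the alignment spans. A read is concordant when all spanned SNP loci carry
#' the origin haplotype's allele; a locus deleted in the read counts as
#' discordant. Reads spanning no SNP are excluded from the fraction.
#'
#' @param reads a \linkS4class{ReadSet} with truth metadata.
#' @param haps the truth \linkS4class{HaplotypeSet} (diploid harness: SNPs
#'   between haplotypes 1 and 2).
#' @param snps optional precomputed \code{\link{haplotypeSNPs}} table.
#' @return list with \code{fraction} (concordant / spanning), \code{per_read}
#'   data.frame (id, n_snps, n_correct, concordant) and \code{n_spanning}.
#' @export
snpConcordance <- function(reads, haps, snps = NULL) {
  stopifnot(is(reads, "ReadSet"))
  tr <- readTruth(reads)
  if (is.null(tr) || nrow(tr) == 0) stop("reads carry no truth metadata")
  if (is.null(snps)) snps <- haplotypeSNPs(haps)
  hs <- as.character(haplotypeSeqs(haps))
  loci <- list(hap1 = list(pos = snps$pos_i, allele = snps$allele_i),
               hap2 = list(pos = snps$pos_j, allele = snps$allele_j))
  names(loci) <- names(hs)[1:2]
  ids <- readIDs(reads)
  seqs <- as.character(readSeqs(reads))
  res <- vector("list", length(reads))
  for (r in seq_along(seqs)) {
    h <- tr$hap[r]
    if (!h %in% names(loci)) next
    best <- NULL
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") seqs[r] else .revcomp(seqs[r])
      al <- .cpp_map_align(hs[[h]], qs, k = 13L, band0 = 64L, pairs = TRUE)
      if (!isTRUE(al$ok)) next
      if (is.null(best) || al$dist < best$dist) best <- al
    }
    if (is.null(best)) next
    lp <- loci[[h]]
    span <- lp$pos >= best$ref_start & lp$pos < best$ref_end
    nsnp <- sum(span)
    if (nsnp == 0) {
      res[[r]] <- data.frame(id = ids[r], n_snps = 0L, n_correct = 0L,
                             concordant = NA)
      next
    }
    hit <- match(lp$pos[span], best$pair_ref)
    ncorrect <- sum(!is.na(hit) & best$pair_match[hit])
    res[[r]] <- data.frame(id = ids[r], n_snps = nsnp,
                           n_correct = as.integer(ncorrect),
                           concordant = ncorrect == nsnp)
  }
  per <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  spanning <- per[!is.na(per$concordant), , drop = FALSE]
  list(fraction = if (nrow(spanning) > 0)
         mean(spanning$concordant) else NA_real_,
       per_read = per, n_spanning = nrow(spanning))
}
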