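#' Read sequences from FASTA or FASTQ
#'
#' Parses a (possibly gzipped) FASTA or FASTQ file into a
#' \linkS4class{ReadSet}. FASTQ records yield per-base Phred qualities
#' (Phred+33 by default); FASTA records carry none. Identifiers are the
#' first whitespace-delimited token of each header. An empty file yields an
#' empty ReadSet.
#'
#' @param path input file.
#' @param format "fasta", "fastq" or "auto" (decide from the file extension,
#'   falling back to the first byte).
#' @param phred_offset quality encoding offset (33 for modern FASTQ).
#' @return A \linkS4class{ReadSet}.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq"),
                          phred_offset = 33L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .sniff_format(path)
  res <- tryCatch({
    if (format == "fastq") {
      x <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
      qs <- S4Vectors::mcols(x)$qualities
      quals <- lapply(as.character(qs), function(s) utf8ToInt(s) - phred_offset)
      list(seqs = as.character(x), quals = quals)
    } else {
      x <- Biostrings::readBStringSet(path, format = "fasta")
      list(seqs = as.character(x), quals = NULL)
    }
  }, error = function(e)
    stop("malformed ", format, " file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  ids <- sub("\\s.*$", "", names(res$seqs))
  if (length(res$seqs) > 0 && !is.null(res$quals)) {
    bad <- which(nchar(res$seqs) != lengths(res$quals))
    if (length(bad) > 0)
      stop("sequence/quality length mismatch at record ", bad[1])
    if (any(unlist(res$quals) < 0))
      stop("negative Phred score; wrong quality encoding offset?")
  }
  names(res$seqs) <- ids
  ReadSet(res$seqs, quals = res$quals)
}

.sniff_format <- function(path) {
  low <- tolower(sub("\\.gz$", "", path))
  if (grepl("\\.(fq|fastq)$", low)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)$", low)) return("fasta")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0) return("fasta")   # empty file: empty ReadSet
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Write sequences to FASTA or FASTQ
#'
#' Reads with empty sequences are skipped with a warning. Corrected reads
#' carry no meaningful qualities and are written as FASTA; FASTQ output
#' requires qualities to be present.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param path output file.
#' @param format "fasta" or "fastq".
#' @param phred_offset quality encoding offset.
#' @return Invisibly, the number of records written.
#' @export
writeSequences <- function(reads, path, format = c("fasta", "fastq"),
                           phred_offset = 33L) {
  format <- match.arg(format)
  empty <- Biostrings::width(readSeqs(reads)) == 0
  if (any(empty)) {
    warning(sum(empty), " empty sequence(s) skipped")
    reads <- reads[!empty]
  }
  s <- readSeqs(reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(s, path)
  } else {
    q <- readQuals(reads)
    if (is.null(q)) stop("FASTQ output requires qualities")
    qs <- Biostrings::BStringSet(vapply(q, function(v)
      intToUtf8(v + phred_offset), character(1)))
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = qs)
  }
  invisible(length(s))
}

#' Convert a Phred score to an error probability
#'
#' \code{10^(-q/10)}, clamped to [0,1].
#'
#' @param q non-negative Phred score(s).
#' @return Numeric error probabilities.
#' @export
phredToErrorProb <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  pmin(1, 10^(-q / 10))
}

#' Read overlaps from a PAF file
#'
#' Parses minimap2-dialect PAF (columns 1-12; additional tag columns are
#' ignored). Coordinates are 0-based half-open, as in the file.
#'
#' @param path PAF file.
#' @param identity derive \code{identity = nmatch / blocklen} from columns
#'   10-11 (otherwise identity is left \code{NA}).
#' @return An \linkS4class{OverlapSet}.
#' @export
readPAF <- function(path, identity = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(OverlapSet(data.frame(qid = character(), qlen = integer(),
                                 qstart = integer(), qend = integer(),
                                 strand = character(), tid = character(),
                                 tlen = integer(), tstart = integer(),
                                 tend = integer(), nmatch = integer(),
                                 blocklen = integer(),
                                 identity = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12)
  if (length(short) > 0)
    stop("PAF line ", short[1], " has fewer than 12 columns")
  getc <- function(i) vapply(fields, `[[`, character(1), i)
  geti <- function(i, what) {
    v <- suppressWarnings(as.integer(getc(i)))
    if (anyNA(v))
      stop("non-integer ", what, " in PAF line ", which(is.na(v))[1])
    v
  }
  rec <- data.frame(
    qid = getc(1), qlen = geti(2, "query length"),
    qstart = geti(3, "query start"), qend = geti(4, "query end"),
    strand = getc(5), tid = getc(6), tlen = geti(7, "target length"),
    tstart = geti(8, "target start"), tend = geti(9, "target end"),
    nmatch = geti(10, "match count"), blocklen = geti(11, "block length"),
    stringsAsFactors = FALSE)
  rec$identity <- if (identity) rec$nmatch / rec$blocklen else NA_real_
  OverlapSet(rec)
}

#' Write overlaps to a PAF file
#'
#' Columns 1-12 of the minimap2 PAF dialect; mapping quality is written
#' as 255 (missing).
#'
#' @param overlaps an \linkS4class{OverlapSet}.
#' @param path output file.
#' @return Invisibly, the number of records written.
#' @export
writePAF <- function(overlaps, path) {
  r <- overlapRecords(overlaps)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
                   r$qid, r$qlen, r$qstart, r$qend, r$strand,
                   r$tid, r$tlen, r$tstart, r$tend, r$nmatch, r$blocklen)
  writeLines(lines, path)
  invisible(nrow(r))
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
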