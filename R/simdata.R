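#' Generate a set of related haplotypes at a target ANI
#'
#' Emulates a polyploid genome (or a set of closely related strains) by
#' mutating a random ancestor sequence independently per haplotype.
#' Mutations are ~90% substitutions and ~10% small indels (1-3 bp), so a
#' diploid at ANI 0.98 carries roughly one heterozygous SNP per 55 bp.
#' The per-haplotype mutation rate is calibrated so the expected pairwise
#' divergence (1 - ANI, measured as alignment identity) matches
#' \code{1 - target_ani}: substitutions contribute two mismatch columns per
#' pair of haplotypes and indels (mean length 2) contribute gap columns,
#' giving divergence ~ 2.2 m for per-haplotype rate m. Realized ANI is
#' measured by global banded alignment and stored in the result.
#'
#' @param ancestor_len ancestor length in bp (>= 1000).
#' @param ploidy number of haplotypes (>= 1).
#' @param target_ani target pairwise average nucleotide identity in
#'   [0.9, 1); 1 is rejected (divergence is required).
#' @param seed RNG seed (same seed, identical haplotypes).
#' @return A \linkS4class{HaplotypeSet}.
#' @export
generateHaplotypes <- function(ancestor_len, ploidy = 2L, target_ani = 0.98,
                               seed = 1L) {
  stopifnot(ancestor_len >= 1000, ploidy >= 1)
  if (target_ani >= 1 || target_ani < 0.9)
    stop("target_ani must lie in [0.9, 1); haplotypes must diverge")
  m <- (1 - target_ani) / 2.2
  if (m * ancestor_len < 10)
    stop("ancestor too short to realise the requested ANI")
  set.seed(seed)
  acgt <- c("A", "C", "G", "T")
  ancestor <- sample(acgt, ancestor_len, replace = TRUE)
  haps <- vapply(seq_len(ploidy), function(h)
    .mutate_seq(ancestor, m, sub_frac = 0.9, max_indel = 3L), character(1))
  names(haps) <- paste0("hap", seq_len(ploidy))
  ani <- diag(nrow = ploidy)
  if (ploidy > 1)
    for (i in 1:(ploidy - 1)) for (j in (i + 1):ploidy) {
      al <- .cpp_edit_align(haps[i], haps[j], band0 = 128L, band_frac = 0.2)
      ani[i, j] <- ani[j, i] <- al$nmatch / al$ncols
    }
  dimnames(ani) <- list(names(haps), names(haps))
  new("HaplotypeSet", haplotypes = Biostrings::DNAStringSet(haps), ani = ani)
}

.mutate_seq <- function(bases, rate, sub_frac, max_indel) {
  acgt <- c("A", "C", "G", "T")
  n <- length(bases)
  hit <- which(runif(n) < rate)
  if (length(hit) > 0) {
    issub <- runif(length(hit)) < sub_frac
    sub <- hit[issub]
    bases[sub] <- acgt[(match(bases[sub], acgt) - 1L +
                          sample(3L, length(sub), replace = TRUE)) %% 4L + 1L]
    indel <- hit[!issub]
    if (length(indel) > 0) {
      isdel <- runif(length(indel)) < 0.5
      lens <- sample(max_indel, length(indel), replace = TRUE)
      for (t in seq_along(indel)) {
        i <- indel[t]
        if (isdel[t]) {
          bases[i:min(n, i + lens[t] - 1L)] <- ""
        } else {
          bases[i] <- paste(c(sample(acgt, lens[t], replace = TRUE),
                              bases[i]), collapse = "")
        }
      }
    }
  }
  paste(bases, collapse = "")
}

#' Measure pairwise ANI between two sequences
#'
#' Alignment identity (matches / alignment columns) of a banded global
#' alignment.
#'
#' @param a,b sequences (character).
#' @return Identity fraction in [0,1].
#' @export
pairwiseANI <- function(a, b) {
  al <- .cpp_edit_align(as.character(a), as.character(b),
                        band0 = 128L, band_frac = 0.2)
  al$nmatch / al$ncols
}

#' Simulate error-laden long reads from a haplotype set
#'
#' Per haplotype, the number of reads is Poisson with mean
#' \code{coverage_per_hap * L / read_len_mean}; read lengths are Normal
#' (truncated at [1000, L]), start positions uniform, strands random.
#' Per-base errors are i.i.d. with the configured mismatch:ins:del mix;
#' qualities are constant at \code{Q = round(-10 log10(error_rate))}.
#' Truth metadata (haplotype, interval on the haplotype, strand) is
#' attached to each read.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param cfg a \code{\link{simConfig}}.
#' @return A \linkS4class{ReadSet} with truth metadata and FASTQ qualities.
#' @export
simulateReads <- function(haps, cfg = simConfig()) {
  stopifnot(is(haps, "HaplotypeSet"), inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  hs <- as.character(haplotypeSeqs(haps))
  out_seq <- character(0); out_qual <- list()
  out_hap <- character(0); out_start <- integer(0); out_end <- integer(0)
  out_strand <- character(0)
  q <- if (cfg$error_rate > 0)
    as.integer(round(-10 * log10(cfg$error_rate))) else 60L
  for (h in names(hs)) {
    L <- nchar(hs[h])
    n <- rpois(1, cfg$coverage_per_hap * L / cfg$read_len_mean)
    if (n == 0) next
    lens <- pmin(pmax(round(rnorm(n, cfg$read_len_mean, cfg$read_len_sd)),
                      1000L), L)
    starts <- floor(runif(n, 0, L - lens + 1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      frag <- substr(hs[h], starts[i] + 1, starts[i] + lens[i])
      if (strands[i] == "-") frag <- .revcomp(frag)
      read <- .inject_errors(frag, cfg$error_rate, cfg$error_mix)
      out_seq <- c(out_seq, read)
      out_qual <- c(out_qual, list(rep(q, nchar(read))))
      out_hap <- c(out_hap, h)
      out_start <- c(out_start, as.integer(starts[i]))
      out_end <- c(out_end, as.integer(starts[i] + lens[i]))
      out_strand <- c(out_strand, strands[i])
    }
  }
  names(out_seq) <- sprintf("%s_read%05d", out_hap,
                            unlist(lapply(table(factor(out_hap,
                              levels = unique(out_hap))), seq_len)))
  truth <- S4Vectors::DataFrame(hap = out_hap, start = out_start,
                                end = out_end, strand = out_strand,
                                row.names = names(out_seq))
  ReadSet(out_seq, quals = out_qual, truth = truth)
}

.inject_errors <- function(seq, e, mix) {
  if (e <= 0) return(seq)
  acgt <- c("A", "C", "G", "T")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  err <- which(runif(n) < e)
  if (length(err) > 0) {
    ty <- sample(3L, length(err), replace = TRUE, prob = mix)
    sub <- err[ty == 1L]
    bases[sub] <- acgt[(match(bases[sub], acgt) - 1L +
                          sample(3L, length(sub), replace = TRUE)) %% 4L + 1L]
    ins <- err[ty == 2L]
    if (length(ins) > 0)
      bases[ins] <- paste0(acgt[sample(4L, length(ins), replace = TRUE)],
                           bases[ins])
    bases[err[ty == 3L]] <- ""
  }
  paste(bases, collapse = "")
}

#' SNP loci distinguishing two haplotypes
#'
#' Aligns two haplotypes globally and reports the substitution columns:
#' position and allele on each haplotype. Used by the haplotype-preservation
#' harness.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param i,j haplotype indices (defaults: the first two).
#' @return data.frame with columns pos_i, allele_i, pos_j, allele_j
#'   (0-based positions).
#' @export
haplotypeSNPs <- function(haps, i = 1L, j = 2L) {
  hs <- as.character(haplotypeSeqs(haps))
  a <- hs[[i]]; b <- hs[[j]]
  al <- .cpp_map_align(a, b, k = 15L, band0 = 128L, pairs = TRUE)
  if (!isTRUE(al$ok)) stop("haplotypes could not be aligned")
  mm <- !al$pair_match
  data.frame(pos_i = al$pair_ref[mm],
             allele_i = substring(a, al$pair_ref[mm] + 1, al$pair_ref[mm] + 1),
             pos_j = al$pair_query[mm],
             allele_j = substring(b, al$pair_query[mm] + 1,
                                  al$pair_query[mm] + 1),
             stringsAsFactors = FALSE)
}
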