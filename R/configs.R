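#' Alignment scoring parameters
#'
#' Scores for the semi-global sequence-to-graph alignment used during
#' variation-graph construction and realignment. Defaults follow the
#' POA-consensus lineage of long-read polishers: match +3, mismatch -5,
#' linear gap -4, with free leading/trailing graph nodes.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap linear gap score (< 0).
#' @return A named list of class \code{alignScoring}.
#' @export
alignScoring <- function(match = 3L, mismatch = -5L, gap = -4L) {
  stopifnot(match > 0, mismatch < 0, gap < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap)), class = c("alignScoring", "list"))
}

#' Overlap filter parameters
#'
#' Governs the overlap filters applied before pile construction: minimum
#' overlap length (500 bp; overlaps that do not exceed it are removed),
#' self-overlap removal, internal-match classification (both overhangs on
#' one read exceed \code{min(internal_match_overhang,
#' internal_match_ratio * mapped length)}), the mapping-length-ratio error
#' filter \code{|1 - min(Lq,Lt)/max(Lq,Lt)| >= max_len_ratio_err}, and the
#' optional minimum base-level identity applied in cycle 2.
#'
#' @param min_len minimum overlap length in bp (records with
#'   \code{min(Lq, Lt) <= min_len} are removed when \code{strict_min_len}).
#' @param max_len_ratio_err maximum mapping-length-ratio error \code{e}.
#' @param internal_match_overhang overhang cap in bp.
#' @param internal_match_ratio overhang cap as a fraction of mapped length.
#' @param min_identity optional minimum overlap identity (delta); used by
#'   the cycle-2 filter only.
#' @param strict_min_len remove overlaps of length exactly \code{min_len}
#'   (the default reading of "do not exceed").
#' @return A named list of class \code{overlapFilterConfig}.
#' @export
overlapFilterConfig <- function(min_len = 500L, max_len_ratio_err = 0.3,
                                internal_match_overhang = 1000L,
                                internal_match_ratio = 0.8,
                                min_identity = NULL,
                                strict_min_len = TRUE) {
  stopifnot(max_len_ratio_err > 0, max_len_ratio_err < 1)
  if (!is.null(min_identity))
    stopifnot(min_identity > 0.5, min_identity <= 1)
  structure(list(min_len = as.integer(min_len),
                 max_len_ratio_err = max_len_ratio_err,
                 internal_match_overhang = as.integer(internal_match_overhang),
                 internal_match_ratio = internal_match_ratio,
                 min_identity = min_identity,
                 strict_min_len = isTRUE(strict_min_len)),
            class = c("overlapFilterConfig", "list"))
}

#' Graph pruning parameters
#'
#' An edge is pruned when \code{Support(e) < s} or \code{Confidence(e) < c},
#' where \code{s = support_factor * C} and \code{C = sum_v w(v) / L} is the
#' average per-position read coverage of the window. Pruning and
#' read realignment alternate for at most \code{iterations} rounds
#' (stopping early once no edge is removed). Edges exactly at a threshold
#' are kept (strict \code{<}).
#'
#' @param confidence confidence threshold \code{c} in (0,1); default 0.2.
#' @param support_factor support scale factor in (0,1); default 0.2.
#' @param iterations maximum prune/realign rounds; default 3.
#' @return A named list of class \code{pruneConfig}.
#' @export
pruneConfig <- function(confidence = 0.2, support_factor = 0.2,
                        iterations = 3L) {
  stopifnot(confidence > 0, confidence < 1,
            support_factor > 0, support_factor < 1, iterations >= 1)
  structure(list(confidence = confidence, support_factor = support_factor,
                 iterations = as.integer(iterations)),
            class = c("pruneConfig", "list"))
}

#' Read simulation parameters
#'
#' Defaults emulate a PacBio-CLR-like design: 30x coverage per haplotype,
#' 10% per-base error dominated by indels (mismatch:ins:del = 25:35:40),
#' read lengths Normal(10 kb, 2.5 kb) truncated at [1 kb, haplotype length].
#' Errors are placed i.i.d. uniformly per base; FASTQ qualities are constant
#' at \code{Q = round(-10 log10(error_rate))}.
#'
#' @param coverage_per_hap expected coverage per haplotype.
#' @param error_rate per-base error rate in [0, 0.3].
#' @param error_mix length-3 numeric (mismatch, insertion, deletion
#'   fractions) summing to 1.
#' @param read_len_mean,read_len_sd read length distribution in bp.
#' @param seed RNG seed (determinism contract: same seed, same reads).
#' @return A named list of class \code{simConfig}.
#' @export
simConfig <- function(coverage_per_hap = 30, error_rate = 0.10,
                      error_mix = c(mismatch = 0.25, ins = 0.35, del = 0.40),
                      read_len_mean = 10000, read_len_sd = 2500,
                      seed = 1L) {
  stopifnot(coverage_per_hap > 0, error_rate >= 0, error_rate <= 0.3,
            length(error_mix) == 3, all(error_mix >= 0),
            abs(sum(error_mix) - 1) < 1e-9, read_len_mean >= 1000)
  structure(list(coverage_per_hap = coverage_per_hap, error_rate = error_rate,
                 error_mix = unname(error_mix),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 seed = as.integer(seed)),
            class = c("simConfig", "list"))
}

#' Pipeline run parameters
#'
#' Bundles all tunables of the two-cycle correction pipeline. The cycle-2
#' identity threshold delta defaults to the "simulated" preset (0.99,
#' recommended for 5-10% sequencing error); the "real" preset uses 0.98
#' (for 15% error).
#'
#' @param window_len window length in bp (default 500).
#' @param scoring an \code{\link{alignScoring}}.
#' @param overlap1 cycle-1 \code{\link{overlapFilterConfig}}.
#' @param prune a \code{\link{pruneConfig}}.
#' @param preset "simulated" (delta = 0.99) or "real" (delta = 0.98).
#' @param delta explicit cycle-2 minimum overlap identity, overriding the
#'   preset.
#' @param min_window_reads windows with fewer overlapping fragments pass the
#'   target subread through unchanged (default 4).
#' @param min_frag minimum bases a fragment must contribute to a window
#'   (default 50).
#' @param max_frags per-window fragment cap, highest identity kept
#'   (default 200, inactive at 30x coverage).
#' @param band initial band half-width of the sequence-to-graph alignment
#'   (doubles on failure).
#' @param k,w,min_chain minimizer overlapper parameters.
#' @param keep_uncorrected keep reads that no filter left correctable
#'   (passed through) instead of dropping them.
#' @param seed seed for any randomised stage (the pipeline itself is
#'   deterministic).
#' @return A named list of class \code{runConfig}.
#' @export
runConfig <- function(window_len = 500L, scoring = alignScoring(),
                      overlap1 = overlapFilterConfig(),
                      prune = pruneConfig(),
                      preset = c("simulated", "real"), delta = NULL,
                      min_window_reads = 4L, min_frag = 50L,
                      max_frags = 200L, band = 32L,
                      k = 15L, w = 5L, min_chain = 4L,
                      keep_uncorrected = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(delta)) delta <- if (preset == "simulated") 0.99 else 0.98
  stopifnot(window_len >= 100, min_window_reads >= 0, 2 <= k, k <= 28)
  structure(list(window_len = as.integer(window_len), scoring = scoring,
                 overlap1 = overlap1, prune = prune, preset = preset,
                 delta = delta,
                 min_window_reads = as.integer(min_window_reads),
                 min_frag = as.integer(min_frag),
                 max_frags = as.integer(max_frags), band = as.integer(band),
                 k = as.integer(k), w = as.integer(w),
                 min_chain = as.integer(min_chain),
                 keep_uncorrected = isTRUE(keep_uncorrected),
                 seed = as.integer(seed)),
            class = c("runConfig", "list"))
}
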