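test_that("the minimizer overlapper finds obvious overlaps and no spurious ones", {
  set.seed(31)
  a <- random_seq(2000)
  rs <- ReadSet(c(r1 = a, r2 = a))
  ov <- computeOverlaps(rs)
  expect_equal(length(ov), 1L)
  r <- overlapRecords(ov)
  expect_lt(r$qstart, 50)
  expect_gt(r$qend, 1950)
  expect_lt(r$tstart, 50)
  expect_gt(r$tend, 1950)

  # reverse-complement overlap is found on the minus strand
  rc <- ReadSet(c(r1 = a, r2 = HapCorrect:::.revcomp(a)))
  ovrc <- computeOverlaps(rc)
  expect_equal(length(ovrc), 1L)
  expect_equal(overlapRecords(ovrc)$strand, "-")

  # unrelated sequences yield nothing
  rs2 <- ReadSet(c(r1 = random_seq(2000), r2 = random_seq(2000)))
  expect_equal(length(computeOverlaps(rs2)), 0L)
})

test_that("overlap detection reaches 90% sensitivity against truth intervals", {
  haps <- generateHaplotypes(20000, 1, 0.98, seed = 13)
  reads <- simulateReads(haps, simConfig(coverage_per_hap = 3,
                                         error_rate = 0.10,
                                         read_len_mean = 4000,
                                         read_len_sd = 500, seed = 13))
  reads <- reads[seq_len(min(20, length(reads)))]
  ov <- overlapRecords(computeOverlaps(reads))
  found <- unique(paste(pmin(ov$qid, ov$tid), pmax(ov$qid, ov$tid)))
  tr <- readTruth(reads)
  ids <- readIDs(reads)
  truth_pairs <- character(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    inter <- min(tr$end[i], tr$end[j]) - max(tr$start[i], tr$start[j])
    if (inter >= 1000)
      truth_pairs <- c(truth_pairs, paste(min(ids[i], ids[j]),
                                          max(ids[i], ids[j])))
  }
  sens <- mean(truth_pairs %in% found)
  expect_gte(sens, 0.9)
})

.fake_reads <- function() {
  # two synthetic reads long enough for any record used below
  ReadSet(setNames(vapply(c(5000, 5000), random_seq, character(1)),
                   c("A", "B")))
}

.rec <- function(qid = "A", tid = "B", qs = 0, qe = 1000, ts = 0, te = 1000,
                 strand = "+", identity = NA_real_) {
  data.frame(qid = qid, qlen = 5000L, qstart = as.integer(qs),
             qend = as.integer(qe), strand = strand, tid = tid,
             tlen = 5000L, tstart = as.integer(ts), tend = as.integer(te),
             nmatch = as.integer(0.9 * (qe - qs)),
             blocklen = as.integer(qe - qs), identity = identity)
}

test_that("cycle-1 filters implement the published removal rules", {
  set.seed(41)
  reads <- .fake_reads()
  cfg <- overlapFilterConfig()

  # (d) mapping-length-ratio: |1 - 700/1000| = 0.3 >= e = 0.3 -> removed
  ov <- OverlapSet(.rec(qe = 1000, te = 700))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 0L)
  # equal mapped lengths -> ratio 0 -> kept
  ov <- OverlapSet(.rec(qe = 1000, te = 1000))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 1L)
  # (a) exactly 500 bp does not exceed 500 -> removed
  ov <- OverlapSet(.rec(qe = 500, te = 520))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 0L)
  # (b) self-overlap removed
  ov <- OverlapSet(.rec(tid = "A"))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 0L)
  # (c) internal match: both overhangs on the query exceed
  # min(1000, 0.8 * 1000) = 800
  ov <- OverlapSet(.rec(qs = 2000, qe = 3000, ts = 0, te = 1000))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 0L)
  # dovetail (one overhang small) kept
  ov <- OverlapSet(.rec(qs = 4000, qe = 5000, ts = 0, te = 1000))
  expect_equal(length(filterOverlapsCycle1(ov, reads, cfg)), 1L)

  expect_error(filterOverlapsCycle1(OverlapSet(.rec(qid = "Z")), reads),
               "unknown read")
})

test_that("filters are idempotent and cycle-2 output nests in cycle-1 output", {
  md <- mini_diploid()
  reads <- md$reads[1:25]
  ov <- computeOverlaps(reads)
  f1 <- filterOverlapsCycle1(ov, reads)
  f1b <- filterOverlapsCycle1(f1, reads)
  expect_equal(overlapRecords(f1b), overlapRecords(f1))

  withid <- computeOverlapIdentity(f1, reads)
  f2 <- filterOverlapsCycle2(withid, reads, delta = 0.8)
  k1 <- overlapRecords(filterOverlapsCycle1(withid, reads))
  k2 <- overlapRecords(f2)
  expect_true(all(paste(k2$qid, k2$tid, k2$qstart) %in%
                    paste(k1$qid, k1$tid, k1$qstart)))

  expect_error(filterOverlapsCycle2(f1, reads), "identity")
})

test_that("overlap identity equals the alignment-matrix definition", {
  set.seed(51)
  s <- random_seq(3000)
  reads <- ReadSet(c(A = s, B = s))
  ov <- OverlapSet(.rec(qe = 1000, te = 1000))
  # identical substrings
  wid <- computeOverlapIdentity(ov, ReadSet(c(A = substr(s, 1, 5000) ,
                                              B = s)))
  expect_equal(overlapRecords(wid)$identity, 1.0)
  # one mismatch in 100 columns
  t100 <- random_seq(100)
  q100 <- t100
  substr(q100, 50, 50) <- setdiff(ACGT, substr(q100, 50, 50))[1]
  reads2 <- ReadSet(c(A = q100, B = t100))
  ov2 <- OverlapSet(data.frame(qid = "A", qlen = 100L, qstart = 0L,
                               qend = 100L, strand = "+", tid = "B",
                               tlen = 100L, tstart = 0L, tend = 100L,
                               nmatch = 99L, blocklen = 100L,
                               identity = NA_real_))
  expect_equal(overlapRecords(computeOverlapIdentity(ov2, reads2))$identity,
               0.99)

  # identity == 1 - editdistance/columns against the quadratic oracle
  for (i in 1:50) {
    t0 <- random_seq(sample(80:150, 1))
    q0 <- mutate_seq_simple(t0, 0.1)
    reads3 <- ReadSet(c(A = q0, B = t0))
    ov3 <- OverlapSet(data.frame(qid = "A", qlen = nchar(q0), qstart = 0L,
                                 qend = nchar(q0), strand = "+", tid = "B",
                                 tlen = nchar(t0), tstart = 0L,
                                 tend = nchar(t0), nmatch = 0L,
                                 blocklen = 1L, identity = NA_real_))
    got <- overlapRecords(computeOverlapIdentity(ov3, reads3))
    o <- oracle_edit(t0, q0)
    expect_equal(got$identity, 1 - o$dist / got$blocklen)
  }
})

test_that("identity separates haplotypes once residual error is low", {
  # emulate pre-corrected diploid reads: 0.3% residual error, ANI 98%
  haps <- generateHaplotypes(12000, 2, 0.98, seed = 17)
  reads <- simulateReads(haps, simConfig(coverage_per_hap = 6,
                                         error_rate = 0.003,
                                         error_mix = c(0.5, 0.25, 0.25),
                                         read_len_mean = 3000,
                                         read_len_sd = 300, seed = 17))
  ov <- computeOverlaps(reads)
  f1 <- filterOverlapsCycle1(ov, reads)
  wid <- computeOverlapIdentity(f1, reads)
  r <- overlapRecords(wid)
  hap_of <- setNames(readTruth(reads)$hap, readIDs(reads))
  within <- hap_of[r$qid] == hap_of[r$tid]
  expect_gt(min(r$identity[within]), max(0.985, mean(r$identity[!within])))
  surv <- overlapRecords(filterOverlapsCycle2(wid, reads, delta = 0.99))
  expect_gte(mean(hap_of[surv$qid] == hap_of[surv$tid]), 0.95)
})

test_that("error-free same-haplotype overlaps have identity 1", {
  haps <- generateHaplotypes(8000, 1, 0.98, seed = 19)
  reads <- simulateReads(haps, simConfig(coverage_per_hap = 4,
                                         error_rate = 0,
                                         read_len_mean = 2500,
                                         read_len_sd = 200, seed = 19))
  ov <- filterOverlapsCycle1(computeOverlaps(reads), reads)
  wid <- computeOverlapIdentity(ov, reads)
  expect_true(all(overlapRecords(wid)$identity == 1))
})
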