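test_that("generated haplotypes realise the target ANI", {
  haps <- generateHaplotypes(50000, 2, 0.98, seed = 1)
  ani <- haplotypeANI(haps)[1, 2]
  expect_gte(ani, 0.977)
  expect_lte(ani, 0.983)
  haps2 <- generateHaplotypes(50000, 2, 0.98, seed = 1)
  expect_identical(as.character(haplotypeSeqs(haps)),
                   as.character(haplotypeSeqs(haps2)))
  expect_error(generateHaplotypes(50000, 2, 1), "diverge")
})

test_that("measured ANI agrees with an independent aligner", {
  haps <- generateHaplotypes(5000, 2, 0.97, seed = 5)
  hs <- haplotypeSeqs(haps)
  ours <- haplotypeANI(haps)[1, 2]
  pa <- Biostrings::pairwiseAlignment(hs[[1]], hs[[2]], type = "global")
  theirs <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  expect_lt(abs(ours - theirs), 0.003)
})

test_that("read simulation matches the sampling design", {
  haps <- generateHaplotypes(50000, 2, 0.98, seed = 2)
  cfg <- simConfig(coverage_per_hap = 30, read_len_mean = 10000, seed = 2)
  reads <- simulateReads(haps, cfg)
  # expected reads: 2 haplotypes x 50 kb x 30x / 10 kb = 300, Poisson spread
  expect_gt(length(reads), 300 - 3 * sqrt(300))
  expect_lt(length(reads), 300 + 3 * sqrt(300))
  expect_true(all(table(readTruth(reads)$hap) > 0))
  reads2 <- simulateReads(haps, cfg)
  expect_identical(as.character(readSeqs(reads)),
                   as.character(readSeqs(reads2)))
  # FASTQ qualities encode the injected error rate
  expect_equal(unique(unlist(readQuals(reads[1:3]))), 10L)
})

test_that("error-free reads are exact haplotype substrings", {
  haps <- generateHaplotypes(5000, 1, 0.98, seed = 3)
  reads <- simulateReads(haps, simConfig(coverage_per_hap = 3,
                                         error_rate = 0,
                                         read_len_mean = 1500,
                                         read_len_sd = 200, seed = 3))
  hs <- as.character(haplotypeSeqs(haps))[[1]]
  for (i in seq_len(length(reads))) {
    s <- as.character(readSeqs(reads)[[i]])
    found <- grepl(s, hs, fixed = TRUE) ||
      grepl(HapCorrect:::.revcomp(s), hs, fixed = TRUE)
    expect_true(found)
  }
})

test_that("the evaluator recovers exact error counts on a toy set", {
  set.seed(21)
  haps <- generateHaplotypes(2000, 2, 0.97, seed = 21)
  hs <- as.character(haplotypeSeqs(haps))
  # truth substrings align perfectly
  subs <- setNames(c(substr(hs[1], 101, 600), substr(hs[2], 901, 1400)),
                   c("a", "b"))
  ev <- evaluateCorrected(ReadSet(subs), haps)
  expect_equal(errorRate(ev), 0)
  expect_equal(perRead(ev)$hap, c("hap1", "hap2"))

  # a single mismatch over 1000 aligned columns
  one <- substr(hs[1], 1, 1000)
  substr(one, 500, 500) <- setdiff(ACGT, substr(one, 500, 500))[1]
  ev1 <- evaluateCorrected(ReadSet(c(x = one)), haps)
  expect_equal(errorRate(ev1), 0.001)
  expect_equal(mismatchRate(ev1), 0.001)
  expect_equal(indelRate(ev1), 0)

  # 10-read toy: aggregate edit operations match a brute-force recount
  reads <- simulateReads(haps, simConfig(coverage_per_hap = 2.5,
                                         error_rate = 0.05,
                                         read_len_mean = 1000,
                                         read_len_sd = 100, seed = 4))
  reads <- reads[seq_len(min(10, length(reads)))]
  ev <- evaluateCorrected(reads, haps)
  per <- perRead(ev)
  for (i in seq_len(nrow(per))) {
    s <- as.character(readSeqs(reads)[[i]])
    if (per$strand[i] == "-") s <- HapCorrect:::.revcomp(s)
    ref <- substr(hs[per$hap[i]], per$ref_start[i] + 1, per$ref_end[i])
    o <- oracle_edit(ref, s)
    expect_equal(per$mismatches[i] + per$insertions[i] + per$deletions[i],
                 o$dist)
  }
})

test_that("evaluating raw simulated reads recovers the injected error rate", {
  md <- mini_diploid()
  ev <- evaluateCorrected(md$reads, md$haps)
  # optimal alignment compresses adjacent/cancelling errors, so the
  # re-estimated rate sits a few percent (relative) below the injected one
  expect_gt(errorRate(ev), 0.10 * 0.8)
  expect_lt(errorRate(ev), 0.10 * 1.05)
  expect_equal(errorRate(ev), mismatchRate(ev) + indelRate(ev),
               tolerance = 1e-10)
  expect_gt(haplotypeCoverage(ev), 0.9)
})

test_that("SNP harness identifies loci and scores concordance", {
  haps <- generateHaplotypes(5000, 2, 0.98, seed = 9)
  snps <- haplotypeSNPs(haps)
  expect_gt(nrow(snps), 20)
  hs <- as.character(haplotypeSeqs(haps))
  expect_true(all(substring(hs[1], snps$pos_i + 1, snps$pos_i + 1) ==
                    snps$allele_i))
  expect_true(all(snps$allele_i != snps$allele_j))
  # perfect truth substrings are fully concordant
  subs <- c(substr(hs[1], 1, 2500), substr(hs[2], 2001, 4800))
  rs <- ReadSet(setNames(subs, c("p1", "p2")),
                truth = S4Vectors::DataFrame(hap = c("hap1", "hap2"),
                                             start = c(0L, 2000L),
                                             end = c(2500L, 4800L),
                                             strand = c("+", "+")))
  sc <- snpConcordance(rs, haps, snps)
  expect_equal(sc$fraction, 1)
  # a read carrying the other haplotype's allele at one SNP is discordant
  bad <- substr(hs[1], 1, 2500)
  k <- which(snps$pos_i < 2400)[1]
  substr(bad, snps$pos_i[k] + 1, snps$pos_i[k] + 1) <- snps$allele_j[k]
  rs2 <- ReadSet(c(p1 = bad),
                 truth = S4Vectors::DataFrame(hap = "hap1", start = 0L,
                                              end = 2500L, strand = "+"))
  expect_equal(snpConcordance(rs2, haps, snps)$fraction, 0)
})
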