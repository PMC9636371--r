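test_that("node weights follow the FASTA / FASTQ definitions", {
  # FASTA: three reads cover each node -> weight 3
  g <- poaBuild(setNames(rep("ACG", 3), paste0("r", 1:3)))
  expect_equal(nodeWeights(g)$weight, rep(3, 3))
  expect_equal(nodeWeights(g)$coverage, rep(3L, 3))

  # FASTQ: two reads at Q10 (p = 0.1) -> weight 2 * 0.9 = 1.8
  gq <- poaBuild(setNames(rep("ACG", 2), c("r1", "r2")),
                 quals = list(rep(10L, 3), rep(10L, 3)))
  expect_equal(nodeWeights(gq)$weight, rep(1.8, 3))
  # FASTQ weights never exceed coverage
  expect_true(all(nodeWeights(gq)$weight <= nodeWeights(gq)$coverage))
})

test_that("edge weights follow the half-probability approximation", {
  # FASTA: four traversing reads -> weight 4 on every chain edge
  g <- poaBuild(setNames(rep("ACGT", 4), paste0("r", 1:4)))
  ew <- edgeWeights(g)
  expect_equal(ew$weight, rep(4, 3))
  expect_equal(ew$support, ew$weight)

  # one FASTQ read with p_i = 0.1, p_j = 0.01 on an edge:
  # w = 1 - 0.05 - 0.005 = 0.945
  gq <- poaBuild(c(r1 = "AC"), quals = list(c(10L, 20L)))
  expect_equal(edgeWeights(gq)$weight, 0.945)

  # the per-read weight 1 - p_i/2 - p_j/2 is the arithmetic-mean
  # approximation of the exact product (1-p_i)(1-p_j); its gap per read is
  # exactly (p_i + p_j)/2 - p_i p_j (checked against the exact-product
  # oracle on random quality profiles)
  set.seed(91)
  for (rep in 1:10) {
    s <- random_seq(30)
    seqs <- setNames(rep(s, 4), paste0("r", 1:4))
    quals <- lapply(1:4, function(i) sample(3:20, 30, replace = TRUE))
    gq2 <- poaBuild(seqs, quals = quals)
    ew2 <- edgeWeights(gq2)
    probs <- lapply(quals, phredToErrorProb)
    for (e in seq_len(nrow(ew2))) {
      i <- ew2$from[e]; j <- ew2$to[e]
      exact <- sum(vapply(1:4, function(r)
        (1 - probs[[r]][i]) * (1 - probs[[r]][j]), numeric(1)))
      gap <- sum(vapply(1:4, function(r)
        (probs[[r]][i] + probs[[r]][j]) / 2 -
          probs[[r]][i] * probs[[r]][j], numeric(1)))
      expect_equal(ew2$weight[e] - exact, gap, tolerance = 1e-9)
    }
  }
})

test_that("confidence arithmetic matches hand calculation on a toy graph", {
  # A with successors C (8 reads) and G (2 reads); C,G rejoin at T
  g <- toy_graph(c("A", "C", "G", "T"),
                 rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
                 c(rep(list(c(1, 2, 4)), 8), rep(list(c(1, 3, 4)), 2)))
  ew <- edgeWeights(g)
  key <- paste(ew$from, ew$to)
  expect_equal(ew$weight[key == "1 2"], 8)
  expect_equal(ew$weight[key == "1 3"], 2)
  expect_equal(ew$conf_fwd[key == "1 3"], 0.2)
  expect_equal(ew$conf_bwd[key == "1 3"], 1)    # G's only in-edge
  expect_equal(ew$confidence[key == "1 3"], 1)  # max of the two directions
  expect_equal(ew$conf_fwd[key == "1 2"], 0.8)
  expect_equal(ew$conf_bwd[key == "2 4"], 0.8)
  expect_equal(ew$conf_fwd[key == "2 4"], 1)
  # forward confidences normalise per source node
  for (v in unique(ew$from))
    expect_equal(sum(ew$conf_fwd[ew$from == v]), 1)
  # symmetric bubble: both branch edges split the forward confidence evenly
  gsym <- toy_graph(c("A", "C", "G", "T"),
                    rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)),
                    c(rep(list(c(1, 2, 4)), 5), rep(list(c(1, 3, 4)), 5)))
  ews <- edgeWeights(gsym)
  keys <- paste(ews$from, ews$to)
  expect_equal(ews$conf_fwd[keys == "1 2"], 0.5)
  expect_equal(ews$conf_fwd[keys == "1 3"], 0.5)
})

test_that("statistics equal a direct recount of the stored paths", {
  set.seed(93)
  for (rep in 1:5) {
    s <- random_seq(60)
    seqs <- c(s, replicate(8, mutate_seq_simple(s, 0.1)))
    names(seqs) <- paste0("r", 1:9)
    quals <- if (rep %% 2) NULL else
      lapply(seqs, function(x) sample(5:20, nchar(x), replace = TRUE))
    g <- poaBuild(seqs, quals = quals)
    o <- oracle_stats(g)
    expect_equal(nodeWeights(g)$weight, o$node_weight, tolerance = 1e-9)
    expect_equal(nodeWeights(g)$coverage, o$node_coverage)
    ew <- edgeWeights(g)
    expect_equal(ew$weight, o$edge_weight, tolerance = 1e-9)
    expect_equal(ew$coverage, o$edge_coverage)
    if (is.null(quals)) {
      # FASTA weights are integral traversal counts
      expect_equal(ew$weight, as.numeric(ew$coverage))
      expect_equal(nodeWeights(g)$weight,
                   as.numeric(nodeWeights(g)$coverage))
    }
  }
})

.window_fixture <- function(n_reads = 30, err_read = 0, n_b = 0,
                            len = 200, seed = 95) {
  # n_reads reads over one haplotype; optionally err_read reads carry one
  # private substitution at position 100; n_b reads carry haplotype B's
  # allele at position 100
  set.seed(seed)
  s <- random_seq(len)
  alt <- s
  substr(alt, 100, 100) <- setdiff(ACGT, substr(s, 100, 100))[1]
  err <- s
  substr(err, 100, 100) <- setdiff(ACGT, c(substr(s, 100, 100),
                                           substr(alt, 100, 100)))[1]
  seqs <- c(rep(s, n_reads - err_read - n_b), rep(alt, n_b),
            rep(err, err_read))
  names(seqs) <- paste0("r", seq_along(seqs))
  list(clean = s, alt = alt, err = err, seqs = seqs)
}

test_that("a private error bubble is pruned, a balanced variant is kept", {
  # 30 reads, 1 carries a private substitution: support 1 < s = 0.2 * ~30
  fx <- .window_fixture(n_reads = 30, err_read = 1)
  g <- poaBuild(fx$seqs)
  expect_equal(nodeCount(g), 201L)
  pr <- pruneOnce(g, pruneConfig(), window_len = 200)
  expect_gte(nrow(pr$removed_edges), 2)
  expect_equal(length(pr$removed_nodes), 1L)   # the error node
  expect_equal(nodeCount(pr$graph), 200L)
  expect_gt(pr$support_threshold, 1)

  # two alleles at 15/15 in a 30-read window: support 15 >= 6,
  # confidence >= 0.5 >= 0.2 -> both kept
  fx2 <- .window_fixture(n_reads = 30, n_b = 15)
  g2 <- poaBuild(fx2$seqs)
  expect_equal(nodeCount(g2), 201L)
  pr2 <- pruneOnce(g2, pruneConfig(), window_len = 200)
  expect_equal(nrow(pr2$removed_edges), 0L)
  expect_equal(nodeCount(pr2$graph), 201L)

  # error-free single-haplotype window: nothing to remove
  fx3 <- .window_fixture(n_reads = 20)
  pr3 <- pruneOnce(poaBuild(fx3$seqs), pruneConfig(), window_len = 200)
  expect_equal(nrow(pr3$removed_edges), 0L)
})

test_that("pruning decisions are invariant to duplicating all reads", {
  fx <- .window_fixture(n_reads = 15, err_read = 1, seed = 97)
  g1 <- poaBuild(fx$seqs)
  doubled <- c(fx$seqs, fx$seqs)
  names(doubled) <- paste0("r", seq_along(doubled))
  g2 <- poaBuild(doubled)
  pr1 <- pruneOnce(g1, window_len = 200)
  pr2 <- pruneOnce(g2, window_len = 200)
  expect_equal(pr2$mean_coverage, 2 * pr1$mean_coverage)
  expect_equal(pr2$removed_edges, pr1$removed_edges)
  expect_equal(nodeCount(pr1$graph), nodeCount(pr2$graph))
})

test_that("the prune/realign cycle converges and respects the iteration cap", {
  fx <- .window_fixture(n_reads = 20)
  g <- poaBuild(fx$seqs)
  res <- pruneIterative(g, fx$seqs, cfg = pruneConfig(iterations = 3))
  # error-free window: first round removes nothing, loop stops
  expect_equal(sum(res$removed_per_iter), 0L)
  expect_false(res$empty)
  expect_lte(length(res$removed_per_iter), 3L)

  set.seed(99)
  noisy <- vapply(seq_len(20), function(i) mutate_seq_simple(fx$clean, 0.1),
                  character(1))
  names(noisy) <- paste0("n", 1:20)
  gn <- poaBuild(c(fx$seqs[1], noisy))
  resn <- pruneIterative(gn, c(fx$seqs[1], noisy),
                         cfg = pruneConfig(iterations = 3))
  expect_lte(length(resn$removed_per_iter), 3L)
  expect_gt(resn$removed_per_iter[1], 0)
  expect_true(validObject(resn$graph))      # still a DAG
  # realigned paths only use surviving edges
  ed <- paste(graphEdges(resn$graph)$from, graphEdges(resn$graph)$to)
  expect_gt(nodeCount(resn$graph), 0)
})

test_that("subread correction fixes errors and preserves haplotype alleles", {
  fx <- .window_fixture(n_reads = 30, seed = 101)
  g <- poaBuild(fx$seqs)
  res <- pruneIterative(g, fx$seqs)
  # clean target on a retained path: unchanged
  out <- correctSubread(res$graph, fx$clean)
  expect_equal(out$seq, fx$clean)
  expect_false(out$flagged)
  # one substitution against a 30-read clean window: corrected
  out2 <- correctSubread(res$graph, fx$err)
  expect_equal(out2$seq, fx$clean)

  # balanced diploid window: the corrected subread keeps its own allele
  fx2 <- .window_fixture(n_reads = 30, n_b = 15, seed = 103)
  seqs <- c(tgt = fx2$alt, fx2$seqs)   # target comes from "haplotype B"
  g2 <- poaBuild(seqs)
  res2 <- pruneIterative(g2, seqs)
  out3 <- correctSubread(res2$graph, fx2$alt)
  expect_equal(substr(out3$seq, 100, 100), substr(fx2$alt, 100, 100))
  out4 <- correctSubread(res2$graph, fx2$clean)
  expect_equal(substr(out4$seq, 100, 100), substr(fx2$clean, 100, 100))

  # empty graph: raw subread passes through, flagged
  gempty <- new("VariationGraph", bases = character(0), ranks = integer(0),
                edgeFrom = integer(0), edgeTo = integer(0),
                pathIDs = character(0), paths = list(),
                pathConsumed = list(), pathProbs = list())
  out5 <- correctSubread(gempty, "ACGT")
  expect_equal(out5$seq, "ACGT")
  expect_true(out5$flagged)
})

test_that("noisy diploid windows come out nearly clean", {
  # 15 reads per haplotype at 10% error; targets from haplotype A must be
  # corrected toward A, not toward a consensus of both
  set.seed(105)
  a <- random_seq(500)
  b <- a
  pos <- sort(sample(20:480, 10))
  for (p in pos) substr(b, p, p) <- setdiff(ACGT, substr(b, p, p))[1]
  noisy <- c(vapply(1:15, function(i) mutate_seq_simple(a, 0.1), character(1)),
             vapply(1:15, function(i) mutate_seq_simple(b, 0.1), character(1)))
  names(noisy) <- paste0("r", 1:30)
  target <- mutate_seq_simple(a, 0.1)
  seqs <- c(tgt = target, noisy)
  g <- poaBuild(seqs)
  res <- pruneIterative(g, seqs)
  out <- correctSubread(res$graph, target)
  al <- oracle_edit(a, out$seq)
  expect_lt(al$dist / nchar(a), 0.02)
})
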