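test_that("POA construction on hand-checkable inputs", {
  # one sequence: a chain
  g <- poaBuild(c(s1 = "ACGT"))
  expect_equal(nodeCount(g), 4L)
  expect_equal(edgeCount(g), 3L)
  expect_equal(graphNodes(g)$base, c("A", "C", "G", "T"))
  expect_equal(graphPaths(g)$s1, 1:4)

  # two identical sequences share the chain; edge weight 2
  g2 <- poaBuild(c(s1 = "ACGT", s2 = "ACGT"))
  expect_equal(nodeCount(g2), 4L)
  expect_equal(unique(edgeWeights(g2)$weight), 2)
  expect_equal(graphPaths(g2)$s1, graphPaths(g2)$s2)

  # a substitution opens a width-1 bubble
  g3 <- poaBuild(c(s1 = "ACGT", s2 = "AGGT"))
  expect_equal(nodeCount(g3), 5L)
  expect_equal(graphNodes(g3)$base[5], "G")
  ed <- graphEdges(g3)
  expect_true(all(c("1 2", "2 3", "3 4", "1 5", "5 3") %in%
                    paste(ed$from, ed$to)))
  expect_equal(nrow(ed), 5L)
  # bubble siblings share rank (window anchor) with the mismatched node
  expect_equal(graphNodes(g3)$rank[5], graphNodes(g3)$rank[2])

  # a third read with the same variant reuses the bubble node
  g4 <- poaBuild(c(s1 = "ACGT", s2 = "AGGT", s3 = "AGGT"))
  expect_equal(nodeCount(g4), 5L)
})

test_that("fusing an already-spelled sequence adds no nodes", {
  set.seed(71)
  s <- random_seq(60)
  m <- mutate_seq_simple(s, 0.1)
  g <- poaBuild(setNames(c(s, m), c("a", "b")))
  n0 <- nodeCount(g)
  g2 <- poaBuild(setNames(c(s, m, m), c("a", "b", "c")))
  expect_equal(nodeCount(g2), n0)
  expect_equal(graphPaths(g2)$b, graphPaths(g2)$c)
})

test_that("POA graphs remain DAGs with valid paths", {
  set.seed(73)
  for (rep in 1:10) {
    s <- random_seq(80)
    seqs <- c(s, replicate(6, mutate_seq_simple(s, 0.12)))
    names(seqs) <- paste0("r", 1:7)
    g <- poaBuild(seqs)
    expect_true(validObject(g))   # includes the cycle check
    ed <- paste(graphEdges(g)$from, graphEdges(g)$to)
    for (p in graphPaths(g))
      if (length(p) > 1)
        expect_true(all(paste(p[-length(p)], p[-1]) %in% ed))
  }
})

test_that("sequence-to-graph alignment matches its contracts", {
  g <- poaBuild(c(s1 = "ACGTACGT", s2 = "ACGAACGT"))
  sc <- alignScoring()
  # a sequence spelled by an existing path returns that path at full score
  al <- alignToGraph(g, "ACGAACGT", sc)
  expect_equal(al$score, 8 * sc$match)
  expect_equal(al$path, graphPaths(g)$s2)
  expect_true(all(al$ops == "M"))
  # empty sequence: empty path, score 0
  al0 <- alignToGraph(g, "", sc)
  expect_equal(length(al0$walk), 0L)
  expect_equal(al0$score, 0)
})

test_that("graph alignment scores equal exhaustive path enumeration", {
  set.seed(77)
  sc <- alignScoring()
  for (rep in 1:25) {
    s <- random_seq(6)
    g <- poaBuild(setNames(c(s, mutate_seq_simple(s, 0.3)), c("a", "b")))
    if (nodeCount(g) > 8) next
    q <- random_seq(sample(3:7, 1))
    al <- alignToGraph(g, q, sc)
    expect_equal(al$score, oracle_graph_align_score(g, q, sc))
  }
})

test_that("single-sequence graphs reduce to pairwise alignment", {
  set.seed(79)
  sc <- alignScoring()
  for (rep in 1:10) {
    s <- random_seq(40)
    g <- poaBuild(c(a = s))
    q <- mutate_seq_simple(substr(s, 6, 35), 0.15)
    al <- alignToGraph(g, q, sc)
    expect_equal(al$score, oracle_semiglobal_score(s, q, sc))
  }
})

test_that("walk spelling handles chains, empties and contract errors", {
  g <- poaBuild(c(s = "ACG"))
  expect_equal(extractPathSequence(g, 1:3), "ACG")
  expect_equal(extractPathSequence(g, integer(0)), "")
  expect_error(extractPathSequence(g, c(3L, 1L)), "missing edge")
})

test_that("aligning an erroneous subread to a clean graph corrects it", {
  set.seed(81)
  s <- random_seq(120)
  g <- poaBuild(setNames(rep(s, 5), paste0("r", 1:5)))
  noisy <- mutate_seq_simple(s, 0.05)
  al <- alignToGraph(g, noisy)
  expect_equal(extractPathSequence(g, al$walk), s)
})

test_that("heaviest bundle equals exhaustive maximum-weight path", {
  # all reads identical -> consensus is that read
  g <- poaBuild(setNames(rep("ACGTAC", 4), paste0("r", 1:4)))
  hb <- heaviestBundle(g)
  expect_equal(hb$sequence, "ACGTAC")
  # linear chain regardless of weights
  g1 <- poaBuild(c(a = "TTAGC"))
  expect_equal(heaviestBundle(g1)$sequence, "TTAGC")
  # random small DAGs vs enumeration
  set.seed(83)
  for (rep in 1:25) {
    s <- random_seq(7)
    seqs <- c(s, replicate(3, mutate_seq_simple(s, 0.25)))
    names(seqs) <- paste0("r", 1:4)
    g <- poaBuild(seqs)
    if (nodeCount(g) > 10) next
    hb <- heaviestBundle(g)
    expect_equal(hb$weight, oracle_heaviest_weight(g), tolerance = 1e-9)
  }
  # bundle weight dominates every recorded read path's weight
  g5 <- poaBuild(setNames(c("ACGTACGT", "ACTTACGT", "ACGTACGT"),
                          paste0("r", 1:3)))
  ew <- edgeWeights(g5)
  key <- paste(ew$from, ew$to)
  for (p in graphPaths(g5)) {
    wp <- sum(ew$weight[match(paste(p[-length(p)], p[-1]), key)])
    expect_gte(heaviestBundle(g5)$weight, wp)
  }
})
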