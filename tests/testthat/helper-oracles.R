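# Independent oracles used to check the C++ engine. These are deliberately
# naive (quadratic DP, exhaustive enumeration) and operate only on tiny
# inputs.

ACGT <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

mutate_seq_simple <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  b[hit] <- sample(ACGT, length(hit), replace = TRUE)
  paste(b, collapse = "")
}

# full quadratic global edit distance with traceback; move priority matches
# the banded implementation (diag, then up/insertion, then left/deletion)
oracle_edit <- function(t, q) {
  tv <- strsplit(t, "")[[1]]; qv <- strsplit(q, "")[[1]]
  n <- length(tv); m <- length(qv)
  D <- matrix(0L, m + 1, n + 1)
  D[1, ] <- 0:n; D[, 1] <- 0:m
  for (j in 1:m) for (i in 1:n)
    D[j + 1, i + 1] <- min(D[j, i] + (tv[i] != qv[j]),
                           D[j, i + 1] + 1L, D[j + 1, i] + 1L)
  # traceback for the column map
  colmap <- rep(-1L, m)
  i <- n; j <- m
  while (j > 0) {
    diag <- if (i > 0) D[j, i] + (tv[i] != qv[j]) else Inf
    up <- D[j, i + 1] + 1L
    left <- if (i > 0) D[j + 1, i] + 1L else Inf
    v <- D[j + 1, i + 1]
    if (v == diag) { colmap[j] <- i - 1L; i <- i - 1; j <- j - 1 }
    else if (v == up) { j <- j - 1 }
    else { i <- i - 1 }
  }
  list(dist = D[m + 1, n + 1], colmap = colmap)
}

# semi-global pairwise DP: query consumed end-to-end, free ends on target
oracle_semiglobal_score <- function(t, q, sc) {
  tv <- strsplit(t, "")[[1]]; qv <- strsplit(q, "")[[1]]
  n <- length(tv); m <- length(qv)
  if (m == 0) return(0)
  D <- matrix(-Inf, m + 1, n + 1)
  D[1, ] <- 0
  for (j in 1:m) {
    D[j + 1, 1] <- j * sc$gap
    for (i in 1:n) {
      sub <- if (tv[i] == qv[j]) sc$match else sc$mismatch
      D[j + 1, i + 1] <- max(D[j, i] + sub, D[j, i + 1] + sc$gap,
                             D[j + 1, i] + sc$gap)
    }
  }
  max(D[m + 1, ])
}

# all source-to-sink paths of a VariationGraph (tiny graphs only)
oracle_all_paths <- function(g) {
  n <- nodeCount(g)
  ed <- graphEdges(g)
  succ <- split(ed$to, factor(ed$from, levels = seq_len(n)))
  sources <- setdiff(seq_len(n), ed$to)
  sinks <- setdiff(seq_len(n), ed$from)
  paths <- list()
  extend <- function(p) {
    v <- p[length(p)]
    if (v %in% sinks) { paths[[length(paths) + 1]] <<- p; return() }
    for (w in succ[[v]]) extend(c(p, w))
  }
  for (s in sources) extend(s)
  paths
}

# exhaustive semi-global sequence-to-graph score: best pairwise score
# against any source-sink walk's spelled sequence
oracle_graph_align_score <- function(g, seq, sc) {
  paths <- oracle_all_paths(g)
  max(vapply(paths, function(p)
    oracle_semiglobal_score(extractPathSequence(g, p), seq, sc), numeric(1)))
}

# exhaustive heaviest-bundle weight
oracle_heaviest_weight <- function(g) {
  ew <- edgeWeights(g)
  key <- paste(ew$from, ew$to)
  paths <- oracle_all_paths(g)
  max(vapply(paths, function(p) {
    if (length(p) < 2) return(0)
    sum(ew$weight[match(paste(p[-length(p)], p[-1]), key)])
  }, numeric(1)))
}

# direct recount of node / edge traversal statistics from the stored paths
oracle_stats <- function(g) {
  n <- nodeCount(g)
  ed <- graphEdges(g)
  ekey <- paste(ed$from, ed$to)
  nw <- numeric(n); ncov <- integer(n)
  ew <- numeric(nrow(ed)); ecov <- integer(nrow(ed))
  probs <- g@pathProbs
  for (pi in seq_along(g@paths)) {
    wk <- g@paths[[pi]]
    cons <- g@pathConsumed[[pi]]
    p <- if (length(probs)) probs[[pi]] else rep(0, length(wk))
    plast <- 0
    pstep <- numeric(length(wk))
    for (s in seq_along(wk)) {
      if (cons[s]) {
        nw[wk[s]] <- nw[wk[s]] + 1 - p[s]
        ncov[wk[s]] <- ncov[wk[s]] + 1L
        plast <- p[s]
        pstep[s] <- p[s]
      } else pstep[s] <- plast
      if (s > 1) {
        e <- match(paste(wk[s - 1], wk[s]), ekey)
        if (!is.na(e)) {
          ew[e] <- ew[e] + 1 - pstep[s - 1] / 2 - pstep[s] / 2
          ecov[e] <- ecov[e] + 1L
        }
      }
    }
  }
  list(node_weight = nw, node_coverage = ncov,
       edge_weight = ew, edge_coverage = ecov)
}

# hand-constructable variation graph for weight/confidence arithmetic
toy_graph <- function(bases, edges, paths, probs = NULL) {
  new("VariationGraph", bases = bases,
      ranks = seq_along(bases) - 1L,
      edgeFrom = as.integer(edges[, 1]), edgeTo = as.integer(edges[, 2]),
      pathIDs = paste0("r", seq_along(paths)),
      paths = lapply(paths, as.integer),
      pathConsumed = lapply(paths, function(p) rep(TRUE, length(p))),
      pathProbs = if (is.null(probs)) list() else probs)
}

# small diploid simulation reused across tests
mini_diploid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      haps <- generateHaplotypes(8000, 2, 0.98, seed = 7)
      reads <- simulateReads(haps, simConfig(coverage_per_hap = 20,
                                             read_len_mean = 3000,
                                             read_len_sd = 500, seed = 7))
      cache <<- list(haps = haps, reads = reads)
    }
    cache
  }
})
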