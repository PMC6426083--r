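# Shared fixture builders and independent oracles.

# Build a DTUExperiment from explicit per-condition count matrices.
makeExperiment <- function(cntA, cntB, geneMap, bootstraps = NULL) {
  txIds <- rownames(cntA)
  repsA <- lapply(seq_len(ncol(cntA)), function(i)
    ReplicateQuant(paste0("A", i), setNames(cntA[, i], txIds),
                   bootstrap = bootstraps[[paste0("A", i)]]))
  repsB <- lapply(seq_len(ncol(cntB)), function(i)
    ReplicateQuant(paste0("B", i), setNames(cntB[, i], txIds),
                   bootstrap = bootstraps[[paste0("B", i)]]))
  ann <- data.frame(transcript_id = txIds, gene_id = geneMap[txIds])
  buildExperiment(repsA, repsB, ann)
}

# Two genes: g1 with a clean isoform swap between conditions, g2 stable.
swapFixture <- function(nReps = 3, scale = 1) {
  tx <- c("g1.t1", "g1.t2", "g2.t1", "g2.t2")
  a <- matrix(rep(c(800, 200, 500, 500) * scale, nReps), ncol = nReps,
              dimnames = list(tx, NULL))
  b <- matrix(rep(c(200, 800, 500, 500) * scale, nReps), ncol = nReps,
              dimnames = list(tx, NULL))
  gm <- setNames(c("g1", "g1", "g2", "g2"), tx)
  makeExperiment(a, b, gm)
}

# Independent G-test oracle: iterative-proportional-fitting likelihood-ratio
# statistic from stats::loglin, a code path disjoint from gTest().
gOracle <- function(m) {
  f <- stats::loglin(m, margin = list(1, 2), print = FALSE)
  list(g_statistic = f$lrt, df = f$df,
       p_value = stats::pchisq(f$lrt, f$df, lower.tail = FALSE))
}

# Independent step-up BH implementation.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * n / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  adj[order(o)]
}

# Random k x 2 integer contingency table with no all-zero row.
randomTable <- function(k, maxCell = 50) {
  repeat {
    m <- matrix(sample(0:maxCell, k * 2, replace = TRUE), nrow = k)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
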