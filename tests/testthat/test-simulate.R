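test_that("a null configuration injects nothing and is seed-reproducible", {
  sim <- simulateExperiment(nGenes = 50, nDtuGenes = 0, nBootstrap = 5,
                            seed = 5)
  expect_equal(nrow(sim$truth), 0L)
  sim2 <- simulateExperiment(nGenes = 50, nDtuGenes = 0, nBootstrap = 5,
                             seed = 5)
  expect_identical(SummarizedExperiment::assay(sim$experiment, "counts"),
                   SummarizedExperiment::assay(sim2$experiment, "counts"))
  expect_identical(bootstraps(sim$experiment)[["A1"]],
                   bootstraps(sim2$experiment)[["A1"]])
})

test_that("the swap rule exchanges the two most abundant isoform means", {
  # near-zero dispersion: counts sit at the means, so the swap is visible
  sim <- simulateExperiment(nGenes = 80, isoformsPerGene = 2, nDtuGenes = 15,
                            dtuMinDprop = 0.3, meanLog = log(20000),
                            sdLog = 0.5, dispersion = 0, nBootstrap = 0,
                            seed = 9)
  cnt <- SummarizedExperiment::assay(sim$experiment, "counts")
  for (i in seq_len(nrow(sim$truth))) {
    t1 <- sim$truth$transcript_1[i]
    t2 <- sim$truth$transcript_2[i]
    # Poisson noise at mean >= ~5000 is < 2% relative
    expect_equal(cnt[t1, "B1"], cnt[t2, "A1"], tolerance = 0.1)
    expect_equal(cnt[t2, "B1"], cnt[t1, "A1"], tolerance = 0.1)
    # injected |dprop| recomputed from the A-side proportions
    pa <- cnt[c(t1, t2), "A1"] / sum(cnt[c(t1, t2), "A1"])
    expect_equal(sim$truth$injected_dprop[i], abs(pa[1] - pa[2]),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  expect_true(all(sim$truth$injected_dprop >= 0.3))
})

test_that("counts follow the negative-binomial mean-variance relation", {
  sim <- simulateExperiment(nGenes = 300, isoformsPerGene = 1, nRepsA = 50,
                            nRepsB = 1, meanLog = log(1000), sdLog = 0,
                            dispersion = 0.1, nBootstrap = 0, seed = 77)
  cnt <- SummarizedExperiment::assay(sim$experiment, "counts")
  a <- cnt[, 1:50]
  mu <- mean(a)
  expect_equal(mu, 1000, tolerance = 0.05)
  expect_equal(var(as.vector(a)), mu + 0.1 * mu^2, tolerance = 0.15)

  # dispersion 0 concentrates counts at the mean (Poisson limit)
  sim0 <- simulateExperiment(nGenes = 200, isoformsPerGene = 1, nRepsA = 10,
                             nRepsB = 1, meanLog = log(10000), sdLog = 0,
                             dispersion = 0, nBootstrap = 0, seed = 78)
  a0 <- SummarizedExperiment::assay(sim0$experiment, "counts")[, 1:10]
  cv <- sd(as.vector(a0)) / mean(a0)
  expect_lt(cv, 0.02)
})

test_that("bootstrap resampling preserves the library size exactly", {
  sim <- simulateExperiment(nGenes = 40, nBootstrap = 12, seed = 15)
  x <- sim$experiment
  cnt <- SummarizedExperiment::assay(x, "counts")
  for (s in colnames(x)) {
    expect_true(all(colSums(bootstraps(x)[[s]]) == sum(cnt[, s])))
  }
})

test_that("infeasible injection requests error", {
  expect_error(simulateExperiment(nGenes = 10, isoformsPerGene = 1,
                                  nDtuGenes = 5, seed = 1),
               "infeasible")
})

test_that("null splits are disjoint, deterministic and cover the pool", {
  sim <- simulateExperiment(nGenes = 30, nRepsA = 16, nRepsB = 1,
                            nBootstrap = 0, seed = 19)
  pool <- pullReplicates(sim$experiment, "A")
  ann <- annotationOf(sim$experiment)

  x <- nullSplit(pool, ann, groupSize = 8, seed = 3)
  expect_equal(as.integer(table(conditions(x))), c(8L, 8L))
  expect_equal(ncol(x), 16L)   # disjoint: all 16 distinct samples used

  x2 <- nullSplit(pool, ann, groupSize = 8, seed = 3)
  expect_identical(colnames(x), colnames(x2))

  expect_error(nullSplit(pool[1:5], ann, groupSize = 3, seed = 1),
               "pool too small")

  seen <- unique(unlist(lapply(1:100, function(s)
    colnames(nullSplit(pool, ann, groupSize = 3, seed = s)))))
  expect_setequal(seen, vapply(pool, function(r) r@sampleId, ""))
})

test_that("scoring matches an independent confusion-matrix recount", {
  perfect <- data.frame(gene_id = paste0("g", 1:10),
                        dtu_call = c(rep(TRUE, 4), rep(FALSE, 6)))
  sc <- scoreAgainstTruth(perfect, paste0("g", 1:4), "gene")
  expect_equal(c(sc$sensitivity, sc$fdr, sc$mcc), c(1, 0, 1))

  silent <- transform(perfect, dtu_call = FALSE)
  sc0 <- scoreAgainstTruth(silent, paste0("g", 1:4), "gene")
  expect_equal(c(sc0$sensitivity, sc0$fdr, sc0$mcc), c(0, 0, 0))

  withr::with_seed(33, {
    for (i in 1:50) {
      n <- 200
      ids <- paste0("g", seq_len(n))
      called <- sample(c(TRUE, FALSE), n, replace = TRUE)
      truth <- sample(ids, sample(0:80, 1))
      sc <- scoreAgainstTruth(data.frame(gene_id = ids, dtu_call = called),
                              truth, "gene")
      cm <- table(factor(called, c(FALSE, TRUE)),
                  factor(ids %in% truth, c(FALSE, TRUE)))
      tp <- cm["TRUE", "TRUE"]; fp <- cm["TRUE", "FALSE"]
      fn <- cm["FALSE", "TRUE"]; tn <- cm["FALSE", "FALSE"]
      expect_equal(sc$sensitivity,
                   if (tp + fn > 0) tp / (tp + fn) else NA_real_)
      expect_equal(sc$fdr, if (tp + fp > 0) fp / (tp + fp) else 0)
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      expect_equal(sc$mcc,
                   if (den > 0) (tp * tn - fp * fn) / den else 0,
                   tolerance = 1e-12)
    }
  })
})
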