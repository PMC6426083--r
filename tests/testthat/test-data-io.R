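test_that("annotation TSV parsing, conflicts and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id", "t1\tg1", "t2\tg1"), f)
  ann <- readAnnotationTSV(f)
  expect_equal(nrow(ann), 2L)
  expect_equal(sort(ann$transcript_id), c("t1", "t2"))
  expect_equal(unique(ann$gene_id), "g1")

  writeLines(c("transcript_id\tgene_id", "t1\tg1", "t1\tg2"), f)
  expect_error(readAnnotationTSV(f), "conflicting gene for t1")

  writeLines(c("foo\tbar", "t1\tg1"), f)
  expect_error(readAnnotationTSV(f), "expected")

  # 6-transcript, 3-gene fixture round-trips identically
  ann6 <- data.frame(transcript_id = paste0("t", 1:6),
                     gene_id = rep(paste0("g", 1:3), each = 2))
  writeAnnotationTSV(ann6, f)
  expect_equal(readAnnotationTSV(f), ann6)
})

test_that("GTF attribute extraction unions transcript and exon features", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t10\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tx\texon\t20\t30\t.\t+\t.\tgene_id "gA"; transcript_id "tA";'), f)
  ann <- readAnnotationGTF(f)
  expect_equal(ann, data.frame(transcript_id = "tA", gene_id = "gA"))

  writeLines(c(
    'chr1\tx\tgene\t1\t99\t.\t+\t.\tgene_id "gA";',
    'chr1\tx\ttranscript\t1\t50\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "gA"; transcript_id "tA2";',
    'chr1\tx\ttranscript\t60\t99\t.\t+\t.\tgene_id "gB"; transcript_id "tB1";'),
    f)
  ann <- readAnnotationGTF(f)
  expect_equal(nrow(ann), 3L)
  expect_setequal(ann$transcript_id, c("tA1", "tA2", "tB1"))
})

test_that("a generated GTF fixture reproduces the generator's map", {
  map <- data.frame(
    transcript_id = sprintf("g%02d.t%d", rep(1:50, each = 2), 1:2),
    gene_id = sprintf("g%02d", rep(1:50, each = 2)))
  f <- withr::local_tempfile(fileext = ".gtf")
  writeAnnotationGTF(map, f)
  got <- readAnnotationGTF(f)
  expect_equal(got[order(got$transcript_id), ],
               map[order(map$transcript_id), ],
               ignore_attr = TRUE)
})

test_that("salmon quant.sf parse, schema check and round-trip", {
  d <- withr::local_tempdir()
  writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
               "t1\t1000\t800\t500000\t10",
               "t2\t1000\t800\t0\t0",
               "t3\t1000\t800\t250000\t5"),
             file.path(d, "quant.sf"))
  rq <- readSalmonQuant(d)
  expect_s4_class(rq, "ReplicateQuant")
  expect_equal(unname(abundanceOf(rq)), c(10, 0, 5))
  expect_equal(names(abundanceOf(rq)), c("t1", "t2", "t3"))
  expect_equal(rq@unit, "counts")
  expect_equal(unname(abundanceOf(readSalmonQuant(d, abundance = "TPM"))),
               c(5e5, 0, 2.5e5))

  writeLines(c("Name\tLength\tEffectiveLength\tNumReads", "t1\t1\t1\t1"),
             file.path(d, "quant.sf"))
  expect_error(readSalmonQuant(d), "TPM")

  # writer/reader round-trip on simulator output
  sim <- simulateExperiment(nGenes = 15, nBootstrap = 4, seed = 3)
  rep1 <- pullReplicates(sim$experiment, "A")[[1]]
  qdir <- file.path(d, "s1")
  writeSalmonQuant(rep1, qdir)
  bsf <- file.path(d, "s1_boot.tsv")
  writeBootstrapTSV(rep1, bsf)
  back <- readSalmonQuant(qdir, sampleId = "A1", bootstrapPath = bsf)
  expect_equal(abundanceOf(back)[names(abundanceOf(rep1))],
               abundanceOf(rep1), tolerance = 1e-9)
  expect_equal(bootstraps(back)[rownames(bootstraps(rep1)), ],
               bootstraps(rep1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("kallisto HDF5 reader recovers counts and bootstrap tensors", {
  skip_if(Sys.which("python") == "" && Sys.which("python3") == "",
          "no python interpreter")
  d <- withr::local_tempdir()
  h5 <- file.path(d, "abundance.h5")
  py <- Sys.which("python"); if (py == "") py <- Sys.which("python3")
  gen <- file.path(d, "make_h5.py")
  writeLines(c(
    "import sys, h5py, numpy as np",
    "rng = np.random.default_rng(12)",
    "ids = [f't{i}' for i in range(20)]",
    "est = rng.integers(0, 100, 20).astype(float)",
    "with h5py.File(sys.argv[1], 'w') as h5:",
    "    h5.create_dataset('aux/ids', data=[s.encode() for s in ids])",
    "    h5.create_dataset('est_counts', data=est)",
    "    if sys.argv[2] == 'boot':",
    "        for b in range(100):",
    "            h5.create_dataset(f'bootstrap/bs{b}',",
    "                              data=rng.poisson(est).astype(float))",
    "    np.savetxt(sys.argv[3], est)"), gen)
  estFile <- file.path(d, "est.txt")
  res <- system2(py, c(gen, h5, "boot", estFile), stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(h5), "h5py unavailable")

  rq <- readKallistoH5(h5, sampleId = "k1")
  est <- scan(estFile, quiet = TRUE)
  expect_equal(unname(abundanceOf(rq)), est)
  expect_equal(names(abundanceOf(rq)), paste0("t", 0:19))
  expect_equal(dim(bootstraps(rq)), c(20L, 100L))

  # no bootstrap group -> bootstrap absent
  h5b <- file.path(d, "plain.h5")
  system2(py, c(gen, h5b, "plain", estFile), stdout = TRUE, stderr = TRUE)
  expect_null(bootstraps(readKallistoH5(h5b, sampleId = "k2")))
})

test_that("TPM scaling is linear, conserves totals and validates input", {
  tpm <- setNames(c(40, 0, 999960), c("t1", "t2", "t3"))
  rq <- ReplicateQuant("s1", tpm, unit = "TPM")
  sc <- scaleTpmToCounts(rq, 25e6)
  expect_equal(unname(abundanceOf(sc)["t1"]), 1000)
  expect_equal(unname(abundanceOf(sc)["t2"]), 0)
  expect_equal(sc@unit, "counts")
  # conservation: TPMs summing to 1e6 scale to exactly the library size
  expect_equal(sum(abundanceOf(sc)), 25e6)
  # linearity: scale-then-sum equals sum-then-scale
  expect_equal(sum(abundanceOf(sc)), sum(tpm) * 25, tolerance = 1e-12)

  expect_error(scaleTpmToCounts(rq, 0), "positive")
  expect_error(scaleTpmToCounts(sc, 1e6), "not in TPM")

  # bootstrap values are scaled too
  bs <- matrix(c(40, 0, 999960, 20, 10, 999970), ncol = 2,
               dimnames = list(names(tpm), NULL))
  rqb <- ReplicateQuant("s2", tpm, bootstrap = bs, unit = "TPM")
  expect_equal(unname(bootstraps(scaleTpmToCounts(rqb, 2e6))[1, ]), c(80, 40))
})

test_that("experiment assembly enforces the shared universe and drops unannotated ids", {
  ann <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g1"))
  r1 <- ReplicateQuant("a1", c(t1 = 5, t2 = 6, t9 = 1))
  r2 <- ReplicateQuant("b1", c(t1 = 2, t2 = 9, t9 = 0))
  expect_message(x <- buildExperiment(list(r1), list(r2), ann),
                 "1 quantified transcript")
  expect_equal(nrow(x), 2L)
  expect_equal(S4Vectors::metadata(x)$n_unannotated_dropped, 1L)

  r3 <- ReplicateQuant("b2", c(t1 = 2, tX = 9))
  expect_error(buildExperiment(list(r1), list(r3), ann),
               "different transcript universe")
  expect_error(
    buildExperiment(list(r1), list(ReplicateQuant("t", c(t1 = 1, t2 = 1),
                                                  unit = "TPM")), ann),
    "scaleTpmToCounts")
})
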