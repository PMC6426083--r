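#' @importFrom stats rlnorm rnbinom rpois rmultinom
NULL

#' Simulate a two-condition bootstrapped DTU experiment
#'
#' Emulates the benchmark designs at the count level. Per-transcript baseline
#' means are drawn log-normally; replicate counts are negative-binomial with
#' a common dispersion (variance `mu + dispersion * mu^2`; dispersion 0 gives
#' Poisson); bootstrap iterations are produced by multinomial resampling of
#' each replicate's counts at its exact library size, emulating
#' read-assignment uncertainty. Condition B uses the same means as condition
#' A, except for `nDtuGenes` genes in which the means of the two most
#' abundant isoforms (judged on condition-A means, ties broken by transcript
#' id) are swapped — a pure isoform-usage change that leaves total gene
#' expression untouched.
#'
#' DTU genes are drawn among "well-expressed" candidates: at least two
#' isoforms, total mean expression at least `minDtuMean`, and a swap-induced
#' proportion change of at least `dtuMinDprop` (and nonzero, so every
#' injected event is a real event).
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene integer vector of possible isoform counts, sampled
#'   uniformly per gene.
#' @param nRepsA,nRepsB replicates per condition.
#' @param meanLog,sdLog log-scale location/spread of per-transcript means.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param nBootstrap bootstrap iterations per replicate (0 = none).
#' @param nDtuGenes number of genes with an injected isoform swap.
#' @param dtuMinDprop minimum injected |dprop| for candidate genes.
#' @param minDtuMean minimum total mean expression for candidate genes.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return list with `experiment` (a [DTUExperiment-class]) and `truth`
#'   (data.frame: `gene_id`, `transcript_1`, `transcript_2`,
#'   `injected_dprop`, one row per injected gene).
#' @export
simulateExperiment <- function(nGenes = 2000, isoformsPerGene = 1:6,
                               nRepsA = 3, nRepsB = 3,
                               meanLog = log(100), sdLog = 1.5,
                               dispersion = 0.1, nBootstrap = 100,
                               nDtuGenes = 0, dtuMinDprop = 0,
                               minDtuMean = 100, seed = 1) {
  stopifnot(nGenes >= 1, all(isoformsPerGene >= 1), nRepsA >= 1, nRepsB >= 1,
            dispersion >= 0, nBootstrap >= 0, nDtuGenes >= 0,
            dtuMinDprop >= 0, dtuMinDprop <= 1)
  .withSeed(seed, {
    k <- sample(rep(isoformsPerGene, 2L), nGenes, replace = TRUE)
    geneIds <- sprintf("g%05d", seq_len(nGenes))
    gi <- rep.int(seq_len(nGenes), k)
    txIds <- sprintf("%s.t%d", geneIds[gi], sequence(k))
    nTx <- length(txIds)
    meansA <- rlnorm(nTx, meanLog, sdLog)

    # candidate genes for injection and the swap itself
    geneTot <- rowsum(meansA, gi)[, 1L]
    top2 <- function(idx) idx[order(-meansA[idx], txIds[idx])][1:2]
    byGene <- split(seq_len(nTx), gi)
    swapDprop <- rep(0, nGenes)
    pairs <- vector("list", nGenes)
    for (g in which(k >= 2)) {
      p <- top2(byGene[[g]])
      pairs[[g]] <- p
      swapDprop[g] <- abs(meansA[p[1L]] - meansA[p[2L]]) / geneTot[g]
    }
    candidates <- which(k >= 2 & geneTot >= minDtuMean &
                        swapDprop > 0 & swapDprop >= dtuMinDprop)
    if (nDtuGenes > length(candidates))
      stop("infeasible nDtuGenes: only ", length(candidates),
           " candidate genes satisfy the injection constraints")
    dtu <- sort(sample(candidates, nDtuGenes))
    meansB <- meansA
    for (g in dtu) {
      p <- pairs[[g]]
      meansB[p] <- meansA[rev(p)]
    }

    rCounts <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    sampleIds <- c(sprintf("A%d", seq_len(nRepsA)),
                   sprintf("B%d", seq_len(nRepsB)))
    counts <- matrix(0, nTx, nRepsA + nRepsB,
                     dimnames = list(txIds, sampleIds))
    for (s in seq_len(nRepsA)) counts[, s] <- rCounts(meansA)
    for (s in seq_len(nRepsB)) counts[, nRepsA + s] <- rCounts(meansB)

    bs <- list()
    if (nBootstrap > 0) {
      for (s in sampleIds) {
        lib <- sum(counts[, s])
        m <- if (lib > 0)
          rmultinom(nBootstrap, lib, counts[, s])
        else
          matrix(0, nTx, nBootstrap)
        dimnames(m) <- list(txIds, paste0("iter", seq_len(nBootstrap)))
        bs[[s]] <- m
      }
    }

    se <- SummarizedExperiment(
      assays = list(counts = counts),
      rowData = DataFrame(gene_id = geneIds[gi], row.names = txIds),
      colData = DataFrame(
        condition = factor(rep(c("A", "B"), c(nRepsA, nRepsB)),
                           levels = c("A", "B")),
        row.names = sampleIds))
    x <- new("DTUExperiment", se, bootstraps = as(bs, "SimpleList"))
    metadata(x)$n_unannotated_dropped <- 0L
    validObject(x)

    truth <- data.frame(
      gene_id = geneIds[dtu],
      transcript_1 = vapply(pairs[dtu], function(p) txIds[p[1L]], ""),
      transcript_2 = vapply(pairs[dtu], function(p) txIds[p[2L]], ""),
      injected_dprop = swapDprop[dtu],
      row.names = NULL)
    list(experiment = x, truth = truth)
  })
}

#' Extract the transcript-to-gene map of an experiment
#'
#' @param x a [DTUExperiment-class].
#' @return data.frame with `transcript_id`, `gene_id`.
#' @export
annotationOf <- function(x) {
  stopifnot(is(x, "DTUExperiment"))
  data.frame(transcript_id = rownames(x),
             gene_id = as.character(rowData(x)$gene_id),
             row.names = NULL)
}

#' Split a single-condition pool into a null two-group experiment
#'
#' Samples two disjoint groups without replacement from a pool of replicates
#' that all come from one condition, so every DTU call on the result is a
#' false positive by construction.
#'
#' @param pool list of [ReplicateQuant-class] objects from one condition.
#' @param annotation data.frame with `transcript_id`, `gene_id`.
#' @param groupSize replicates per pseudo-group; the pool must hold at least
#'   `2 * groupSize`.
#' @param seed integer seed; the split is deterministic given it.
#' @return A [DTUExperiment-class] with pseudo-conditions "A" and "B".
#' @export
nullSplit <- function(pool, annotation, groupSize, seed = 1) {
  stopifnot(groupSize >= 1)
  if (length(pool) < 2 * groupSize)
    stop("pool too small: need at least ", 2 * groupSize, " replicates")
  picked <- .withSeed(seed, sample.int(length(pool), 2L * groupSize))
  buildExperiment(pool[picked[seq_len(groupSize)]],
                  pool[picked[groupSize + seq_len(groupSize)]],
                  annotation)
}

#' Score calls against the injected truth
#'
#' Computes sensitivity (fraction of injected events detected), false
#' discovery rate (fraction of reported events not injected; 0 when nothing
#' is called) and the Matthews correlation coefficient over the 2x2 confusion
#' counts. The feature universe is every gene (or transcript) in the result
#' table.
#'
#' @param result a [DTUResult-class], or a data.frame with an id column
#'   (`gene_id`/`transcript_id`) and `dtu_call`.
#' @param truth data.frame as returned by [simulateExperiment()], or a
#'   character vector of true feature ids.
#' @param level `"gene"` or `"transcript"`.
#' @return list with `sensitivity`, `fdr`, `mcc` and the confusion counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
scoreAgainstTruth <- function(result, truth, level = c("gene", "transcript")) {
  level <- match.arg(level)
  tab <- if (is(result, "DTUResult")) {
    if (level == "gene") geneResults(result) else txResults(result)
  } else result
  idCol <- if (level == "gene") "gene_id" else "transcript_id"
  ids <- tab[[idCol]]
  called <- tab$dtu_call
  trueIds <- if (is.character(truth)) truth
             else if (level == "gene") truth$gene_id
             else c(truth$transcript_1, truth$transcript_2)
  isTrue <- ids %in% trueIds
  tp <- sum(called & isTrue)
  fp <- sum(called & !isTrue)
  fn <- sum(!called & isTrue)
  tn <- sum(!called & !isTrue)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(sensitivity = sens, fdr = fdr, mcc = mcc,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
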