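#' Run configuration for DTU calling
#'
#' All thresholds and seeds of a run, recorded verbatim in every output as
#' provenance. Defaults: significance level 0.05 (BH-adjusted), effect-size
#' (proportion-difference) threshold 0.2, abundance detection threshold 5
#' counts (set 0 to disable pre-filtering entirely), quantification
#' reproducibility threshold 0.95 over 100 bootstrap draws, inter-replicate
#' reproducibility threshold 0.85.
#'
#' @param alpha significance level applied to BH-adjusted p-values.
#' @param dpropThreshold minimum absolute proportion difference for a call.
#' @param abundanceThreshold minimum mean abundance (counts, per condition)
#'   for a transcript to count as detected; 0 disables the pre-filter.
#' @param qrepThreshold minimum fraction of bootstrap draws that must
#'   reproduce a provisional call (strictly greater-than).
#' @param rrepThreshold minimum fraction of cross-condition replicate pairs
#'   that must reproduce a provisional call (strictly greater-than).
#' @param nQuantDraws number of random bootstrap draws.
#' @param seed integer seed driving the bootstrap draws.
#' @param quantReprod,replicateReprod logical switches for the two
#'   reproducibility filters.
#' @return named list of validated settings.
#' @export
dtuConfig <- function(alpha = 0.05, dpropThreshold = 0.2,
                      abundanceThreshold = 5,
                      qrepThreshold = 0.95, rrepThreshold = 0.85,
                      nQuantDraws = 100L, seed = 1L,
                      quantReprod = TRUE, replicateReprod = TRUE) {
  stopifnot(alpha > 0, alpha < 1,
            dpropThreshold >= 0, dpropThreshold <= 1,
            abundanceThreshold >= 0,
            qrepThreshold >= 0, qrepThreshold <= 1,
            rrepThreshold >= 0, rrepThreshold <= 1,
            nQuantDraws >= 1)
  list(alpha = alpha, dpropThreshold = dpropThreshold,
       abundanceThreshold = abundanceThreshold,
       qrepThreshold = qrepThreshold, rrepThreshold = rrepThreshold,
       nQuantDraws = as.integer(nQuantDraws), seed = as.integer(seed),
       quantReprod = isTRUE(quantReprod),
       replicateReprod = isTRUE(replicateReprod))
}

# Precomputed gene/transcript bookkeeping, shared by the main run and every
# reproducibility re-run so the hot path does no string work.
.pipelineContext <- function(x) {
  g <- as.character(rowData(x)$gene_id)
  geneF <- factor(g)
  list(txIds = rownames(x),
       geneIds = g,
       gi = as.integer(geneF),
       geneLevels = levels(geneF),
       nG = nlevels(geneF),
       nIso = tabulate(as.integer(geneF), nlevels(geneF)),
       condA = which(conditions(x) == levels(conditions(x))[1L]),
       condB = which(conditions(x) == levels(conditions(x))[2L]))
}

.REASONS <- c("ok", "unannotated", "absent_in_a_condition", "single_isoform",
              "below_abundance_threshold")

# One full pass of the calling pipeline (detection -> eligibility -> G-tests
# -> BH -> effect classification) on explicit count matrices. This is the
# unit re-run per bootstrap draw and per replicate pair.
.pipelineRun <- function(cntA, cntB, ctx, alpha, dpropThreshold,
                         abundanceThreshold) {
  meanA <- rowMeans(cntA)
  meanB <- rowMeans(cntB)
  detA <- meanA >= abundanceThreshold
  detB <- meanB >= abundanceThreshold
  detEither <- detA | detB
  sumA <- rowSums(cntA)
  sumB <- rowSums(cntB)
  gi <- ctx$gi
  nG <- ctx$nG

  st <- .gStatVec(sumA, sumB, gi, nG)
  nDet <- rowsum(detEither + 0, gi)[, 1L]

  # gene eligibility with the first failing reason in fixed order
  geneReason <- rep("ok", nG)
  absent <- st$geneSumA == 0 | st$geneSumB == 0
  single <- ctx$nIso < 2 | st$nNonzeroRows < 2
  lowAb <- nDet < 2
  geneReason[lowAb] <- "below_abundance_threshold"
  geneReason[single] <- "single_isoform"
  geneReason[absent] <- "absent_in_a_condition"
  geneEligible <- geneReason == "ok" & !st$geneDegenerate
  geneReason[!geneEligible & geneReason == "ok"] <- "single_isoform"

  # proportions and effect sizes
  gAi <- st$geneSumA[gi]
  gBi <- st$geneSumB[gi]
  propA <- ifelse(gAi > 0, sumA / gAi, NA_real_)
  propB <- ifelse(gBi > 0, sumB / gBi, NA_real_)
  dprop <- propB - propA
  absd <- abs(dprop)
  absd0 <- ifelse(is.na(absd), 0, absd)
  effect <- .groupMax(absd0, gi, nG)

  # transcript eligibility
  txReason <- geneReason[gi]
  rowTot <- sumA + sumB
  sibZero <- (gAi - sumA) + (gBi - sumB) == 0
  txEligible <- geneEligible[gi] & detEither & rowTot > 0 & !sibZero
  txReason[geneEligible[gi] & (!detEither | rowTot == 0)] <-
    "below_abundance_threshold"
  txReason[geneEligible[gi] & detEither & rowTot > 0 & sibZero] <-
    "single_isoform"

  # BH within each family, independently
  genePAdj <- rep(NA_real_, nG)
  genePAdj[geneEligible] <- p.adjust(st$geneP[geneEligible], "BH")
  txPAdj <- rep(NA_real_, length(gi))
  txPAdj[txEligible] <- p.adjust(st$txP[txEligible], "BH")

  geneSig <- geneEligible & !is.na(genePAdj) & genePAdj < alpha
  geneCall <- geneSig & effect >= dpropThreshold
  txSig <- txEligible & !is.na(txPAdj) & txPAdj < alpha
  txCall <- txSig & absd0 >= dpropThreshold

  geneCause <- ifelse(!geneEligible, "ineligible",
                      ifelse(!geneSig, "not_significant",
                             ifelse(!geneCall, "small_effect", "none")))
  txCause <- ifelse(!txEligible, "ineligible",
                    ifelse(!txSig, "not_significant",
                           ifelse(!txCall, "small_effect", "none")))

  list(detA = detA, detB = detB, sumA = sumA, sumB = sumB,
       meanA = meanA, meanB = meanB,
       propA = propA, propB = propB, dprop = dprop,
       geneEligible = geneEligible, geneReason = geneReason,
       geneG = st$geneG, geneDf = st$geneDf, geneP = st$geneP,
       genePAdj = genePAdj, effect = effect,
       geneCall = geneCall, geneCause = geneCause,
       geneSumA = st$geneSumA, geneSumB = st$geneSumB, nDet = nDet,
       txEligible = txEligible, txReason = txReason,
       txG = st$txG, txP = st$txP, txPAdj = txPAdj,
       txCall = txCall, txCause = txCause)
}

# max of x within groups gi (1..nG); groups with no finite entry get 0
.groupMax <- function(x, gi, nG) {
  o <- order(gi, -x)
  first <- !duplicated(gi[o])
  out <- numeric(nG)
  out[gi[o][first]] <- x[o][first]
  out
}

#' Per-isoform proportions and proportion differences
#'
#' @param geneCounts isoforms x 2 matrix of replicate-summed counts for one
#'   gene; both column sums must be positive.
#' @return data.frame with `prop_a`, `prop_b` (each summing to 1) and
#'   `dprop = prop_b - prop_a` per isoform.
#' @export
isoformProportions <- function(geneCounts) {
  m <- as.matrix(geneCounts)
  if (ncol(m) != 2L) stop("expected a 2-column isoforms x conditions table")
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero column sum: gene absent in a condition")
  pa <- m[, 1L] / cs[1L]
  pb <- m[, 2L] / cs[2L]
  data.frame(prop_a = pa, prop_b = pb, dprop = pb - pa,
             row.names = rownames(m))
}

#' Gene-level effect size
#'
#' The largest absolute proportion difference among a gene's isoforms.
#'
#' @param dprops numeric vector of per-isoform proportion differences.
#' @return value in `[0, 1]`.
#' @export
geneEffectSize <- function(dprops) {
  if (!length(dprops)) return(0)
  max(abs(dprops), na.rm = TRUE)
}

#' Significance-and-effect classification
#'
#' A feature is provisionally called DTU when its BH-adjusted p-value is
#' below `alpha` AND its effect size reaches `dpropThreshold`; a significant
#' feature whose proportion change is small is rejected with cause
#' `small_effect`. Reproducibility causes are appended downstream by
#' [applyReproducibilityFilters()].
#'
#' @param pAdjusted BH-adjusted p-values (`NA` for untested features).
#' @param effectSize absolute proportion-difference effect sizes.
#' @param eligible logical eligibility per feature.
#' @param alpha significance level.
#' @param dpropThreshold effect-size threshold.
#' @return data.frame with `dtu_call` and `rejection_cause` (first failing
#'   criterion in the order ineligible, not_significant, small_effect).
#' @export
classifyCalls <- function(pAdjusted, effectSize, eligible,
                          alpha = 0.05, dpropThreshold = 0.2) {
  sig <- eligible & !is.na(pAdjusted) & pAdjusted < alpha
  call <- sig & effectSize >= dpropThreshold
  cause <- ifelse(!eligible, "ineligible",
                  ifelse(!sig, "not_significant",
                         ifelse(!call, "small_effect", "none")))
  data.frame(dtu_call = call, rejection_cause = cause)
}

#' Isoform-switch detection
#'
#' Reports genes whose most abundant (dominant) isoform differs between the
#' two conditions. Ties on the maximum proportion are broken by lexicographic
#' transcript id and flagged.
#'
#' @param txTable data.frame with columns `gene_id`, `transcript_id`,
#'   `prop_a`, `prop_b` (as produced by [callDTU()]).
#' @return data.frame with one row per switching gene: `gene_id`,
#'   `dominant_a`, `dominant_b`, `tie`.
#' @export
findSwitches <- function(txTable) {
  keep <- !is.na(txTable$prop_a) & !is.na(txTable$prop_b)
  tt <- txTable[keep, , drop = FALSE]
  if (!nrow(tt))
    return(data.frame(gene_id = character(), dominant_a = character(),
                      dominant_b = character(), tie = logical()))
  dom <- function(p) {
    o <- order(tt$gene_id, -p, tt$transcript_id, method = "radix")
    first <- !duplicated(tt$gene_id[o])
    top <- tt[o, ][first, ]
    # a tie: another isoform of the gene attains the same max proportion
    key <- paste0(tt$gene_id, "\r", signif(p, 12))
    topKey <- paste0(top$gene_id, "\r", signif(p[o][first], 12))
    nAtMax <- table(key)[topKey]
    data.frame(gene_id = top$gene_id, dominant = top$transcript_id,
               tie = as.integer(nAtMax) > 1L)
  }
  da <- dom(tt$prop_a)
  db <- dom(tt$prop_b)
  stopifnot(identical(da$gene_id, db$gene_id))
  sw <- da$dominant != db$dominant
  data.frame(gene_id = da$gene_id[sw],
             dominant_a = da$dominant[sw],
             dominant_b = db$dominant[sw],
             tie = (da$tie | db$tie)[sw],
             row.names = NULL)
}

#' Call differential transcript usage
#'
#' The full calling pipeline on a two-condition experiment: detection
#' pre-filter, eligibility, gene-level and transcript-level G-tests on
#' replicate-summed counts, independent BH correction of the two families,
#' proportion-difference effect sizes, provisional classification, and
#' (when the data allow) the two bootstrap-based reproducibility filters.
#'
#' Quantification reproducibility requires bootstrap matrices on every
#' sample; inter-replicate reproducibility requires at least two replicates
#' per condition. When a prerequisite is missing the filter is skipped with a
#' warning and the corresponding score column is `NA`.
#'
#' @param x a [DTUExperiment-class].
#' @param config a [dtuConfig()] list.
#' @return A [DTUResult-class].
#' @examples
#' sim <- simulateExperiment(nGenes = 40, nDtuGenes = 5, nBootstrap = 20,
#'                           seed = 7)
#' res <- callDTU(sim$experiment, dtuConfig(abundanceThreshold = 0, seed = 7))
#' res
#' @export
callDTU <- function(x, config = dtuConfig()) {
  stopifnot(is(x, "DTUExperiment"))
  ctx <- .pipelineContext(x)
  cnt <- assay(x, "counts")
  cntA <- cnt[, ctx$condA, drop = FALSE]
  cntB <- cnt[, ctx$condB, drop = FALSE]
  main <- .pipelineRun(cntA, cntB, ctx, config$alpha, config$dpropThreshold,
                       config$abundanceThreshold)

  qrepGene <- rep(NA_real_, ctx$nG)
  qrepTx <- rep(NA_real_, nrow(x))
  nDraws <- 0L
  if (config$quantReprod) {
    bs <- bootstraps(x)
    if (length(bs) == ncol(x)) {
      qs <- .quantReprodScores(x, ctx, config)
      qrepGene <- qs$gene
      qrepTx <- qs$tx
      nDraws <- config$nQuantDraws
    } else {
      warning("quantification reproducibility skipped: ",
              "bootstrap matrices missing for ",
              ncol(x) - length(bs), " sample(s)")
    }
  }

  rrepGene <- rep(NA_real_, ctx$nG)
  rrepTx <- rep(NA_real_, nrow(x))
  nPairs <- 0L
  if (config$replicateReprod) {
    if (length(ctx$condA) >= 2L && length(ctx$condB) >= 2L) {
      rs <- .replicateReprodScores(x, ctx, config)
      rrepGene <- rs$gene
      rrepTx <- rs$tx
      nPairs <- rs$nPairs
    } else {
      warning("inter-replicate reproducibility skipped: ",
              "needs >= 2 replicates per condition")
    }
  }

  gene <- .applyReprodVec(main$geneCall, main$geneCause,
                          qrepGene, rrepGene,
                          config$qrepThreshold, config$rrepThreshold)
  tx <- .applyReprodVec(main$txCall, main$txCause,
                        qrepTx, rrepTx,
                        config$qrepThreshold, config$rrepThreshold)

  geneTab <- data.frame(
    gene_id = ctx$geneLevels,
    n_isoforms = ctx$nIso,
    n_detected = main$nDet,
    sum_a = main$geneSumA, sum_b = main$geneSumB,
    eligible = main$geneEligible,
    g_statistic = main$geneG, df = main$geneDf,
    p_value = main$geneP, p_adjusted = main$genePAdj,
    effect_size = main$effect,
    qrep_fraction = qrepGene, rrep_fraction = rrepGene,
    dtu_call = gene$call, rejection_cause = gene$cause,
    row.names = NULL)
  txTab <- data.frame(
    transcript_id = ctx$txIds,
    gene_id = ctx$geneIds,
    detected_a = main$detA, detected_b = main$detB,
    sum_a = main$sumA, sum_b = main$sumB,
    prop_a = main$propA, prop_b = main$propB, dprop = main$dprop,
    eligible = main$txEligible,
    g_statistic = main$txG, df = ifelse(is.na(main$txG), NA_real_, 1),
    p_value = main$txP, p_adjusted = main$txPAdj,
    qrep_fraction = qrepTx, rrep_fraction = rrepTx,
    dtu_call = tx$call, rejection_cause = tx$cause,
    row.names = NULL)
  elig <- rbind(
    data.frame(feature_id = geneTab$gene_id, level = "gene",
               eligible = geneTab$eligible, reason = main$geneReason),
    data.frame(feature_id = txTab$transcript_id, level = "transcript",
               eligible = txTab$eligible, reason = main$txReason))

  prov <- config
  prov$n_quant_draws_used <- nDraws
  prov$n_replicate_subsets_used <- nPairs
  prov$conditions <- levels(conditions(x))
  prov$n_replicates <- as.integer(table(conditions(x)))
  new("DTUResult", geneResults = geneTab, txResults = txTab,
      eligibility = elig, switches = findSwitches(txTab), config = prov)
}
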