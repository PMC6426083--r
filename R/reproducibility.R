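# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Fraction of bootstrap draws reproducing a provisional positive call.
.quantReprodScores <- function(x, ctx, config) {
  bs <- bootstraps(x)
  samples <- colnames(x)
  bsList <- lapply(samples, function(s) bs[[s]])
  nIters <- vapply(bsList, ncol, integer(1))
  nTx <- nrow(x)
  posGene <- numeric(ctx$nG)
  posTx <- numeric(nTx)
  ia <- ctx$condA
  ib <- ctx$condB
  .withSeed(config$seed, {
    for (d in seq_len(config$nQuantDraws)) {
      pick <- vapply(seq_along(bsList),
                     function(i) bsList[[i]][, sample.int(nIters[i], 1L)],
                     numeric(nTx))
      run <- .pipelineRun(pick[, ia, drop = FALSE], pick[, ib, drop = FALSE],
                          ctx, config$alpha, config$dpropThreshold,
                          config$abundanceThreshold)
      posGene <- posGene + run$geneCall
      posTx <- posTx + run$txCall
    }
  })
  list(gene = posGene / config$nQuantDraws,
       tx = posTx / config$nQuantDraws)
}

# Fraction of cross-condition replicate pairs reproducing a positive call:
# all n_a x n_b one-vs-one pairings are run (9 pairs for a 3 vs 3 design).
.replicateReprodScores <- function(x, ctx, config) {
  cnt <- assay(x, "counts")
  posGene <- numeric(ctx$nG)
  posTx <- numeric(nrow(x))
  nPairs <- 0L
  for (i in ctx$condA) {
    for (j in ctx$condB) {
      run <- .pipelineRun(cnt[, i, drop = FALSE], cnt[, j, drop = FALSE],
                          ctx, config$alpha, config$dpropThreshold,
                          config$abundanceThreshold)
      posGene <- posGene + run$geneCall
      posTx <- posTx + run$txCall
      nPairs <- nPairs + 1L
    }
  }
  list(gene = posGene / nPairs, tx = posTx / nPairs, nPairs = nPairs)
}

# Demote provisional positives that fail a reproducibility threshold; the
# quantification filter is checked first. Absent scores (NA) leave the call
# untouched. Filters only ever remove calls.
.applyReprodVec <- function(call, cause, qrep, rrep, qThr, rThr) {
  failQ <- call & !is.na(qrep) & qrep <= qThr
  failR <- call & !failQ & !is.na(rrep) & rrep <= rThr
  cause[failQ] <- "low_quant_reproducibility"
  cause[failR] <- "low_replicate_reproducibility"
  list(call = call & !failQ & !failR, cause = cause)
}

#' Quantification reproducibility scores
#'
#' For each of `nQuantDraws` draws, one bootstrap iteration index is sampled
#' uniformly (with replacement, independently per replicate), the full
#' calling pipeline is re-run on the drawn counts, and the score is the
#' fraction of draws yielding a positive provisional call. Deterministic
#' given the seed in `config`.
#'
#' @param x a [DTUExperiment-class] with bootstraps on every sample.
#' @param config a [dtuConfig()] list (uses `alpha`, `dpropThreshold`,
#'   `abundanceThreshold`, `nQuantDraws`, `seed`).
#' @return data.frame with `feature_id`, `level`, `fraction`, `n_draws`.
#' @export
quantReproducibility <- function(x, config = dtuConfig()) {
  stopifnot(is(x, "DTUExperiment"))
  if (length(bootstraps(x)) != ncol(x))
    stop("every replicate needs a bootstrap matrix")
  ctx <- .pipelineContext(x)
  qs <- .quantReprodScores(x, ctx, config)
  rbind(
    data.frame(feature_id = ctx$geneLevels, level = "gene",
               fraction = qs$gene, n_draws = config$nQuantDraws),
    data.frame(feature_id = ctx$txIds, level = "transcript",
               fraction = qs$tx, n_draws = config$nQuantDraws))
}

#' Inter-replicate reproducibility scores
#'
#' Re-runs the calling pipeline once per cross-condition replicate pair (all
#' `n_a * n_b` one-vs-one pairings) and scores each feature by the fraction
#' of pairs with a positive provisional call.
#'
#' @param x a [DTUExperiment-class] with >= 2 replicates per condition.
#' @param config a [dtuConfig()] list.
#' @return data.frame with `feature_id`, `level`, `fraction`, `n_subsets`.
#' @export
replicateReproducibility <- function(x, config = dtuConfig()) {
  stopifnot(is(x, "DTUExperiment"))
  ctx <- .pipelineContext(x)
  if (length(ctx$condA) < 2L || length(ctx$condB) < 2L)
    stop("inter-replicate reproducibility needs >= 2 replicates per condition")
  rs <- .replicateReprodScores(x, ctx, config)
  rbind(
    data.frame(feature_id = ctx$geneLevels, level = "gene",
               fraction = rs$gene, n_subsets = rs$nPairs),
    data.frame(feature_id = ctx$txIds, level = "transcript",
               fraction = rs$tx, n_subsets = rs$nPairs))
}

#' Re-apply the reproducibility filters at different thresholds
#'
#' Reconstructs the provisional calls from the stored statistics (BH-adjusted
#' p-values and effect sizes at the run's `alpha` and `dpropThreshold`) and
#' re-screens them against the stored reproducibility fractions. A
#' provisional positive survives only if its quantification-reproducibility
#' fraction strictly exceeds `qrepThreshold` and its replicate fraction
#' strictly exceeds `rrepThreshold` (scores that are absent impose no
#' constraint). Failures record `low_quant_reproducibility` or
#' `low_replicate_reproducibility` as rejection cause, in that order.
#'
#' @param result a [DTUResult-class].
#' @param qrepThreshold,rrepThreshold new thresholds.
#' @return A [DTUResult-class] with updated calls, causes and config.
#' @export
applyReproducibilityFilters <- function(result, qrepThreshold = 0.95,
                                        rrepThreshold = 0.85) {
  stopifnot(is(result, "DTUResult"))
  cfg <- result@config
  g <- result@geneResults
  tx <- result@txResults
  pg <- classifyCalls(g$p_adjusted, g$effect_size, g$eligible,
                      cfg$alpha, cfg$dpropThreshold)
  pt <- classifyCalls(tx$p_adjusted, abs(tx$dprop), tx$eligible,
                      cfg$alpha, cfg$dpropThreshold)
  fg <- .applyReprodVec(pg$dtu_call, pg$rejection_cause,
                        g$qrep_fraction, g$rrep_fraction,
                        qrepThreshold, rrepThreshold)
  ft <- .applyReprodVec(pt$dtu_call, pt$rejection_cause,
                        tx$qrep_fraction, tx$rrep_fraction,
                        qrepThreshold, rrepThreshold)
  g$dtu_call <- fg$call; g$rejection_cause <- fg$cause
  tx$dtu_call <- ft$call; tx$rejection_cause <- ft$cause
  cfg$qrepThreshold <- qrepThreshold
  cfg$rrepThreshold <- rrepThreshold
  initialize(result, geneResults = g, txResults = tx, config = cfg)
}
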