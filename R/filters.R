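#' Detection pre-filter
#'
#' A transcript is detected in a condition when its mean abundance across
#' that condition's replicates reaches `abundanceThreshold`. At threshold 0
#' every transcript is detected in both conditions (no pre-filter), which is
#' the setting used for benchmarking.
#'
#' @param x a [DTUExperiment-class] (abundances in counts).
#' @param abundanceThreshold non-negative detection threshold.
#' @return data.frame with `transcript_id`, `detected_a`, `detected_b`.
#' @export
detectTranscripts <- function(x, abundanceThreshold = 5) {
  stopifnot(is(x, "DTUExperiment"), abundanceThreshold >= 0)
  ctx <- .pipelineContext(x)
  cnt <- assay(x, "counts")
  data.frame(
    transcript_id = rownames(x),
    detected_a = rowMeans(cnt[, ctx$condA, drop = FALSE]) >= abundanceThreshold,
    detected_b = rowMeans(cnt[, ctx$condB, drop = FALSE]) >= abundanceThreshold,
    row.names = NULL)
}

#' Eligibility of genes and transcripts for DTU testing
#'
#' Isoform-ratio changes are only defined for genes expressed in both
#' conditions with at least two detected isoforms; a transcript is eligible
#' when its gene is eligible and the transcript is detected in at least one
#' condition. Each feature receives exactly one record carrying the first
#' failing reason in the fixed order unannotated, absent_in_a_condition,
#' single_isoform, below_abundance_threshold.
#'
#' @param x a [DTUExperiment-class].
#' @param abundanceThreshold detection threshold passed to
#'   [detectTranscripts()].
#' @return data.frame with `feature_id`, `level` ("gene"/"transcript"),
#'   `eligible`, `reason`.
#' @export
eligibleFeatures <- function(x, abundanceThreshold = 5) {
  stopifnot(is(x, "DTUExperiment"))
  ctx <- .pipelineContext(x)
  cnt <- assay(x, "counts")
  run <- .pipelineRun(cnt[, ctx$condA, drop = FALSE],
                      cnt[, ctx$condB, drop = FALSE],
                      ctx, alpha = 0.05, dpropThreshold = 0.2,
                      abundanceThreshold = abundanceThreshold)
  rbind(
    data.frame(feature_id = ctx$geneLevels, level = "gene",
               eligible = run$geneEligible, reason = run$geneReason),
    data.frame(feature_id = ctx$txIds, level = "transcript",
               eligible = run$txEligible, reason = run$txReason))
}

#' Write an eligibility table as TSV
#'
#' @param eligibility data.frame from [eligibleFeatures()] or
#'   [eligibility()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEligibilityTSV <- function(eligibility, path) {
  data.table::fwrite(eligibility, path, sep = "\t")
  invisible(path)
}
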