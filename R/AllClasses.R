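#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors SimpleList
#' @import SummarizedExperiment
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Single-sample transcript quantification
#'
#' Holds one replicate's transcript abundances: a point estimate per
#' transcript, optionally a matrix of bootstrapped quantification iterations
#' (inferential replicates), and the unit of the values.
#'
#' @slot sampleId single sample identifier.
#' @slot abundance named numeric vector, one non-negative value per
#'   transcript, in the unit given by `unit`.
#' @slot bootstrap `NULL`, or a transcripts x iterations matrix of
#'   non-negative values with rownames equal to `names(abundance)`.
#' @slot unit `"counts"` or `"TPM"`.
#'
#' @aliases ReplicateQuant-class
#' @exportClass ReplicateQuant
setClass("ReplicateQuant",
  representation(
    sampleId = "character",
    abundance = "numeric",
    bootstrap = "matrixOrNULL",
    unit = "character"
  )
)

setValidity("ReplicateQuant", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (is.null(names(object@abundance)) || anyNA(names(object@abundance)) ||
      any(!nzchar(names(object@abundance))))
    msg <- c(msg, "abundance must be named by transcript id")
  if (anyDuplicated(names(object@abundance)))
    msg <- c(msg, "duplicate transcript ids in abundance")
  if (any(object@abundance < 0) || anyNA(object@abundance))
    msg <- c(msg, "abundances must be non-negative and non-missing")
  if (!object@unit %in% c("counts", "TPM"))
    msg <- c(msg, "unit must be 'counts' or 'TPM'")
  if (!is.null(object@bootstrap)) {
    if (!identical(sort(rownames(object@bootstrap)),
                   sort(names(object@abundance))))
      msg <- c(msg, "bootstrap transcript set must equal abundance transcript set")
    if (any(object@bootstrap < 0) || anyNA(object@bootstrap))
      msg <- c(msg, "bootstrap values must be non-negative and non-missing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReplicateQuant
#'
#' @param sampleId sample identifier.
#' @param abundance named numeric vector of per-transcript abundances.
#' @param bootstrap optional transcripts x iterations matrix; rownames must
#'   match `names(abundance)` (any order).
#' @param unit `"counts"` (default) or `"TPM"`.
#' @return A [ReplicateQuant-class] object.
#' @examples
#' rq <- ReplicateQuant("s1", c(t1 = 10, t2 = 5))
#' abundanceOf(rq)
#' @export
ReplicateQuant <- function(sampleId, abundance, bootstrap = NULL,
                           unit = "counts") {
  if (!is.null(bootstrap)) {
    bootstrap <- as.matrix(bootstrap)
    if (is.null(rownames(bootstrap)))
      stop("bootstrap matrix must have transcript rownames")
    bootstrap <- bootstrap[names(abundance), , drop = FALSE]
  }
  new("ReplicateQuant", sampleId = sampleId,
      abundance = abundance, bootstrap = bootstrap, unit = unit)
}

#' Two-condition bootstrapped DTU experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding the transcript
#' count matrix (assay `"counts"`, transcripts x samples), the condition of
#' each sample in `colData(x)$condition` (a factor with exactly two levels),
#' the transcript-to-gene map in `rowData(x)$gene_id`, and per-sample
#' bootstrap matrices in the `bootstraps` slot (possibly empty).
#'
#' @slot bootstraps a [S4Vectors::SimpleList] of transcripts x iterations
#'   matrices, named by sample; samples without bootstraps are simply absent.
#'
#' @aliases DTUExperiment-class
#' @exportClass DTUExperiment
setClass("DTUExperiment",
  contains = "SummarizedExperiment",
  representation(bootstraps = "SimpleList")
)

setValidity("DTUExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  cd <- colData(object)
  if (!"condition" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else {
    cond <- cd$condition
    if (!is.factor(cond) || nlevels(cond) != 2L)
      msg <- c(msg, "condition must be a factor with exactly 2 levels")
    else if (any(table(cond) < 1L))
      msg <- c(msg, "each condition needs at least one replicate")
  }
  if (!"gene_id" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'gene_id'")
  else if (anyNA(rowData(object)$gene_id) ||
           any(!nzchar(rowData(object)$gene_id)))
    msg <- c(msg, "gene_id must be non-empty for every transcript")
  if (is.null(rownames(object)))
    msg <- c(msg, "transcript rownames are required")
  cnt <- assay(object, "counts")
  if (anyNA(cnt) || any(cnt < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  bs <- object@bootstraps
  if (length(bs)) {
    if (is.null(names(bs)) || !all(names(bs) %in% colnames(object)))
      msg <- c(msg, "bootstraps must be named by sample")
    for (nm in names(bs)) {
      m <- bs[[nm]]
      if (!is.matrix(m) || nrow(m) != nrow(object) ||
          !identical(rownames(m), rownames(object)))
        msg <- c(msg, sprintf("bootstrap matrix for '%s' must share the transcript universe", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' DTU calling results
#'
#' Container for the output of [callDTU()]: gene-level and transcript-level
#' result tables, the eligibility table, the isoform-switch list, and the run
#' configuration (provenance).
#'
#' @slot geneResults data.frame of per-gene statistics and calls.
#' @slot txResults data.frame of per-transcript statistics and calls.
#' @slot eligibility data.frame with one row per feature (gene and
#'   transcript) giving eligibility and the first failing reason.
#' @slot switches data.frame of genes whose dominant isoform differs between
#'   conditions.
#' @slot config list of all thresholds and seeds used (recorded verbatim).
#'
#' @aliases DTUResult-class
#' @exportClass DTUResult
setClass("DTUResult",
  representation(
    geneResults = "data.frame",
    txResults = "data.frame",
    eligibility = "data.frame",
    switches = "data.frame",
    config = "list"
  )
)

setValidity("DTUResult", function(object) {
  msg <- character()
  g <- object@geneResults
  if (nrow(g) && any(g$dtu_call & g$rejection_cause != "none", na.rm = TRUE))
    msg <- c(msg, "positive gene calls must have rejection_cause 'none'")
  tx <- object@txResults
  if (nrow(tx) && any(tx$dtu_call & tx$rejection_cause != "none", na.rm = TRUE))
    msg <- c(msg, "positive transcript calls must have rejection_cause 'none'")
  if (length(msg)) msg else TRUE
})
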