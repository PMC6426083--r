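#' @rdname ReplicateQuant
#' @param x a `ReplicateQuant` or `DTUExperiment`.
#' @export
setGeneric("abundanceOf", function(x) standardGeneric("abundanceOf"))

#' @rdname DTUExperiment
#' @param x object.
#' @export
setGeneric("bootstraps", function(x) standardGeneric("bootstraps"))

#' @rdname DTUExperiment
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname DTUExperiment
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname DTUResult
#' @param x a `DTUResult`.
#' @export
setGeneric("geneResults", function(x) standardGeneric("geneResults"))

#' @rdname DTUResult
#' @export
setGeneric("txResults", function(x) standardGeneric("txResults"))

#' @rdname DTUResult
#' @export
setGeneric("eligibility", function(x) standardGeneric("eligibility"))

#' @rdname DTUResult
#' @export
setGeneric("switchList", function(x) standardGeneric("switchList"))

#' @rdname DTUResult
#' @export
setGeneric("runConfig", function(x) standardGeneric("runConfig"))

setMethod("abundanceOf", "ReplicateQuant", function(x) x@abundance)

setMethod("bootstraps", "ReplicateQuant", function(x) x@bootstrap)

setMethod("bootstraps", "DTUExperiment", function(x) x@bootstraps)

setMethod("conditions", "DTUExperiment", function(x)
  colData(x)$condition)

setMethod("geneIds", "DTUExperiment", function(x) {
  g <- as.character(rowData(x)$gene_id)
  names(g) <- rownames(x)
  g
})

setMethod("geneResults", "DTUResult", function(x) x@geneResults)
setMethod("txResults", "DTUResult", function(x) x@txResults)
setMethod("eligibility", "DTUResult", function(x) x@eligibility)
setMethod("switchList", "DTUResult", function(x) x@switches)
setMethod("runConfig", "DTUResult", function(x) x@config)

setMethod("show", "ReplicateQuant", function(object) {
  cat("ReplicateQuant '", object@sampleId, "': ",
      length(object@abundance), " transcripts (", object@unit, ")",
      if (!is.null(object@bootstrap))
        paste0(", ", ncol(object@bootstrap), " bootstrap iterations"),
      "\n", sep = "")
})

setMethod("show", "DTUExperiment", function(object) {
  tab <- table(conditions(object))
  cat("DTUExperiment: ", nrow(object), " transcripts, ",
      length(unique(rowData(object)$gene_id)), " genes\n", sep = "")
  cat("  conditions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  nb <- length(object@bootstraps)
  cat("  bootstraps: ",
      if (nb) paste0(nb, "/", ncol(object), " samples") else "none",
      "\n", sep = "")
})

setMethod("show", "DTUResult", function(object) {
  g <- object@geneResults
  tx <- object@txResults
  cat("DTUResult\n")
  cat(sprintf("  genes:       %d tested of %d, %d called DTU\n",
              sum(g$eligible), nrow(g), sum(g$dtu_call)))
  cat(sprintf("  transcripts: %d tested of %d, %d called DTU\n",
              sum(tx$eligible), nrow(tx), sum(tx$dtu_call)))
  cat(sprintf("  thresholds: alpha=%g dprop=%g qrep=%g rrep=%g abundance=%g\n",
              object@config$alpha, object@config$dpropThreshold,
              object@config$qrepThreshold, object@config$rrepThreshold,
              object@config$abundanceThreshold))
})
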