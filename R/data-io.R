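#' @importFrom data.table fread fwrite
#' @importFrom utils head
NULL

# -- annotation ---------------------------------------------------------------

.validateAnnotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("transcript_id", "gene_id") %in% colnames(ann)))
  ann$transcript_id <- as.character(ann$transcript_id)
  ann$gene_id <- as.character(ann$gene_id)
  if (any(!nzchar(ann$transcript_id)) || any(!nzchar(ann$gene_id)) ||
      anyNA(ann$transcript_id) || anyNA(ann$gene_id))
    stop("annotation contains empty identifiers")
  ann <- unique(ann[, c("transcript_id", "gene_id")])
  dup <- ann$transcript_id[duplicated(ann$transcript_id)]
  if (length(dup))
    stop("conflicting gene for ", paste(unique(dup), collapse = ", "))
  rownames(ann) <- NULL
  ann
}

#' Read a transcript-to-gene map from a TSV file
#'
#' The file must have a header row; the transcript and gene columns are found
#' by name (case-insensitive match against common conventions such as
#' `transcript_id`/`target_id` and `gene_id`/`parent`) or can be named
#' explicitly. Each transcript must map to exactly one gene.
#'
#' @param path path to a tab-separated file with >= 2 named columns.
#' @param transcriptCol,geneCol optional explicit column names.
#' @return data.frame with columns `transcript_id` and `gene_id`, one row per
#'   unique transcript.
#' @export
readAnnotationTSV <- function(path, transcriptCol = NULL, geneCol = NULL) {
  tab <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                             colClasses = "character"))
  findCol <- function(given, patterns, what) {
    if (!is.null(given)) {
      if (!given %in% colnames(tab))
        stop(sprintf("column '%s' not found; file has: %s",
                     given, paste(colnames(tab), collapse = ", ")))
      return(given)
    }
    hit <- grep(patterns, colnames(tab), ignore.case = TRUE, value = TRUE)
    if (!length(hit))
      stop(sprintf(
        "no %s id column found; expected a header matching '%s', file has: %s",
        what, patterns, paste(colnames(tab), collapse = ", ")))
    hit[1L]
  }
  tc <- findCol(transcriptCol, "transcript|target_id|^tx", "transcript")
  gc <- findCol(geneCol, "gene|parent", "gene")
  .validateAnnotation(data.frame(transcript_id = tab[[tc]],
                                 gene_id = tab[[gc]]))
}

#' Read a transcript-to-gene map from GTF attributes
#'
#' Only the `transcript_id` and `gene_id` attributes of `transcript` and
#' `exon` features are used; coordinates are never interpreted. Features
#' lacking a `transcript_id` attribute (e.g. gene lines) are ignored.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `transcript_id` and `gene_id`.
#' @export
readAnnotationGTF <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("failed to parse GTF '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (!all(c("transcript_id", "gene_id") %in% colnames(md)))
    stop("GTF lacks transcript_id/gene_id attributes")
  if ("type" %in% colnames(md))
    md <- md[as.character(md$type) %in% c("transcript", "exon"), , drop = FALSE]
  md <- md[!is.na(md$transcript_id) & !is.na(md$gene_id), , drop = FALSE]
  if (!nrow(md))
    stop("no transcript_id-bearing features found in '", path, "'")
  .validateAnnotation(data.frame(transcript_id = md$transcript_id,
                                 gene_id = md$gene_id))
}

# -- quantifications ----------------------------------------------------------

#' Read a Salmon quantification
#'
#' Parses a `quant.sf` table (columns `Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`). By default the estimated read counts (`NumReads`)
#' become the abundances; set `abundance = "TPM"` for the length-normalised
#' view (scale with [scaleTpmToCounts()] before testing). A bootstrap matrix
#' can be attached from a companion plain-TSV table
#' (see [readBootstrapTSV()]).
#'
#' @param path a `quant.sf` file or the Salmon output directory containing it.
#' @param sampleId sample identifier; defaults to the directory name.
#' @param abundance which column to use as the abundance, `"counts"`
#'   (NumReads) or `"TPM"`.
#' @param bootstrapPath optional path to a bootstrap TSV
#'   (transcripts x iterations).
#' @return A [ReplicateQuant-class].
#' @export
readSalmonQuant <- function(path, sampleId = NULL,
                            abundance = c("counts", "TPM"),
                            bootstrapPath = NULL) {
  abundance <- match.arg(abundance)
  file <- if (dir.exists(path)) file.path(path, "quant.sf") else path
  if (!file.exists(file)) stop("no quant.sf at '", path, "'")
  tab <- as.data.frame(fread(file, sep = "\t", header = TRUE))
  expected <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  if (!all(expected %in% colnames(tab)))
    stop("quant.sf header mismatch; found: ",
         paste(colnames(tab), collapse = ", "),
         "; expected: ", paste(expected, collapse = ", "))
  if (is.null(sampleId))
    sampleId <- basename(dirname(normalizePath(file)))
  vals <- if (abundance == "counts") tab$NumReads else tab$TPM
  names(vals) <- as.character(tab$Name)
  bs <- if (!is.null(bootstrapPath)) readBootstrapTSV(bootstrapPath)
  ReplicateQuant(sampleId, vals, bootstrap = bs,
                 unit = if (abundance == "counts") "counts" else "TPM")
}

#' Read a generic bootstrap matrix TSV
#'
#' First column: transcript id; remaining columns: one quantification
#' iteration each.
#'
#' @param path path to the TSV.
#' @return numeric matrix, transcripts x iterations, with transcript rownames.
#' @export
readBootstrapTSV <- function(path) {
  tab <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  if (ncol(tab) < 2L) stop("bootstrap TSV needs an id column plus iterations")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Read a Kallisto HDF5 quantification
#'
#' Reads `abundance.h5` (estimated counts in `/est_counts`, transcript ids in
#' `/aux/ids`, bootstrap vectors under `/bootstrap/bs*`). HDF5 decoding is
#' delegated to a Python interpreter with `h5py` on the PATH; an informative
#' error is raised when none is available.
#'
#' @param path path to an `abundance.h5` file.
#' @param sampleId sample identifier; defaults to the directory name.
#' @return A [ReplicateQuant-class] with a bootstrap matrix when the file
#'   carries bootstrap vectors.
#' @export
readKallistoH5 <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("no file at '", path, "'")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("readKallistoH5 requires a 'python' with h5py on the PATH")
  script <- system.file("scripts", "kallisto_h5_dump.py", package = "bootDTU")
  if (!nzchar(script)) stop("bundled HDF5 dump script not found")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  status <- system2(py, c(script, shQuote(path), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L)
    stop("HDF5 read failed for '", path, "': ",
         paste(status, collapse = " "))
  tab <- as.data.frame(fread(out, sep = "\t", header = TRUE))
  if (!nrow(tab)) stop("zero transcripts in '", path, "'")
  if (is.null(sampleId))
    sampleId <- basename(dirname(normalizePath(path)))
  vals <- as.numeric(tab$est_counts)
  names(vals) <- as.character(tab$target_id)
  bsCols <- grep("^bs", colnames(tab), value = TRUE)
  bs <- NULL
  if (length(bsCols)) {
    bs <- as.matrix(tab[, bsCols, drop = FALSE])
    mode(bs) <- "numeric"
    rownames(bs) <- names(vals)
  }
  ReplicateQuant(sampleId, vals, bootstrap = bs, unit = "counts")
}

#' Scale TPM abundances to pseudo-counts
#'
#' Multiplies every point and bootstrap value by `librarySize / 1e6`, turning
#' transcripts-per-million into count-scale values (not rounded to integers).
#' Count-based tests are under-powered on raw TPM, so length-normalised
#' abundances should be rescaled to a typical library size before testing.
#'
#' @param quant a [ReplicateQuant-class] with `unit == "TPM"`.
#' @param librarySize positive number of reads (e.g. `25e6`).
#' @return A [ReplicateQuant-class] in counts.
#' @export
scaleTpmToCounts <- function(quant, librarySize) {
  stopifnot(is(quant, "ReplicateQuant"))
  if (quant@unit != "TPM") stop("quant is not in TPM")
  if (length(librarySize) != 1L || is.na(librarySize) || librarySize <= 0)
    stop("librarySize must be a positive number")
  f <- librarySize / 1e6
  bs <- quant@bootstrap
  if (!is.null(bs)) bs <- bs * f
  ReplicateQuant(quant@sampleId, quant@abundance * f, bootstrap = bs,
                 unit = "counts")
}

# -- experiment assembly ------------------------------------------------------

#' Assemble a two-condition DTU experiment
#'
#' Combines per-replicate quantifications and the annotation into a
#' [DTUExperiment-class]. All replicates must be in counts and share one
#' transcript universe. Transcripts absent from the annotation are dropped
#' with a message (the count is kept in `metadata(x)$n_unannotated_dropped`);
#' silent identifier munging is never performed, so ids must match exactly.
#'
#' @param conditionA,conditionB lists of [ReplicateQuant-class] objects.
#' @param annotation data.frame with `transcript_id` and `gene_id` columns.
#' @param conditionNames length-2 character, labels of the two conditions.
#' @return A [DTUExperiment-class].
#' @export
buildExperiment <- function(conditionA, conditionB, annotation,
                            conditionNames = c("A", "B")) {
  if (is(conditionA, "ReplicateQuant")) conditionA <- list(conditionA)
  if (is(conditionB, "ReplicateQuant")) conditionB <- list(conditionB)
  reps <- c(conditionA, conditionB)
  if (length(conditionA) < 1L || length(conditionB) < 1L)
    stop("each condition needs at least one replicate")
  if (!all(vapply(reps, is, logical(1), "ReplicateQuant")))
    stop("replicates must be ReplicateQuant objects")
  units <- vapply(reps, function(r) r@unit, character(1))
  if (any(units != "counts"))
    stop("all replicates must be in counts; use scaleTpmToCounts() on TPM data")
  ann <- .validateAnnotation(annotation)
  universe <- sort(names(reps[[1L]]@abundance))
  for (r in reps[-1L])
    if (!identical(sort(names(r@abundance)), universe))
      stop("replicate '", r@sampleId,
           "' has a different transcript universe")
  annotated <- universe %in% ann$transcript_id
  nDropped <- sum(!annotated)
  if (nDropped)
    message(nDropped, " quantified transcript(s) absent from the annotation; dropped")
  universe <- universe[annotated]
  if (!length(universe)) stop("no quantified transcript is annotated")
  ids <- vapply(reps, function(r) r@sampleId, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  counts <- vapply(reps, function(r) r@abundance[universe], numeric(length(universe)))
  dimnames(counts) <- list(universe, ids)
  gmap <- ann$gene_id[match(universe, ann$transcript_id)]
  cond <- factor(rep(conditionNames, c(length(conditionA), length(conditionB))),
                 levels = conditionNames)
  bs <- list()
  for (r in reps)
    if (!is.null(r@bootstrap))
      bs[[r@sampleId]] <- r@bootstrap[universe, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_id = gmap, row.names = universe),
    colData = DataFrame(condition = cond, row.names = ids))
  obj <- new("DTUExperiment", se, bootstraps = as(bs, "SimpleList"))
  metadata(obj)$n_unannotated_dropped <- nDropped
  validObject(obj)
  obj
}

#' Extract the replicates of one condition as ReplicateQuant objects
#'
#' @param x a [DTUExperiment-class].
#' @param condition one of the two condition labels.
#' @return list of [ReplicateQuant-class], with bootstraps where present.
#' @export
pullReplicates <- function(x, condition) {
  stopifnot(is(x, "DTUExperiment"))
  keep <- colnames(x)[conditions(x) == condition]
  if (!length(keep)) stop("unknown condition '", condition, "'")
  cnt <- assay(x, "counts")
  bs <- bootstraps(x)
  lapply(keep, function(s)
    ReplicateQuant(s, cnt[, s],
                   bootstrap = if (s %in% names(bs)) bs[[s]],
                   unit = "counts"))
}

# -- fixture writers ----------------------------------------------------------

#' Write a replicate in the Salmon quant.sf dialect
#'
#' Emits `Name Length EffectiveLength TPM NumReads` with fabricated lengths
#' (all transcripts length 1000, effective length 800) since only ids and
#' abundances are meaningful for testing; TPM is derived from the counts
#' assuming equal effective lengths.
#'
#' @param quant a [ReplicateQuant-class] in counts.
#' @param dir output directory (created if needed); `quant.sf` is written
#'   inside it.
#' @return path to the written `quant.sf`, invisibly.
#' @export
writeSalmonQuant <- function(quant, dir) {
  stopifnot(is(quant, "ReplicateQuant"), quant@unit == "counts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cnt <- quant@abundance
  tot <- sum(cnt)
  tpm <- if (tot > 0) cnt / tot * 1e6 else cnt * 0
  tab <- data.frame(Name = names(cnt), Length = 1000L,
                    EffectiveLength = 800, TPM = tpm, NumReads = cnt)
  out <- file.path(dir, "quant.sf")
  fwrite(tab, out, sep = "\t")
  invisible(out)
}

#' Write a bootstrap matrix in the generic TSV dialect
#'
#' @param quant a [ReplicateQuant-class] carrying a bootstrap matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBootstrapTSV <- function(quant, path) {
  stopifnot(is(quant, "ReplicateQuant"))
  if (is.null(quant@bootstrap)) stop("replicate has no bootstrap matrix")
  bs <- quant@bootstrap
  tab <- data.frame(transcript_id = rownames(bs), as.data.frame(bs),
                    check.names = FALSE)
  colnames(tab) <- c("transcript_id", paste0("iter", seq_len(ncol(bs))))
  fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Write an annotation map as a two-column TSV
#'
#' @param annotation data.frame with `transcript_id`, `gene_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTSV <- function(annotation, path) {
  ann <- .validateAnnotation(annotation)
  fwrite(ann[, c("transcript_id", "gene_id")], path, sep = "\t")
  invisible(path)
}

#' Write an annotation map as a minimal GTF
#'
#' One exon feature per transcript with fabricated coordinates; only the
#' `gene_id` and `transcript_id` attributes are meaningful.
#'
#' @param annotation data.frame with `transcript_id`, `gene_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGTF <- function(annotation, path) {
  ann <- .validateAnnotation(annotation)
  n <- nrow(ann)
  start <- seq_len(n) * 2000L
  lines <- sprintf(
    'chr1\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
    start, start + 999L, ann$gene_id, ann$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
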