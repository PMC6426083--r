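#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom rlang .data
#' @import ggplot2
NULL

.logStage <- function(stage, nIn, nOut) {
  message(sprintf("[bootDTU] %s: in=%d out=%d", stage, nIn, nOut))
}

.checksumExperiment <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(assay(x, "counts"), as.character(rowData(x)$gene_id),
               as.character(conditions(x))), tmp)
  unname(md5sum(tmp))
}

.causeTally <- function(tab) {
  tested <- tab[tab$eligible, , drop = FALSE]
  c(table(factor(tested$rejection_cause,
                 levels = c("none", "not_significant", "small_effect",
                            "low_quant_reproducibility",
                            "low_replicate_reproducibility"))))
}

#' Run the DTU pipeline and write the output bundle
#'
#' Calls [callDTU()] and writes, under `outDir`: `genes.tsv`,
#' `transcripts.tsv`, `eligibility.tsv`, `switches.tsv`, a human-readable
#' `summary.txt` (tested/called counts and a tally of rejection causes per
#' level), and `provenance.json` (full configuration, input checksum, seed).
#' Reruns with identical inputs, config and seed are byte-identical.
#'
#' @param x a [DTUExperiment-class].
#' @param config a [dtuConfig()] list.
#' @param outDir output directory, created if needed.
#' @return the [DTUResult-class], invisibly.
#' @export
runDTU <- function(x, config = dtuConfig(), outDir) {
  stopifnot(is(x, "DTUExperiment"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- callDTU(x, config)
  g <- geneResults(res)
  tx <- txResults(res)
  .logStage("genes", nrow(g), sum(g$dtu_call))
  .logStage("transcripts", nrow(tx), sum(tx$dtu_call))
  data.table::fwrite(g, file.path(outDir, "genes.tsv"), sep = "\t")
  data.table::fwrite(tx, file.path(outDir, "transcripts.tsv"), sep = "\t")
  data.table::fwrite(eligibility(res), file.path(outDir, "eligibility.tsv"),
                     sep = "\t")
  data.table::fwrite(switchList(res), file.path(outDir, "switches.tsv"),
                     sep = "\t")

  lines <- c(
    sprintf("genes: %d in universe, %d tested, %d called DTU",
            nrow(g), sum(g$eligible), sum(g$dtu_call)),
    sprintf("transcripts: %d in universe, %d tested, %d called DTU",
            nrow(tx), sum(tx$eligible), sum(tx$dtu_call)),
    sprintf("isoform switches: %d genes", nrow(switchList(res))),
    "rejection causes among tested genes:",
    sprintf("  %s: %d", names(.causeTally(g)), .causeTally(g)),
    "rejection causes among tested transcripts:",
    sprintf("  %s: %d", names(.causeTally(tx)), .causeTally(tx)))
  writeLines(lines, file.path(outDir, "summary.txt"))

  prov <- runConfig(res)
  prov$input_checksum <- .checksumExperiment(x)
  prov$n_transcripts <- nrow(x)
  prov$n_genes <- nrow(g)
  prov$n_unannotated_dropped <- metadata(x)$n_unannotated_dropped
  write_json(prov, file.path(outDir, "provenance.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Threshold-sweep benchmark against an injected truth set
#'
#' Runs the caller across a grid of effect-size and reproducibility
#' thresholds and scores each combination against the truth set. The effect
#' threshold changes the per-draw classification inside the reproducibility
#' filters, so each `dprop` value triggers a full re-run; the
#' reproducibility thresholds are post-hoc screens re-applied to the stored
#' fractions.
#'
#' @param x a [DTUExperiment-class].
#' @param truth truth set (see [scoreAgainstTruth()]).
#' @param config base [dtuConfig()].
#' @param dpropGrid effect-size thresholds to sweep.
#' @param qrepGrid,rrepGrid reproducibility thresholds to sweep (ignored,
#'   with a single `NA` row each, when the respective filter is off or its
#'   scores are absent).
#' @param level `"gene"` or `"transcript"`.
#' @return data.frame with one row per threshold combination:
#'   `dprop`, `qrep`, `rrep`, `n_calls`, `sensitivity`, `fdr`, `mcc`.
#' @export
runBenchmark <- function(x, truth, config = dtuConfig(),
                         dpropGrid = c(0.05, 0.1, 0.2),
                         qrepGrid = c(0.8, 0.85, 0.9, 0.95),
                         rrepGrid = c(0.55, 0.65, 0.75, 0.85),
                         level = c("gene", "transcript")) {
  level <- match.arg(level)
  rows <- list()
  for (dp in dpropGrid) {
    cfg <- config
    cfg$dpropThreshold <- dp
    res <- callDTU(x, cfg)
    tab <- if (level == "gene") geneResults(res) else txResults(res)
    qGrid <- if (all(is.na(tab$qrep_fraction))) NA_real_ else qrepGrid
    rGrid <- if (all(is.na(tab$rrep_fraction))) NA_real_ else rrepGrid
    for (q in qGrid) for (r in rGrid) {
      res2 <- applyReproducibilityFilters(
        res,
        qrepThreshold = if (is.na(q)) 0 else q,
        rrepThreshold = if (is.na(r)) 0 else r)
      sc <- scoreAgainstTruth(res2, truth, level)
      tab2 <- if (level == "gene") geneResults(res2) else txResults(res2)
      rows[[length(rows) + 1L]] <- data.frame(
        dprop = dp, qrep = q, rrep = r,
        n_calls = sum(tab2$dtu_call),
        sensitivity = sc$sensitivity, fdr = sc$fdr, mcc = sc$mcc)
    }
  }
  do.call(rbind, rows)
}

#' Plot per-replicate isoform proportions for one gene
#'
#' Grouped bars of the mean isoform proportion per condition with the
#' individual replicates overplotted; each replicate's proportions sum to 1.
#'
#' @param x a [DTUExperiment-class].
#' @param geneId gene to plot.
#' @param file optional output path (png/pdf/svg by extension); when given,
#'   the plot is also written there.
#' @return the ggplot object, invisibly.
#' @export
plotGeneProportions <- function(x, geneId, file = NULL) {
  stopifnot(is(x, "DTUExperiment"))
  sel <- as.character(rowData(x)$gene_id) == geneId
  if (!any(sel)) stop("unknown gene '", geneId, "'")
  cnt <- assay(x, "counts")[sel, , drop = FALSE]
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("gene '", geneId, "' has zero expression in a replicate")
  prop <- sweep(cnt, 2L, tot, "/")
  df <- data.frame(
    transcript = rep(rownames(prop), ncol(prop)),
    sample = rep(colnames(prop), each = nrow(prop)),
    condition = rep(as.character(conditions(x)), each = nrow(prop)),
    proportion = as.vector(prop))
  p <- ggplot(df, aes(x = .data$transcript, y = .data$proportion,
                      fill = .data$condition)) +
    stat_summary(fun = mean, geom = "bar",
                 position = position_dodge(width = 0.9), width = 0.8) +
    geom_point(position = position_dodge(width = 0.9), shape = 21) +
    labs(title = geneId, x = NULL, y = "isoform proportion") +
    ylim(0, 1) +
    theme_minimal()
  if (!is.null(file)) ggsave(file, p, width = 5, height = 4, dpi = 120)
  invisible(p)
}
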