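#' @importFrom stats pchisq p.adjust
NULL

#' G-test of independence
#'
#' Likelihood-ratio test of independence on a contingency table,
#' `G = 2 * sum(O * ln(O / E))` with expectations from the row and column
#' marginals, no continuity correction, and zero cells contributing zero.
#' Rows whose total is zero are dropped before computing the degrees of
#' freedom `(rows - 1) * (cols - 1)`; the p-value is the upper chi-squared
#' tail. Cell values may be non-integer (e.g. after TPM scaling).
#'
#' @param observed numeric matrix of non-negative observed values with at
#'   least 2 rows and 2 columns.
#' @return list with `g_statistic`, `df` and `p_value`.
#' @examples
#' gTest(matrix(c(100, 0, 0, 100), 2))  # G = 400 * log(2)
#' @export
gTest <- function(observed) {
  m <- as.matrix(observed)
  mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0)) stop("observed values must be non-negative")
  if (ncol(m) < 2L) stop("need at least 2 columns")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("degenerate table: fewer than 2 nonzero rows")
  cs <- colSums(m)
  if (any(cs == 0)) stop("degenerate table: a column sums to zero")
  rs <- rowSums(m)
  n <- sum(rs)
  e <- outer(rs, cs) / n
  term <- ifelse(m > 0, m * log(m / e), 0)
  g <- 2 * sum(term)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(g_statistic = g, df = df,
       p_value = pchisq(g, df, lower.tail = FALSE))
}

#' Gene-level DTU test
#'
#' Applies the G-test to a gene's isoforms x conditions table of
#' replicate-summed counts: a significant result means the gene's isoform
#' abundance ratios differ between the two conditions.
#'
#' @param geneCounts numeric matrix, isoforms x 2 conditions, of
#'   replicate-summed counts.
#' @return list with `g_statistic`, `df` and `p_value`; all `NA` (with a
#'   warning suppressed into the eligibility machinery when used through
#'   [callDTU()]) if the table is degenerate.
#' @export
geneLevelTest <- function(geneCounts) {
  tryCatch(gTest(geneCounts),
           error = function(e)
             list(g_statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_))
}

#' Transcript-level DTU test
#'
#' Tests one transcript against the pooled abundance of its sibling isoforms:
#' the 2x2 table `[[target_a, target_b], [siblings_a, siblings_b]]` under the
#' G-test with one degree of freedom.
#'
#' @param target length-2 numeric, the transcript's replicate-summed counts
#'   in conditions A and B.
#' @param siblings length-2 numeric, the pooled counts of the gene's other
#'   isoforms.
#' @return list with `g_statistic`, `df` and `p_value` (all `NA` when
#'   degenerate).
#' @export
transcriptLevelTest <- function(target, siblings) {
  stopifnot(length(target) == 2L, length(siblings) == 2L)
  geneLevelTest(rbind(target = target, siblings = siblings))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(pValues) {
  if (anyNA(pValues) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

# Vectorised G-test machinery used by the calling pipeline. `sumA`/`sumB` are
# per-transcript replicate-summed counts, `gi` maps transcripts to gene index
# 1..nG. Returns per-gene and per-transcript statistics in one pass; all-zero
# isoform rows are excluded from the df, genes left with < 2 nonzero rows are
# flagged degenerate.
.gStatVec <- function(sumA, sumB, gi, nG) {
  gs <- rowsum(cbind(sumA, sumB), gi)      # nG x 2, rows in index order
  gA <- gs[, 1L]; gB <- gs[, 2L]
  n <- gA + gB
  rowTot <- sumA + sumB
  gAi <- gA[gi]; gBi <- gB[gi]; ni <- n[gi]
  eA <- rowTot * gAi / ni
  eB <- rowTot * gBi / ni
  termA <- ifelse(sumA > 0, sumA * log(sumA / eA), 0)
  termB <- ifelse(sumB > 0, sumB * log(sumB / eB), 0)
  gStat <- 2 * rowsum(termA + termB, gi)[, 1L]
  nz <- rowsum((rowTot > 0) + 0, gi)[, 1L]
  degenerate <- nz < 2 | gA == 0 | gB == 0
  df <- pmax(nz - 1, 1)
  pG <- pchisq(gStat, df, lower.tail = FALSE)
  gStat[degenerate] <- NA_real_
  pG[degenerate] <- NA_real_
  df[degenerate] <- NA_real_

  # transcript vs pooled siblings, 2x2, df = 1
  sa <- gAi - sumA
  sb <- gBi - sumB
  sibTot <- sa + sb
  e11 <- rowTot * gAi / ni; e12 <- rowTot * gBi / ni
  e21 <- sibTot * gAi / ni; e22 <- sibTot * gBi / ni
  t11 <- ifelse(sumA > 0, sumA * log(sumA / e11), 0)
  t12 <- ifelse(sumB > 0, sumB * log(sumB / e12), 0)
  t21 <- ifelse(sa > 0, sa * log(sa / e21), 0)
  t22 <- ifelse(sb > 0, sb * log(sb / e22), 0)
  gTx <- 2 * (t11 + t12 + t21 + t22)
  txDegen <- rowTot == 0 | sibTot == 0 | gA[gi] == 0 | gB[gi] == 0
  pTx <- pchisq(gTx, 1, lower.tail = FALSE)
  gTx[txDegen] <- NA_real_
  pTx[txDegen] <- NA_real_

  list(geneG = gStat, geneDf = df, geneP = pG, geneDegenerate = degenerate,
       geneSumA = gA, geneSumB = gB, nNonzeroRows = nz,
       txG = gTx, txP = pTx, txDegenerate = txDegen)
}
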