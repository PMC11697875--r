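# Motif-conditioned differential gene expression: the delta-median
# statistic and its exact combinatorial tail probability.

#' Delta median expression
#'
#' Median expression of a gene among the cells of one type that occupy a
#' motif position, minus the median across all cells of that type.
#'
#' @param exprMotif expression values of the motif-subset cells
#' @param exprAll expression values of all cells of the type
#' @return numeric delta median
#' @export
deltaMedian <- function(exprMotif, exprAll) {
  if (!length(exprMotif)) stop("empty motif subset")
  if (!length(exprAll)) stop("empty cell-type population")
  stats::median(exprMotif) - stats::median(exprAll)
}

#' Exact tail probability of a delta median
#'
#' Under random selection of \code{nAM} of the \code{nA} cells of a type,
#' the probability that the subset's median exceeds the observed shift is
#' the probability that at least \code{N0 = floor(nAM/2 + 1)} of the
#' selected cells have delta expression above \code{x0}:
#' \deqn{p_0 = \sum_{k=N_0}^{N_{AM}} \binom{N_H}{k} \binom{N_L}{N_{AM}-k}
#'       / \binom{N_A}{N_{AM}}}
#' where \code{nH} cells lie above the shift and \code{nL = nA - nH} at or
#' below it (ties count toward \code{nL}). For a negative shift the
#' mirrored lower tail (at most \code{nAM - N0} cells above) is used.
#'
#' @param nH number of cells with delta expression above x0
#' @param nL number of cells at or below x0 (\code{nH + nL = nA})
#' @param nAM motif-subset size (<= nA)
#' @param tail "upper" (default; positive shifts) or "lower"
#' @param logBase 10 (default) or "e"
#' @return log p-value (<= 0)
#' @examples
#' # nA = 4, nAM = 2, nH = nL = 2: p = C(2,2) C(2,0) / C(4,2) = 1/6
#' exp(dmedianLogPvalue(2, 2, 2) * log(10))
#' @export
dmedianLogPvalue <- function(nH, nL, nAM, tail = c("upper", "lower"),
                             logBase = 10) {
  tail <- match.arg(tail)
  nA <- nH + nL
  if (nAM > nA) stop("motif subset larger than the cell-type population")
  if (nAM < 1) stop("empty motif subset")
  n0 <- floor(nAM / 2 + 1)
  lp <- if (tail == "upper")
    stats::phyper(n0 - 1, nH, nL, nAM, lower.tail = FALSE, log.p = TRUE)
  else
    stats::phyper(nAM - n0, nH, nL, nAM, lower.tail = TRUE, log.p = TRUE)
  lp / logBaseFactor(logBase)
}

#' Motif-conditioned differential expression analysis
#'
#' Treats each (motif, position, cell type) combination with at least
#' \code{minCells} member cells as a separate case and, for every gene,
#' reports the delta median and its signed log10 p-value
#' (\code{-sign(x0) * log10(p)}: positive = upregulated in the motif).
#' With \code{control = TRUE} the motif cells of each case are replaced by
#' a random subset of cells of the same type and size, giving the matched
#' null used to judge the specificity of significant cases.
#'
#' @param fit a \code{\link{SmoreFit}}
#' @param expr genes x cells matrix; columns ordered as the cells of the
#'   fitted sections, concatenated in section order. Rownames are gene
#'   identifiers.
#' @param minCells minimum motif-subset size per case (default 3)
#' @param control replace motif subsets by random same-type subsets
#' @param seed seed for the control draws
#' @return data.frame with columns motif, position, cell_type, gene, N_A,
#'   N_AM, delta_median, log10_p (signed), case ("motif-position-celltype"),
#'   and padj_BH (Benjamini-Hochberg adjusted two-sided p; supplementary
#'   output beyond the raw log p scale).
#' @export
analyzeMotifExpression <- function(fit, expr, minCells = 3L,
                                   control = FALSE, seed = 1L) {
  stopifnot(is(fit, "SmoreFit"))
  expr <- as.matrix(expr)
  labels <- globalLabels(lapply(fit@graphs, cellLabels))
  if (ncol(expr) != length(labels))
    stop("expression matrix must have one column per cell (",
         length(labels), " expected, got ", ncol(expr), ")")
  typeNames <- cellTypes(fit@graphs[[1L]])
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expr)))

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(deriveSeed(seed, "misc"))

  res <- list()
  for (m in fit@motifs) {
    for (j in seq_along(m@positionNodes)) {
      cellsJ <- m@positionNodes[[j]]
      if (!length(cellsJ)) next
      for (ty in sort(unique(labels[cellsJ]))) {
        if (ty == 0L) next
        sub <- cellsJ[labels[cellsJ] == ty]
        if (length(sub) < minCells) next
        allTy <- which(labels == ty)
        if (control)
          sub <- sample(allTy, length(sub))
        for (gi in seq_len(nrow(expr))) {
          xa <- expr[gi, allTy]
          if (anyNA(xa)) {
            warning("missing expression for gene ", genes[gi],
                    "; case skipped")
            next
          }
          xm <- expr[gi, sub]
          medAll <- stats::median(xa)
          x0 <- stats::median(xm) - medAll
          delta <- xa - medAll
          nH <- sum(delta > x0)
          nL <- length(xa) - nH
          lp <- dmedianLogPvalue(nH, nL, length(sub),
                                 tail = if (x0 < 0) "lower" else "upper")
          res[[length(res) + 1L]] <- data.frame(
            motif = m@rank, position = j, cell_type = typeNames[ty],
            gene = genes[gi], N_A = length(allTy), N_AM = length(sub),
            delta_median = x0,
            log10_p = if (x0 < 0) lp else -lp,
            case = paste(m@rank, j, typeNames[ty], sep = "-"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(motif = integer(0), position = integer(0),
               cell_type = character(0), gene = character(0),
               N_A = integer(0), N_AM = integer(0),
               delta_median = numeric(0), log10_p = numeric(0),
               case = character(0))
  out$padj_BH <- stats::p.adjust(10^(-abs(out$log10_p)), method = "BH")
  out
}

#' Upper-tail hypergeometric overlap probability of two gene sets
#'
#' Probability of observing at least \code{k} shared genes between sets of
#' sizes \code{n1} and \code{n2} drawn from a universe of \code{universe}
#' genes.
#'
#' @param k observed overlap
#' @param n1,n2 set sizes
#' @param universe universe size
#' @return p-value (linear scale)
#' @export
geneOverlapPvalue <- function(k, n1, n2, universe) {
  stopifnot(k >= 0, n1 <= universe, n2 <= universe)
  exp(stats::phyper(k - 1, n1, universe - n1, n2, lower.tail = FALSE,
                    log.p = TRUE))
}
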