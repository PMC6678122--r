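# Hypergeometric over-representation of annotation terms in a target gene
# set against the transcriptome background, with Benjamini-Hochberg FDR
# control applied separately within each annotation family (GO MF/BP/CC,
# KEGG).

#' Hypergeometric enrichment of a gene set
#'
#' For each term with at least `min_background` annotated background
#' genes, computes the upper-tail hypergeometric probability of observing
#' at least `k` annotated genes among the `n` target genes drawn from a
#' background of `N` genes of which `K` carry the term, i.e.
#' `P = P(X >= k)` with `X ~ Hypergeometric(K, N - K, n)`. BH adjustment
#' is applied within each category; terms with FDR at or below
#' `fdr_threshold` are flagged.
#'
#' @param genes character vector of target genes (must be a subset of
#'   `background`)
#' @param annotation data frame with columns `gene`, `term`, `name`,
#'   `category`
#' @param background character vector of all genes (the transcriptome)
#' @param fdr_threshold significance threshold on the BH-adjusted P
#' @param min_background minimum background genes per tested term
#' @return data frame sorted by FDR within category: term, name, category,
#'   k, n, K, N, p, fdr, significant
#' @export
enrich_terms <- function(genes, annotation, background,
                         fdr_threshold = 0.05, min_background = 2L) {
  stopifnot(all(c("gene", "term", "name", "category") %in% names(annotation)))
  genes <- unique(genes)
  background <- unique(background)
  if (!all(genes %in% background))
    stop("target genes must be a subset of the background")
  ann <- unique(annotation[annotation$gene %in% background,
                           c("gene", "term", "name", "category")])
  N <- length(background)
  n <- length(genes)
  rows <- list()
  for (cat in sort(unique(ann$category))) {
    sub <- ann[ann$category == cat, , drop = FALSE]
    for (tm in sort(unique(sub$term))) {
      tg <- sub$gene[sub$term == tm]
      K <- length(tg)
      if (K < min_background) {
        if (K == 0L) warning("term ", tm, " has no background genes; skipped")
        next
      }
      k <- sum(genes %in% tg)
      p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, name = sub$name[sub$term == tm][1L], category = cat,
        k = k, n = n, K = K, N = N, p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(term = character(0), name = character(0),
                      category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$fdr <- NA_real_
  for (cat in unique(res$category)) {
    i <- res$category == cat
    res$fdr[i] <- p.adjust(res$p[i], method = "BH")
  }
  res$significant <- res$fdr <= fdr_threshold
  res[order(res$category, res$fdr, res$p, res$term), , drop = FALSE]
}
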