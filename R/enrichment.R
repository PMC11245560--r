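#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over the standard step-up procedure: sorted
#' ascending, adjusted_i = min over j >= i of p_j * m / j, clipped at 1,
#' original order restored.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite numbers in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-sided hypergeometric over-representation test
#'
#' For each term with K annotated genes in a universe of N, of which n are
#' selected and k overlap the term, p = P(X >= k) under
#' Hypergeometric(N, K, n). P-values are BH-adjusted across all tested
#' terms; terms with no annotated genes in the universe are skipped.
#'
#' @param selection character vector of selected genes (subset of the
#'   universe).
#' @param annotation data frame (gene, term).
#' @param universe gene universe; defaults to all annotated genes.
#' @return an object of class `enrichment_table`: data frame (term, N, K,
#'   n, k, fold_enrichment, p, padj) ordered by p.
#' @export
hypergeom_enrich <- function(selection, annotation, universe = NULL) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  universe <- unique(universe %||% annotation$gene)
  if (!length(universe)) stop("empty universe")
  selection <- unique(selection)
  if (!length(selection)) stop("empty selection")
  if (!all(selection %in% universe))
    stop("selection must be a subset of the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(selection)
  Ktab <- table(ann$term)
  ktab <- table(ann$term[ann$gene %in% selection])
  terms <- names(Ktab)[Ktab > 0]
  K <- as.integer(Ktab[terms])
  k <- as.integer(ktab[terms]); k[is.na(k)] <- 0L
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, N = N, K = K, n = n, k = k,
                    fold_enrichment = (k / n) / (K / N),
                    p = p, padj = bh_adjust(p))
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
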