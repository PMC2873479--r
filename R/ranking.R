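#' Gene ranking container
#'
#' All scoring methods return a `GeneRanking`: the per-gene score vector,
#' the score direction (`"higher_better"` for SNR/t/LSD/RFGS/SVST,
#' `"lower_better"` for TNoM/MDMR/WEPO), and the best-first order with
#' ties broken by ascending gene index so rankings are deterministic.
#'
#' @param method Method tag (e.g. `"snr"`).
#' @param scores Numeric per-gene score vector.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param gene_ids Character vector of gene ids, same length as `scores`.
#' @param extra Optional named list of method-specific extras, kept as-is.
#' @return A `GeneRanking` object.
#' @export
gene_ranking <- function(method, scores,
                         direction = c("higher_better", "lower_better"),
                         gene_ids, extra = list()) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(gene_ids))
  key <- if (direction == "higher_better") -scores else scores
  ord <- order(key, seq_along(scores))   # stable: ties by ascending index
  structure(
    c(list(method = method, scores = as.numeric(scores),
           direction = direction, order = ord,
           gene_ids = as.character(gene_ids)),
      extra),
    class = "GeneRanking")
}

#' @export
print.GeneRanking <- function(x, n = 10, ...) {
  cat("GeneRanking <", x$method, "> (", x$direction, "), ",
      length(x$scores), " genes\n", sep = "")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
as.data.frame.GeneRanking <- function(x, ...) {
  data.frame(rank = seq_along(x$order),
             gene_id = x$gene_ids[x$order],
             score = x$scores[x$order],
             method = x$method,
             stringsAsFactors = FALSE)
}

#' Top-ranked gene ids
#'
#' @param ranking A [gene_ranking()].
#' @param n Number of genes to return (default 25).
#' @return Character vector of the `n` best-ranked gene ids.
#' @export
top_genes <- function(ranking, n = 25) {
  stopifnot(inherits(ranking, "GeneRanking"))
  ranking$gene_ids[ranking$order[seq_len(min(n, length(ranking$order)))]]
}

# Indices (row numbers) of the top n genes; internal.
top_indices <- function(ranking, n) {
  ranking$order[seq_len(min(n, length(ranking$order)))]
}

#' Names of the registered ranking methods
#' @return Character vector of the eight method tags.
#' @export
ranking_methods <- function() {
  c("snr", "ttest", "lsd", "tnom", "mdmr", "wepo", "rfgs", "svst")
}

#' Rank genes by any registered method
#'
#' Dispatcher over the eight scoring methods. Method-specific parameters
#' (e.g. `n_groups`, `n_cycles`, `n_runs`, `seed` for RFGS; `C`,
#' `sv_policy` for SVST) are passed through `...`.
#'
#' @param x A labelled [expression_matrix()].
#' @param method One of [ranking_methods()].
#' @param ... Passed to the underlying scorer.
#' @return A [gene_ranking()].
#' @export
rank_genes <- function(x, method = ranking_methods(), ...) {
  method <- match.arg(method)
  switch(method,
    snr = snr_scores(x),
    ttest = ttest_scores(x),
    lsd = lsd_scores(x),
    tnom = tnom_scores(x),
    mdmr = mdmr_scores(x),
    wepo = wepo_scores(x),
    rfgs = rfgs_rank(x, ...)$ranking,
    svst = svst_rank(x, ...))
}

#' Write a ranking as TSV
#'
#' Columns: rank, gene_id, score, method.
#'
#' @param ranking A [gene_ranking()].
#' @param path Output path.
#' @param n Optional number of top genes to write (default: all).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, n = NULL) {
  df <- as.data.frame(ranking)
  if (!is.null(n)) df <- utils::head(df, n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
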