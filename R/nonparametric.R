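#' Nonparametric gene scores: TNoM, MDMR, WEPO
#'
#' Three rank/combinatorial two-class scores; a smaller score marks a more
#' informative gene.
#'
#' * TNoM (threshold number of misclassifications): the minimum number of
#'   misclassified samples over all single-threshold decision rules
#'   `sign(a x + b)`, i.e. over every cut between distinct expression
#'   values and both orientations. Integer in `[0, min(m+, m-)]`.
#' * MDMR (minimum distance to modal ranking): sort the samples by
#'   expression and count the minimum number of adjacent swaps needed to
#'   turn the induced label sequence into a perfect class split; equals
#'   the cross-class inversion count, minimized over the two modal targets
#'   (all `+` first / all `-` first). Tied expression values contribute no
#'   swaps (the most favorable tie ordering is taken). 0 means the gene
#'   splits the classes exactly.
#' * WEPO (weighted punishment on overlap): robust z-score each gene,
#'   `z = (x - mean) / MAD` with MAD the *mean* absolute deviation, then
#'   punish every cross-class pair in the wrong order by the z-gap it
#'   spans, `sum |z_i - z_j|`, minimized over the two orientations. This
#'   z-gap-weighted swap punishment is a reconstructed instantiation of
#'   the published scheme (the original formula is not reproduced here);
#'   it reduces to MDMR's wrong-order pairs weighted by separation in z.
#'   Genes with MAD below `eps` score 0 and are flagged `degenerate`.
#'
#' @param x A labelled [expression_matrix()].
#' @param eps MAD floor below which a gene counts as constant (WEPO only).
#' @return A [gene_ranking()] with `direction = "lower_better"`; WEPO
#'   rankings carry a logical `degenerate` element marking MAD-zero genes.
#' @name nonparametric_scores
NULL

#' @rdname nonparametric_scores
#' @export
tnom_scores <- function(x) {
  check_two_classes(x)
  y <- x$labels
  s <- length(y)
  scores <- vapply(seq_len(nrow(x$values)), function(i) {
    xv <- x$values[i, ]
    o <- order(xv)
    ys <- y[o]
    xs <- xv[o]
    pc <- c(0L, cumsum(ys == 1L))        # positives among first k, k = 0..s
    npos <- pc[s + 1L]
    nneg <- s - npos
    k <- 0:s
    # cuts only between distinct values (plus the two trivial ends)
    allowed <- c(TRUE, xs[-s] < xs[-1L], TRUE)
    err_pos_left <- (k - pc) + (npos - pc)   # left -> +1, right -> -1
    err_neg_left <- pc + (nneg - (k - pc))   # left -> -1, right -> +1
    min(pmin(err_pos_left, err_neg_left)[allowed])
  }, numeric(1))
  gene_ranking("tnom", scores, "lower_better", x$gene_ids)
}

#' @rdname nonparametric_scores
#' @export
mdmr_scores <- function(x) {
  check_two_classes(x)
  y <- x$labels
  scores <- vapply(seq_len(nrow(x$values)), function(i) {
    xv <- x$values[i, ]
    xp <- xv[y == 1L]
    xn <- sort(xv[y == -1L])
    n_le <- findInterval(xp, xn)                     # xn <= xp
    n_lt <- findInterval(xp, xn, left.open = TRUE)   # xn <  xp
    inv_pos_first <- sum(n_lt)                   # pairs with xn strictly below xp
    inv_neg_first <- sum(length(xn) - n_le)      # pairs with xn strictly above xp
    min(inv_pos_first, inv_neg_first)
  }, numeric(1))
  gene_ranking("mdmr", scores, "lower_better", x$gene_ids)
}

#' @rdname nonparametric_scores
#' @export
wepo_scores <- function(x, eps = 1e-12) {
  check_two_classes(x)
  y <- x$labels
  g <- nrow(x$values)
  scores <- numeric(g)
  degenerate <- logical(g)
  pos <- y == 1L
  for (i in seq_len(g)) {
    xv <- x$values[i, ]
    mu <- mean(xv)
    mad <- mean(abs(xv - mu))
    if (mad <= eps) {
      degenerate[i] <- TRUE
      next
    }
    z <- (xv - mu) / mad
    d <- outer(z[pos], z[!pos], "-")   # z_pos - z_neg for every cross pair
    punish_pos_low <- sum(d[d > 0])    # "+ below -": wrong pairs have z+ > z-
    punish_neg_low <- -sum(d[d < 0])
    scores[i] <- min(punish_pos_low, punish_neg_low)
  }
  gene_ranking("wepo", scores, "lower_better", x$gene_ids,
               extra = list(degenerate = degenerate))
}

#' Robust z-score of one gene
#'
#' `z = (x - mean) / MAD` with MAD the mean absolute deviation about the
#' mean. If MAD is below `eps` the z-scores are all zero.
#'
#' @param xv Numeric vector of one gene's expression values.
#' @param eps MAD floor.
#' @return List with elements `z` and `mad`.
#' @export
zscore_mad <- function(xv, eps = 1e-12) {
  mu <- mean(xv)
  mad <- mean(abs(xv - mu))
  z <- if (mad <= eps) rep(0, length(xv)) else (xv - mu) / mad
  list(z = z, mad = mad)
}
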