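#' Parametric gene scores: SNR, Welch t, Fisher/LSD
#'
#' Three classical parametric two-class scores. Writing `mu`/`sigma` for
#' the per-class mean and SD and `m` for the class size:
#'
#' * SNR (signal-to-noise ratio): `|mu+ - mu-| / (sigma+ + sigma-)`,
#'   population SDs.
#' * t (Welch unpaired t): `|mu+ - mu-| / sqrt(sigma+^2/m+ + sigma-^2/m-)`,
#'   sample SDs (`ddof = 1`).
#' * LSD (Fisher criterion): `(mu+ - mu-)^2 / (sigma+^2 + sigma-^2)`,
#'   population SDs.
#'
#' A larger score marks a more informative gene. Denominators are floored
#' at `eps` so constant genes score finitely (a gene constant in both
#' classes with equal means scores exactly 0). Absolute values make all
#' three symmetric under class-label swap.
#'
#' @param x A labelled [expression_matrix()].
#' @param eps Denominator floor for degenerate (zero-variance) genes.
#' @return A [gene_ranking()] with `direction = "higher_better"`.
#' @name parametric_scores
NULL

#' @rdname parametric_scores
#' @export
snr_scores <- function(x, eps = 1e-12) {
  cs <- class_stats(x, ddof = 0)
  s <- abs(cs$mu_pos - cs$mu_neg) / pmax(cs$sigma_pos + cs$sigma_neg, eps)
  gene_ranking("snr", s, "higher_better", x$gene_ids)
}

#' @rdname parametric_scores
#' @export
ttest_scores <- function(x, eps = 1e-12) {
  cs <- class_stats(x, ddof = 1)
  se2 <- cs$sigma_pos^2 / cs$m_pos + cs$sigma_neg^2 / cs$m_neg
  s <- abs(cs$mu_pos - cs$mu_neg) / sqrt(pmax(se2, eps))
  gene_ranking("ttest", s, "higher_better", x$gene_ids)
}

#' @rdname parametric_scores
#' @export
lsd_scores <- function(x, eps = 1e-12) {
  cs <- class_stats(x, ddof = 0)
  s <- (cs$mu_pos - cs$mu_neg)^2 /
    pmax(cs$sigma_pos^2 + cs$sigma_neg^2, eps)
  gene_ranking("lsd", s, "higher_better", x$gene_ids)
}
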