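#' Fit a linear soft-margin SVM on the samples
#'
#' Wraps a libsvm C-classification fit (linear kernel, penalty `C`) and
#' re-expresses it in primal/dual form on the package's `+1`/`-1` label
#' coding: per-sample dual coefficients `alpha` (`0 <= alpha_i <= C`,
#' `sum alpha_i y_i = 0`), weight vector `w = sum alpha_i y_i x_i` over
#' genes, bias `b`, and decision values `fx = t(X) w + b` so that
#' `sign(fx)` predicts the class. Samples with `alpha_i = 0` lie strictly
#' outside the margin; `0 < alpha_i < C` marks unbounded support vectors
#' on the margin; `alpha_i = C` marks margin violators.
#'
#' @param x A labelled [expression_matrix()], normally z-normalized first
#'   (see [normalize_genes()]).
#' @param C Soft-margin penalty (default 1).
#' @return A list of class `SvmModel` with elements `alpha`, `C`, `w`,
#'   `b`, `fx`, `labels`, `sample_ids`, and `gamma` (the recorded 1/genes
#'   kernel parameter, inert under the linear kernel).
#' @export
fit_linear_svm <- function(x, C = 1) {
  check_two_classes(x)
  xt <- t(x$values)                 # samples x genes
  yf <- factor(x$labels, levels = c(-1L, 1L))
  fit <- e1071::svm(x = xt, y = yf, type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = 1e-8)   # tight KKT for SV extraction
  s <- ncol(x$values)
  alpha <- numeric(s)
  alpha[fit$index] <- abs(fit$coefs[, 1])
  w_raw <- drop(crossprod(fit$coefs, fit$SV))
  b_raw <- -fit$rho
  # libsvm treats its first label as the internal +1 class; flip to ours
  internal_pos <- levels(yf)[fit$labels[1]]
  sgn <- if (internal_pos == "1") 1 else -1
  w <- sgn * w_raw
  b <- sgn * b_raw
  fx <- drop(xt %*% w) + b
  structure(list(alpha = alpha, C = C, w = w, b = b, fx = fx,
                 labels = x$labels, sample_ids = x$sample_ids,
                 gamma = 1 / nrow(x$values)),
            class = "SvmModel")
}

#' @export
print.SvmModel <- function(x, ...) {
  nsv <- sum(x$alpha > 1e-6 * x$C)
  cat("SvmModel: linear kernel, C =", x$C, "-", nsv, "support vectors /",
      length(x$alpha), "samples\n")
  invisible(x)
}

#' Select support-vector samples from a fitted SVM
#'
#' @param model A fitted [fit_linear_svm()] model.
#' @param policy `"all_sv"` keeps every sample with `alpha > tol`
#'   (default); `"unbounded_only"` keeps only on-margin samples with
#'   `tol < alpha < C - tol`.
#' @param tol Numeric dust tolerance for alpha (default `1e-6 * C`).
#' @return A list of class `SupportSampleSet` with `indices` and per-index
#'   `status` (`"unbounded"` or `"bounded"`).
#' @export
select_support_samples <- function(model,
                                   policy = c("all_sv", "unbounded_only"),
                                   tol = 1e-6 * model$C) {
  stopifnot(inherits(model, "SvmModel"))
  policy <- match.arg(policy)
  a <- model$alpha
  C <- model$C
  unbounded <- a > tol & a < C - tol
  bounded <- a >= C - tol
  idx <- if (policy == "all_sv") which(unbounded | bounded) else which(unbounded)
  if (length(idx) == 0)
    stop("no ", if (policy == "unbounded_only") "unbounded " else "",
         "support vectors found",
         if (policy == "unbounded_only")
           "; every support vector is at the C bound - try policy = \"all_sv\""
         else "")
  structure(list(indices = idx,
                 status = ifelse(unbounded[idx], "unbounded", "bounded")),
            class = "SupportSampleSet")
}

#' Support Vector Sampling Technique (SVST) gene ranking
#'
#' Two-step ranking: fit a linear SVM (penalty `C`) on all samples, keep
#' only the support-vector samples, then rank genes by the SNR score
#' computed on that sample subset. The idea is that samples far from the
#' decision boundary dilute the class statistics; restricting to the
#' support vectors concentrates the ranking on the informative samples.
#' Class statistics are recomputed on the reduced set; rows are not
#' re-normalized (set `renormalize = TRUE` to re-apply
#' [normalize_genes()] to the subset).
#'
#' @inheritParams fit_linear_svm
#' @inheritParams select_support_samples
#' @param renormalize Re-z-normalize gene rows over the retained samples
#'   before scoring (default `FALSE`).
#' @return A [gene_ranking()] (`direction = "higher_better"`) with extras
#'   `n_support` (retained sample count) and `support` (the
#'   `SupportSampleSet`).
#' @export
svst_rank <- function(x, C = 1, policy = c("all_sv", "unbounded_only"),
                      tol = 1e-6 * C, renormalize = FALSE) {
  policy <- match.arg(policy)
  model <- fit_linear_svm(x, C = C)
  svs <- select_support_samples(model, policy = policy, tol = tol)
  sub <- expression_matrix(x$values[, svs$indices, drop = FALSE],
                           x$gene_ids, x$sample_ids[svs$indices],
                           labels = x$labels[svs$indices])
  if (!any(sub$labels == 1L) || !any(sub$labels == -1L))
    stop("support-vector samples cover a single class; degenerate fit")
  if (renormalize) sub <- normalize_genes(sub)
  r <- snr_scores(sub)
  gene_ranking("svst", r$scores, "higher_better", x$gene_ids,
               extra = list(n_support = length(svs$indices), support = svs))
}

#' Support-sample report
#'
#' Per-sample table of the quantities SVST filters on: the dual
#' coefficient, the margin status, and `y * f(x)`.
#'
#' @param model A fitted [fit_linear_svm()] model.
#' @param tol Alpha dust tolerance.
#' @return Data frame with columns `sample_id`, `alpha`, `status`,
#'   `y_fx`.
#' @export
support_report <- function(model, tol = 1e-6 * model$C) {
  stopifnot(inherits(model, "SvmModel"))
  a <- model$alpha
  status <- ifelse(a <= tol, "non_sv",
                   ifelse(a >= model$C - tol, "bounded", "unbounded"))
  data.frame(sample_id = model$sample_ids, alpha = a, status = status,
             y_fx = model$labels * model$fx, stringsAsFactors = FALSE)
}
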