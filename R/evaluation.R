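#' Stratified random k-fold validation indices
#'
#' Partitions `1:length(labels)` into `k` validation folds whose sizes
#' differ by at most one, stratified by class so every fold carries both
#' classes whenever the class sizes permit. Uses the current RNG state.
#'
#' @param labels Integer `+1`/`-1` label vector.
#' @param k Number of folds.
#' @return List of `k` disjoint integer index vectors covering all
#'   samples. A warning is raised if some fold ends up single-class.
#' @export
random_kfold_indices <- function(labels, k) {
  s <- length(labels)
  stopifnot(k >= 2, k <= s)
  folds <- vector("list", k)
  sizes <- integer(k)
  for (cl in c(1L, -1L)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    cnt <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0) {
      # route remainders to the currently smallest folds
      extra <- order(sizes, seq_len(k))[seq_len(r)]
      cnt[extra] <- cnt[extra] + 1L
    }
    pos <- 0L
    for (f in seq_len(k)) {
      if (cnt[f] > 0) {
        folds[[f]] <- c(folds[[f]], idx[pos + seq_len(cnt[f])])
        pos <- pos + cnt[f]
      }
    }
    sizes <- sizes + cnt
  }
  single <- vapply(folds, function(f)
    length(unique(labels[f])) < 2L, logical(1))
  if (any(single))
    warning("fold(s) ", paste(which(single), collapse = ", "),
            " contain a single class")
  folds
}

#' Repeated random k-fold benchmark of a ranking method
#'
#' The study protocol behind the accuracy tables: repeatedly split the
#' samples into `n_folds` random (stratified) folds; in each repeat use
#' every fold once for validation, selecting the top-`k` genes with
#' `method`, training a linear SVM (penalty `C`) on the remaining folds
#' restricted to those genes, and scoring accuracy on the validation fold.
#' With `selection_scope = "per_fold"` (default) gene selection sees only
#' the training folds — the guard against the selection bias that inflates
#' accuracy when genes are chosen on the full dataset;
#' `"whole_dataset"` ranks once per repeat on all samples, reproducing
#' the biased variant for comparison.
#'
#' @param x A labelled [expression_matrix()].
#' @param method One of [ranking_methods()].
#' @param top_k Integer vector of gene-set sizes to evaluate.
#' @param n_folds Number of folds (default 3).
#' @param n_repeats Number of independent random re-foldings (default 100).
#' @param selection_scope `"per_fold"` or `"whole_dataset"`.
#' @param C Linear-SVM penalty for the classifier.
#' @param seed Optional RNG seed; each repeat draws its own stream so the
#'   whole report is reproducible.
#' @param method_args Named list of extra arguments for the ranking
#'   method (e.g. `list(n_groups = 50, n_cycles = 20)` for RFGS).
#' @param skip_failed If `TRUE`, a fold where the method or classifier
#'   fails is recorded as `NA` and excluded from aggregation instead of
#'   aborting the run.
#' @return A list of class `CvReport`: `method`, `top_k`, `accuracy`
#'   (repeats x folds x top_k array), and `summary` (data frame with
#'   `mean`, `min`, `max` accuracy per top_k).
#' @export
evaluate_method <- function(x, method, top_k = c(25, 50, 75, 100, 125, 150),
                            n_folds = 3, n_repeats = 100,
                            selection_scope = c("per_fold", "whole_dataset"),
                            C = 1, seed = NULL, method_args = list(),
                            skip_failed = FALSE) {
  check_two_classes(x)
  selection_scope <- match.arg(selection_scope)
  top_k <- as.integer(top_k)
  stopifnot(all(top_k >= 1), all(top_k <= nrow(x$values)))
  acc <- array(NA_real_, c(n_repeats, n_folds, length(top_k)))
  with_seed(seed, {
    repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  })
  for (rep_i in seq_len(n_repeats)) {
    acc[rep_i, , ] <- with_seed(repeat_seeds[rep_i], {
      folds <- random_kfold_indices(x$labels, n_folds)
      a <- matrix(NA_real_, n_folds, length(top_k))
      ranking_full <- NULL
      if (selection_scope == "whole_dataset")
        ranking_full <- do.call(rank_genes,
                                c(list(x, method), method_args))
      for (f in seq_len(n_folds)) {
        val <- folds[[f]]
        train <- setdiff(seq_len(ncol(x$values)), val)
        one_fold <- function() {
          ranking <- if (selection_scope == "per_fold") {
            xt <- expression_matrix(x$values[, train, drop = FALSE],
                                    x$gene_ids, x$sample_ids[train],
                                    labels = x$labels[train])
            do.call(rank_genes, c(list(xt, method), method_args))
          } else ranking_full
          vapply(seq_along(top_k), function(ki) {
            sel <- top_indices(ranking, top_k[ki])
            fit <- e1071::svm(
              x = t(x$values[sel, train, drop = FALSE]),
              y = factor(x$labels[train], levels = c(-1L, 1L)),
              type = "C-classification", kernel = "linear",
              cost = C, scale = FALSE)
            pred <- stats::predict(
              fit, t(x$values[sel, val, drop = FALSE]))
            mean(as.integer(as.character(pred)) == x$labels[val])
          }, numeric(1))
        }
        a[f, ] <- if (skip_failed) {
          tryCatch(one_fold(), error = function(e) {
            warning("fold failed (", conditionMessage(e), "); skipped")
            rep(NA_real_, length(top_k))
          })
        } else one_fold()
      }
      a
    })
  }
  summary <- data.frame(
    method = method, top_k = top_k,
    mean = vapply(seq_along(top_k), function(ki)
      mean(acc[, , ki], na.rm = TRUE), numeric(1)),
    min = vapply(seq_along(top_k), function(ki)
      min(acc[, , ki], na.rm = TRUE), numeric(1)),
    max = vapply(seq_along(top_k), function(ki)
      max(acc[, , ki], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(method = method, top_k = top_k, accuracy = acc,
                 summary = summary),
            class = "CvReport")
}

#' @export
print.CvReport <- function(x, ...) {
  cat("CvReport <", x$method, ">: ", dim(x$accuracy)[1], " repeats x ",
      dim(x$accuracy)[2], " folds\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ".95", "1", ".80" - the accuracy-table number style
format_accuracy <- function(v) {
  s <- sprintf("%.2f", v)
  ifelse(s == "1.00", "1", sub("^0", "", s))
}

#' Render CV reports as an accuracy table
#'
#' One row per method, one column per gene-set size, cells in the
#' `".95(.88 to 1)"` mean-and-range style.
#'
#' @param reports A `CvReport` or list of them (one per method).
#' @return Data frame of formatted cells with a `method` column; print it
#'   or write it as TSV.
#' @export
format_cv_report <- function(reports) {
  if (inherits(reports, "CvReport")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  top_k <- reports[[1]]$top_k
  rows <- lapply(reports, function(r) {
    stopifnot(identical(r$top_k, top_k))
    cells <- vapply(seq_along(top_k), function(ki) {
      s <- r$summary[ki, ]
      paste0(format_accuracy(s$mean), "(", format_accuracy(s$min),
             " to ", format_accuracy(s$max), ")")
    }, "")
    c(r$method, cells)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- c("method", paste(top_k, "genes"))
  out
}
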