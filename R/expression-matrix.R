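#' Two-class expression matrix
#'
#' Light-weight container for a genes-by-samples expression matrix with
#' optional binary class labels. Rows are genes (the GCT/RES convention),
#' columns are samples; labels are coded `+1` / `-1` (e.g. normal vs tumor).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param labels Optional integer vector of class labels, one per sample,
#'   each `+1` or `-1`. Both classes must be non-empty before any scoring
#'   function is applied; labels may be attached later with
#'   [attach_labels()].
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' em <- expression_matrix(x, paste0("g", 1:3), paste0("s", 1:4),
#'                         labels = c(1, 1, -1, -1))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         if (length(dup) > 5) ", ..." else "")
  }
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  obj <- structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = NULL),
    class = "ExpressionMatrix")
  if (!is.null(labels)) obj <- attach_labels(obj, labels)
  obj
}

#' Attach class labels to an expression matrix
#'
#' @param x An [expression_matrix()].
#' @param labels Vector of `+1`/`-1` labels, one per sample.
#' @return `x` with labels attached.
#' @export
attach_labels <- function(x, labels) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- as.integer(labels)
  if (length(labels) != ncol(x$values))
    stop("labels length (", length(labels), ") does not match sample count (",
         ncol(x$values), ")")
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be coded +1 / -1")
  x$labels <- labels
  x
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$labels)) {
    cat("labels: ", sum(x$labels == 1L), " (+1), ", sum(x$labels == -1L),
        " (-1)\n", sep = "")
  } else {
    cat("labels: unset\n")
  }
  invisible(x)
}

# Both classes present and labelled; shared guard for every scoring function.
check_two_classes <- function(x) {
  if (is.null(x$labels))
    stop("expression matrix has no class labels; use attach_labels()")
  if (!any(x$labels == 1L) || !any(x$labels == -1L))
    stop("both classes must be non-empty")
  invisible(x)
}

#' Per-gene z-normalization
#'
#' Centers and scales each gene row to mean 0 and (population) standard
#' deviation 1 — the shared preprocessing step of all the ranking methods.
#' Rows with zero variance are mapped to all zeros rather than producing
#' NaN, so constant probes pass through harmlessly.
#'
#' @param x An [expression_matrix()].
#' @param eps Variance floor below which a row counts as constant.
#' @return The normalized `ExpressionMatrix`; labels and ids unchanged.
#' @export
normalize_genes <- function(x, eps = 1e-12) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  mu <- rowMeans(v)
  cv <- v - mu
  sdev <- sqrt(rowMeans(cv * cv))   # population SD
  keep <- sdev > eps
  out <- cv
  out[keep, ] <- cv[keep, , drop = FALSE] / sdev[keep]
  out[!keep, ] <- 0
  x$values <- out
  x
}

#' Per-class means and standard deviations
#'
#' @param x A labelled [expression_matrix()].
#' @param ddof Degrees-of-freedom convention for the SD: `0` (population,
#'   divisor m) or `1` (sample, divisor m - 1). `ddof = 1` requires at
#'   least two samples per class.
#' @return A list of class `ClassStats` with per-gene vectors `mu_pos`,
#'   `mu_neg`, `sigma_pos`, `sigma_neg` and counts `m_pos`, `m_neg`.
#' @export
class_stats <- function(x, ddof = 0) {
  check_two_classes(x)
  stopifnot(ddof %in% c(0, 1))
  pos <- x$values[, x$labels == 1L, drop = FALSE]
  neg <- x$values[, x$labels == -1L, drop = FALSE]
  m_pos <- ncol(pos)
  m_neg <- ncol(neg)
  if (ddof == 1 && (m_pos < 2 || m_neg < 2))
    stop("ddof = 1 requires at least 2 samples per class")
  sd_of <- function(m, mu, n) {
    cv <- m - mu
    sqrt(rowSums(cv * cv) / (n - ddof))
  }
  mu_pos <- rowMeans(pos)
  mu_neg <- rowMeans(neg)
  structure(
    list(mu_pos = mu_pos, mu_neg = mu_neg,
         sigma_pos = sd_of(pos, mu_pos, m_pos),
         sigma_neg = sd_of(neg, mu_neg, m_neg),
         m_pos = m_pos, m_neg = m_neg),
    class = "ClassStats")
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
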