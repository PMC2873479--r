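#' Read an expression matrix from file
#'
#' Supports three dialects: plain delimited text (gene ids in the first
#' column, sample ids in the header), GenePattern GCT (versioned `#1.2`
#' header with gene Name/Description columns), and GenePattern RES
#' (expression values interleaved with A/P/M call columns, which are
#' discarded on read).
#'
#' @param path File path.
#' @param format One of `"delimited"`, `"gct"`, `"res"`.
#' @param sep Field separator for the delimited dialect (default tab).
#' @param transpose For the delimited dialect only: set `TRUE` when the
#'   file stores samples in rows.
#' @param dedup What to do with duplicate gene ids: `"error"` (default,
#'   names the duplicates) or `"suffix"` (disambiguate with `.1`, `.2`, ...).
#' @return An [expression_matrix()] with labels unset.
#' @export
read_expression <- function(path, format = c("delimited", "gct", "res"),
                            sep = "\t", transpose = FALSE,
                            dedup = c("error", "suffix")) {
  format <- match.arg(format)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) stop("file not found: ", path)
  res <- switch(format,
    delimited = read_delimited_matrix(path, sep, transpose),
    gct = read_gct(path),
    res = read_res(path))
  if (anyDuplicated(res$gene_ids)) {
    if (dedup == "suffix") {
      res$gene_ids <- make.unique(res$gene_ids, sep = ".")
    } # else: expression_matrix() rejects, naming the duplicates
  }
  expression_matrix(res$values, res$gene_ids, res$sample_ids)
}

read_delimited_matrix <- function(path, sep, transpose) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (transpose) {
    list(values = t(vals), gene_ids = colnames(vals), sample_ids = ids)
  } else {
    list(values = vals, gene_ids = ids, sample_ids = colnames(vals))
  }
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (length(dims) < 2 || any(is.na(dims[1:2])))
    stop("malformed GCT dimension line")
  ng <- dims[1]; ns <- dims[2]
  header <- strsplit(lines[3], "\t")[[1]]
  sample_ids <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng)
    stop("GCT header declares ", ng, " genes but body has ",
         length(body), " rows")
  if (length(sample_ids) != ns)
    stop("GCT header declares ", ns, " samples but column header has ",
         length(sample_ids))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ns + 2L)
  if (length(bad))
    stop("GCT row ", bad[1], " has ", lengths(parts)[bad[1]] - 2L,
         " values, expected ", ns)
  gene_ids <- vapply(parts, `[[`, "", 1L)
  vals <- matrix(as.numeric(unlist(lapply(parts, `[`, -(1:2)))),
                 nrow = ng, ncol = ns, byrow = TRUE)
  list(values = vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

# RES dialect: row 1 = Description, Accession, then each sample name followed
# by an empty field (the call column has no header text); row 2 = sample
# descriptions (ignored); row 3 = number of genes; data rows = description,
# accession, then (value, call) pairs. Calls (A/P/M) are discarded.
read_res <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("not a RES file: ", path)
  head1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rest <- head1[-(1:2)]
  sample_ids <- rest[nzchar(rest)]
  ns <- length(sample_ids)
  ng <- as.integer(trimws(lines[3]))
  if (is.na(ng)) stop("malformed RES gene-count line")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng)
    stop("RES header declares ", ng, " genes but body has ",
         length(body), " rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  gene_ids <- vapply(parts, `[[`, "", 2L)   # accession column
  vals <- matrix(NA_real_, nrow = ng, ncol = ns)
  for (i in seq_len(ng)) {
    p <- parts[[i]]
    want <- 2L + 2L * ns
    if (length(p) < want)
      stop("RES row ", i, " has ", length(p) - 2L,
           " fields, expected ", 2L * ns)
    vals[i, ] <- as.numeric(p[seq(3L, by = 2L, length.out = ns)])
  }
  list(values = vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix to file
#'
#' @inheritParams read_expression
#' @param x An [expression_matrix()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("delimited", "gct", "res"),
                             sep = "\t") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  v <- x$values
  switch(format,
    delimited = {
      df <- data.frame(gene_id = x$gene_ids, v, check.names = FALSE)
      colnames(df) <- c("gene_id", x$sample_ids)
      utils::write.table(df, path, sep = sep, quote = FALSE,
                         row.names = FALSE)
    },
    gct = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"),
                   paste(c("Name", "Description", x$sample_ids),
                         collapse = "\t")), con)
      body <- paste(x$gene_ids, "na",
                    apply(format(v, trim = TRUE, digits = 15), 1, paste,
                          collapse = "\t"),
                    sep = "\t")
      writeLines(body, con)
    },
    res = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(paste(c("Description", "Accession",
                         rbind(x$sample_ids, "")), collapse = "\t"), con)
      writeLines(paste(c("", "", rbind(x$sample_ids, "")),
                       collapse = "\t"), con)
      writeLines(as.character(nrow(v)), con)
      calls <- matrix("P", nrow(v), ncol(v))
      body <- vapply(seq_len(nrow(v)), function(i) {
        paste(c("na", x$gene_ids[i],
                rbind(format(v[i, ], trim = TRUE, digits = 15),
                      calls[i, ])), collapse = "\t")
      }, "")
      writeLines(body, con)
    })
  invisible(path)
}

#' Read class labels
#'
#' Reads binary class labels from a GenePattern CLS file or a two-column
#' `sample<TAB>class` file and maps the two class names to `+1` / `-1`.
#' By default the first class name encountered maps to `+1`; pass
#' `positive_class` to override (e.g. the prostate convention maps the
#' normal samples to `+1` and tumor to `-1`).
#'
#' @param path File path.
#' @param format `"cls"` or `"two_column"`.
#' @param positive_class Optional class name to map to `+1`.
#' @return Integer vector of `+1`/`-1` labels with attributes
#'   `class_names` (names for `+1` and `-1`, in that order) and, for
#'   two-column files, `sample_ids`.
#' @export
read_labels <- function(path, format = c("cls", "two_column"),
                        positive_class = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "cls") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3) stop("malformed CLS file")
    hdr <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
    names_line <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
    if (names_line[1] != "#") stop("malformed CLS name line")
    class_names <- names_line[-1]
    toks <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
    if (!is.na(hdr[1]) && length(toks) != hdr[1])
      stop("CLS declares ", hdr[1], " samples but lists ", length(toks))
    # tokens may be class names or 0-based indices into class_names
    if (all(toks %in% class_names)) {
      cls <- toks
    } else {
      idx <- suppressWarnings(as.integer(toks))
      if (anyNA(idx)) stop("CLS labels are neither names nor indices")
      cls <- class_names[idx + 1L]
    }
    sample_ids <- NULL
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("two-column label file needs 2 columns")
    sample_ids <- as.character(df[[1]])
    cls <- as.character(df[[2]])
    class_names <- unique(cls)
  }
  u <- unique(cls)
  if (length(u) != 2)
    stop("expected exactly 2 classes, found ", length(u), ": ",
         paste(u, collapse = ", "))
  pos <- if (is.null(positive_class)) u[1] else positive_class
  if (!pos %in% u) stop("positive_class '", pos, "' not among classes")
  neg <- setdiff(u, pos)
  out <- ifelse(cls == pos, 1L, -1L)
  attr(out, "class_names") <- c(pos, neg)
  if (!is.null(sample_ids)) attr(out, "sample_ids") <- sample_ids
  out
}

#' Write labels as a GenePattern CLS file
#'
#' @param labels Integer `+1`/`-1` label vector.
#' @param path Output path.
#' @param class_names Names for the `+1` and `-1` classes, in that order.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path, class_names = c("POS", "NEG")) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(-1L, 1L)), length(class_names) == 2)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(length(labels), 2, 1), con)
  writeLines(paste("#", class_names[1], class_names[2]), con)
  writeLines(paste(ifelse(labels == 1L, class_names[1], class_names[2]),
                   collapse = " "), con)
  invisible(path)
}
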