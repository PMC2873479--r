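#' Random Forest Gene Selection (RFGS)
#'
#' RFGS ranks genes by how often they are chosen as the *root* of a
#' decision tree grown on a random gene subset. Each cycle partitions all
#' genes uniformly at random into `n_groups` groups; within each group the
#' root is the gene whose best univariate threshold split minimizes the
#' weighted Gini impurity of the two children (the root a CART tree on
#' those genes would choose — only the root is needed, no tree is grown
#' below it). Root selections ("hits") are accumulated over `n_cycles`
#' cycles and `n_runs` independent runs; genes are ranked by mean hit
#' count. Per run exactly `n_cycles * n_groups` hits are distributed, so
#' the hit table conserves that total.
#'
#' The defaults (`n_groups = 1000`, `n_cycles = 100`, `n_runs = 10`,
#' `top_n = 25`) suit genome-scale matrices (e.g. ~7000 genes gives
#' groups of 7-8); `n_groups` must not exceed the gene count.
#'
#' @param x A labelled [expression_matrix()].
#' @param n_groups Number of random gene groups per cycle (`M`).
#' @param n_cycles Number of re-partition cycles per run (`N`).
#' @param n_runs Number of independent runs averaged over.
#' @param seed Optional RNG seed; one root seed spawns per-run streams so
#'   runs are independent yet reproducible.
#' @param top_n Report size used for the per-run top-list membership count.
#' @return A list of class `RfgsResult`:
#'   * `hits` — genes x runs integer matrix of root-selection counts;
#'   * `mean_hits` — per-gene mean over runs;
#'   * `top_count` — in how many runs each gene entered that run's
#'     top-`top_n` hit list (the "hits out of 10" of the method's reports);
#'   * `ranking` — [gene_ranking()] on `mean_hits`, higher better.
#' @export
rfgs_rank <- function(x, n_groups = 1000, n_cycles = 100, n_runs = 10,
                      seed = NULL, top_n = 25) {
  check_two_classes(x)
  g <- nrow(x$values)
  stopifnot(n_groups >= 1, n_cycles >= 1, n_runs >= 1)
  if (n_groups > g)
    stop("n_groups (", n_groups, ") exceeds gene count (", g, ")")
  # The group root depends only on each gene's own best-split impurity,
  # which the random grouping never changes - compute it once.
  quality <- best_split_impurity(x)
  with_seed(seed, {
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
    hits <- matrix(0L, g, n_runs)
    for (r in seq_len(n_runs)) {
      hits[, r] <- with_seed(run_seeds[r], {
        h <- integer(g)
        for (cyc in seq_len(n_cycles)) {
          groups <- partition_genes(g, n_groups)
          roots <- vapply(groups, function(grp)
            grp[order(quality[grp], grp)[1L]], integer(1))
          h[roots] <- h[roots] + 1L
        }
        h
      })
    }
  })
  mean_hits <- rowMeans(hits)
  top_count <- integer(g)
  for (r in seq_len(n_runs)) {
    ord <- order(-hits[, r], seq_len(g))
    top_count[ord[seq_len(min(top_n, g))]] <-
      top_count[ord[seq_len(min(top_n, g))]] + 1L
  }
  ranking <- gene_ranking("rfgs", mean_hits, "higher_better", x$gene_ids,
                          extra = list(top_count = top_count))
  structure(list(hits = hits, mean_hits = mean_hits,
                 top_count = top_count, ranking = ranking,
                 config = list(n_groups = n_groups, n_cycles = n_cycles,
                               n_runs = n_runs, top_n = top_n, seed = seed)),
            class = "RfgsResult")
}

#' @export
print.RfgsResult <- function(x, ...) {
  cfg <- x$config
  cat("RfgsResult:", nrow(x$hits), "genes,", cfg$n_groups, "groups x",
      cfg$n_cycles, "cycles x", cfg$n_runs, "runs\n")
  print(x$ranking, ...)
  invisible(x)
}

#' Random balanced partition of genes into groups
#'
#' Chunks a uniform random permutation of `1:g` into `m` disjoint groups
#' whose sizes differ by at most one. Uses the current RNG state.
#'
#' @param g Gene count.
#' @param m Group count, `1 <= m <= g`.
#' @return List of `m` integer index vectors covering `1:g`.
#' @export
partition_genes <- function(g, m) {
  if (m < 1 || m > g) stop("need 1 <= m <= g")
  sizes <- rep(g %/% m, m)
  extra <- g %% m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- sample.int(g)
  unname(split(perm, rep(seq_len(m), times = sizes)))
}

#' Best-split Gini impurity per gene
#'
#' For each gene, the minimum over all threshold splits (cuts between
#' consecutive distinct sorted values) of the size-weighted Gini impurity
#' of the two children. Genes with no valid split (constant rows) get
#' `Inf`.
#'
#' @param x A labelled [expression_matrix()].
#' @param genes Integer indices of genes to evaluate (default: all).
#' @return Numeric vector of impurities, one per requested gene.
#' @export
best_split_impurity <- function(x, genes = seq_len(nrow(x$values))) {
  check_two_classes(x)
  y <- x$labels
  s <- length(y)
  vapply(genes, function(i) {
    xv <- x$values[i, ]
    o <- order(xv)
    ys <- y[o]
    xs <- xv[o]
    k <- seq_len(s - 1L)
    allowed <- xs[-s] < xs[-1L]
    if (!any(allowed)) return(Inf)
    pc <- cumsum(ys == 1L)[k]
    npos <- sum(ys == 1L)
    p_left <- pc / k
    p_right <- (npos - pc) / (s - k)
    gini <- (k * 2 * p_left * (1 - p_left) +
             (s - k) * 2 * p_right * (1 - p_right)) / s
    # rounded so that mathematically tied splits compare as exact ties
    signif(min(gini[allowed]), 10)
  }, numeric(1))
}

#' Root gene of a random group
#'
#' The gene in `group` whose best single threshold split minimizes the
#' weighted Gini impurity; ties go to the lowest gene index.
#'
#' @param group Integer vector of gene indices.
#' @param x A labelled [expression_matrix()].
#' @return A single gene index.
#' @export
root_gene <- function(group, x) {
  stopifnot(length(group) >= 1)
  imp <- best_split_impurity(x, group)
  group[order(imp, group)[1L]]
}
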