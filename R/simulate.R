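#' Simulate a two-class expression matrix with planted genes
#'
#' Generates a genes-by-samples matrix of i.i.d. Gaussian noise
#' `Normal(baseline_mean, noise_sd^2)` and shifts the `+1`-class mean of
#' each planted gene by `direction * delta * noise_sd` — the classical
#' "few differentially expressed genes on a large noise background" shape
#' of two-class microarray studies. Optional heavier-tailed noise
#' (`df` for t-distributed noise) and per-gene SD jitter are available for
#' robustness checks of the rank-based scores.
#'
#' @param n_genes Total number of genes.
#' @param n_pos,n_neg Class sizes; samples are ordered `+1` block first.
#' @param planted Integer indices of planted (differentially expressed)
#'   genes.
#' @param delta Effect size(s) in `noise_sd` units, recycled over planted
#'   genes.
#' @param direction `+1`/`-1` shift direction(s), recycled.
#' @param noise_sd Baseline noise SD.
#' @param baseline_mean Baseline mean.
#' @param df If finite, draw noise from a scaled t distribution with `df`
#'   degrees of freedom instead of a Gaussian.
#' @param sd_jitter If `> 0`, multiply each gene's SD by
#'   `exp(rnorm(1, 0, sd_jitter))`.
#' @param seed Optional RNG seed; the same seed reproduces the matrix
#'   bit-for-bit.
#' @return List with `x` (a labelled [expression_matrix()]) and `truth`
#'   (the planted gene indices).
#' @export
simulate_expression <- function(n_genes, n_pos, n_neg, planted = integer(0),
                                delta = 2, direction = 1L, noise_sd = 1,
                                baseline_mean = 0, df = Inf, sd_jitter = 0,
                                seed = NULL) {
  stopifnot(n_genes >= 1, n_pos >= 1, n_neg >= 1, all(delta >= 0))
  planted <- as.integer(planted)
  if (anyDuplicated(planted) || any(planted < 1 | planted > n_genes))
    stop("planted indices must be unique and within 1..n_genes")
  s <- n_pos + n_neg
  with_seed(seed, {
    noise <- if (is.finite(df)) {
      stats::rt(n_genes * s, df = df) / sqrt(df / (df - 2))
    } else {
      stats::rnorm(n_genes * s)
    }
    vals <- matrix(noise, n_genes, s)
    gene_sd <- rep(noise_sd, n_genes)
    if (sd_jitter > 0)
      gene_sd <- gene_sd * exp(stats::rnorm(n_genes, 0, sd_jitter))
    vals <- vals * gene_sd + baseline_mean
    if (length(planted)) {
      shift <- rep_len(delta, length(planted)) *
        rep_len(as.numeric(direction), length(planted)) *
        gene_sd[planted]
      vals[planted, seq_len(n_pos)] <-
        vals[planted, seq_len(n_pos), drop = FALSE] + shift
    }
  })
  labels <- c(rep(1L, n_pos), rep(-1L, n_neg))
  x <- expression_matrix(
    vals,
    gene_ids = sprintf("G%0*d", nchar(n_genes), seq_len(n_genes)),
    sample_ids = sprintf("S%0*d", nchar(s), seq_len(s)),
    labels = labels)
  list(x = x, truth = planted)
}

#' Leukemia-shaped synthetic preset
#'
#' A 7129-gene, 72-sample (47 `+1` / 25 `-1` by default, the ALL/AML-style
#' split) synthetic matrix with 30 planted genes at effect sizes drawn
#' uniformly from 1-3 SD units in random directions.
#'
#' @param seed RNG seed.
#' @param n_pos,n_neg Class sizes (default 47 / 25).
#' @return As [simulate_expression()].
#' @export
golub_like <- function(seed = NULL, n_pos = 47, n_neg = 25) {
  with_seed(seed, {
    planted <- sort(sample.int(7129, 30))
    delta <- stats::runif(30, 1, 3)
    dirs <- sample(c(-1L, 1L), 30, replace = TRUE)
    inner_seed <- sample.int(.Machine$integer.max - 1L, 1)
  })
  simulate_expression(7129, n_pos, n_neg, planted = planted, delta = delta,
                      direction = dirs, seed = inner_seed)
}

#' Prostate-shaped synthetic preset
#'
#' A 12600-gene, 102-sample synthetic matrix following the tumor/normal
#' coding convention: 52 tumor samples labelled `-1`, 50 normal samples
#' labelled `+1`; 30 planted genes at effect sizes 1-3.
#'
#' @param seed RNG seed.
#' @return As [simulate_expression()].
#' @export
singh_like <- function(seed = NULL) {
  with_seed(seed, {
    planted <- sort(sample.int(12600, 30))
    delta <- stats::runif(30, 1, 3)
    dirs <- sample(c(-1L, 1L), 30, replace = TRUE)
    inner_seed <- sample.int(.Machine$integer.max - 1L, 1)
  })
  sim <- simulate_expression(12600, n_pos = 50, n_neg = 52,
                             planted = planted, delta = delta,
                             direction = dirs, seed = inner_seed)
  # reorder: 52 tumor (-1) first, then 50 normal (+1), as distributed
  ord <- c(which(sim$x$labels == -1L), which(sim$x$labels == 1L))
  sim$x <- expression_matrix(sim$x$values[, ord], sim$x$gene_ids,
                             sprintf("S%03d", seq_along(ord)),
                             labels = sim$x$labels[ord])
  sim
}
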