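# Fixture builders and independent brute-force oracles used across tests.

# One-or-more-gene matrix from a values vector/matrix plus labels.
make_em <- function(values, labels, gene_ids = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  expression_matrix(values, gene_ids,
                    paste0("s", seq_len(ncol(values))), labels = labels)
}

# Random two-class gene with possible ties; returns list(x, y).
random_gene <- function(s, tie_pool = 6) {
  y <- integer(s)
  while (length(unique(y)) < 2) y <- sample(c(-1L, 1L), s, replace = TRUE)
  list(x = sample.int(tie_pool, s, replace = TRUE) + 0, y = y)
}

# TNoM oracle: enumerate every threshold between distinct values (plus the
# two trivial ends) and both rule orientations.
oracle_tnom <- function(xv, y) {
  u <- sort(unique(xv))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- length(y)
  for (t in cuts) for (orient in c(1L, -1L)) {
    pred <- ifelse(xv > t, orient, -orient)
    best <- min(best, sum(pred != y))
  }
  best
}

# MDMR oracle: breadth-first search over adjacent transpositions from the
# expression-sorted label sequence to the nearest perfect split.
oracle_mdmr_bfs <- function(labs) {
  is_split <- function(v) !is.unsorted(v) || !is.unsorted(rev(v))
  if (is_split(labs)) return(0L)
  seen <- new.env(hash = TRUE)
  assign(paste(labs, collapse = ","), TRUE, envir = seen)
  frontier <- list(labs)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (v in frontier) {
      for (i in seq_len(length(v) - 1L)) {
        w <- v
        w[c(i, i + 1L)] <- w[c(i + 1L, i)]
        key <- paste(w, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          if (is_split(w)) return(d)
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
    stopifnot(length(frontier) > 0)
  }
}

# WEPO oracle: explicit double loop over cross-class pairs, both
# orientations.
oracle_wepo <- function(xv, y, eps = 1e-12) {
  mu <- mean(xv)
  mad <- mean(abs(xv - mu))
  if (mad <= eps) return(0)
  z <- (xv - mu) / mad
  zp <- z[y == 1L]
  zn <- z[y == -1L]
  a <- 0; b <- 0
  for (p in zp) for (n in zn) {
    if (p > n) a <- a + (p - n)
    if (n > p) b <- b + (n - p)
  }
  min(a, b)
}

# CART-root oracle: scan every (gene, cut, orientation) triple for the
# minimum weighted Gini impurity; ties to the lowest gene index.
oracle_root <- function(group, em) {
  y <- em$labels
  s <- length(y)
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p <- mean(yy == 1L)
    2 * p * (1 - p)
  }
  best_imp <- rep(Inf, length(group))
  for (gi in seq_along(group)) {
    xv <- em$values[group[gi], ]
    u <- sort(unique(xv))
    if (length(u) < 2) next
    cuts <- (u[-1] + u[-length(u)]) / 2
    for (t in cuts) for (orient in c(TRUE, FALSE)) {
      left <- if (orient) xv <= t else xv > t
      imp <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / s
      if (imp < best_imp[gi]) best_imp[gi] <- imp
    }
  }
  group[order(signif(best_imp, 10), group)[1L]]
}

with_seed_helper <- function(seed, expr) withr::with_seed(seed, expr)

# Synthetic recovery protocol shared by the scoring-method tests: how many
# of the planted genes land in the method's top n.
recovered_in_top <- function(ranking, truth, n = 25) {
  length(intersect(top_indices(ranking, n), truth))
}
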