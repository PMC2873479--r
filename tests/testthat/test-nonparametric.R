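test_that("TNoM matches spec micro-examples and its upper bound", {
  em <- make_em(c(1, 2, 3, 10, 11, 12),
                labels = c(-1, -1, -1, 1, 1, 1))
  expect_equal(tnom_scores(em)$scores, 0)
  em2 <- make_em(c(1, 2, 3, 4), labels = c(1, -1, 1, -1))
  expect_equal(tnom_scores(em2)$scores, 1)
  set.seed(41)
  for (rep_i in 1:50) {
    g <- random_gene(s = sample(4:12, 1))
    sc <- tnom_scores(make_em(g$x, labels = g$y))$scores
    expect_lte(sc, min(sum(g$y == 1), sum(g$y == -1)))
  }
})

test_that("TNoM sweep equals the exhaustive cut-orientation oracle", {
  set.seed(42)
  for (rep_i in 1:500) {
    g <- random_gene(s = sample(4:12, 1))
    expect_equal(tnom_scores(make_em(g$x, labels = g$y))$scores,
                 oracle_tnom(g$x, g$y))
  }
})

test_that("MDMR equals the BFS swap-distance oracle for every short label sequence", {
  for (s in 2:8) {
    for (code in seq_len(2^s) - 1L) {
      labs <- ifelse(bitwAnd(code, 2^(seq_len(s) - 1L)) > 0, 1L, -1L)
      if (length(unique(labs)) < 2) next
      em <- make_em(as.numeric(seq_len(s)), labels = labs)
      expect_equal(mdmr_scores(em)$scores, oracle_mdmr_bfs(labs),
                   info = paste(labs, collapse = ""))
    }
  }
})

test_that("MDMR worked examples: perfect split 0, alternating sequences", {
  em <- make_em(c(1, 2, 3, 4), labels = c(1, 1, -1, -1))
  expect_equal(mdmr_scores(em)$scores, 0)
  em2 <- make_em(c(1, 2, 3, 4), labels = c(1, -1, 1, -1))
  expect_equal(mdmr_scores(em2)$scores, 1)
  em3 <- make_em(as.numeric(1:6), labels = c(1, -1, 1, -1, 1, -1))
  expect_equal(mdmr_scores(em3)$scores, 3)
})

test_that("WEPO reproduces the enumerated worked example and the pair-sum oracle", {
  em <- make_em(c(1, 3, 2, 4), labels = c(1, 1, -1, -1))
  expect_equal(wepo_scores(em)$scores, 1, tolerance = 1e-12)
  set.seed(43)
  for (rep_i in 1:200) {
    g <- random_gene(s = sample(4:12, 1))
    expect_equal(wepo_scores(make_em(g$x, labels = g$y))$scores,
                 oracle_wepo(g$x, g$y), tolerance = 1e-10)
  }
})

test_that("constant genes score 0 with the degenerate flag set", {
  em <- make_em(rbind(c(7, 7, 7, 7), c(1, 2, 0, 1)),
                labels = c(1, 1, -1, -1))
  r <- wepo_scores(em)
  expect_equal(r$scores[1], 0)
  expect_identical(r$degenerate, c(TRUE, FALSE))
  expect_equal(tnom_scores(em)$scores[1], 2)  # all-one-side rule
})

test_that("TNoM/MDMR are monotone-invariant, WEPO affine-invariant", {
  set.seed(44)
  v <- matrix(rnorm(15 * 10), 15, 10)
  em <- make_em(v, labels = rep(c(1L, -1L), each = 5))
  mono <- make_em(exp(v), labels = em$labels)      # strictly increasing
  affine <- make_em(3 * v + 2, labels = em$labels)
  expect_equal(tnom_scores(mono)$scores, tnom_scores(em)$scores)
  expect_equal(mdmr_scores(mono)$scores, mdmr_scores(em)$scores)
  expect_equal(wepo_scores(affine)$scores, wepo_scores(em)$scores,
               tolerance = 1e-9)
})

test_that("separability is one property: TNoM=0 iff MDMR=0 iff WEPO=0", {
  set.seed(45)
  shift <- sample(c(0, 0.5, 5), 300, replace = TRUE)
  v <- matrix(rnorm(300 * 10), 300, 10)
  v[, 1:5] <- v[, 1:5] + shift
  em <- make_em(v, labels = rep(c(1L, -1L), each = 5))
  tn <- tnom_scores(em)$scores
  md <- mdmr_scores(em)$scores
  we <- wepo_scores(em)$scores
  expect_identical(tn == 0, md == 0)
  expect_identical(tn == 0, we < 1e-12)
  expect_true(any(tn == 0) && any(tn > 0))  # both regimes exercised
})

test_that("nonparametric methods recover planted genes on synthetic data", {
  n_seeds <- 50
  ok <- matrix(FALSE, n_seeds, 3,
               dimnames = list(NULL, c("tnom", "mdmr", "wepo")))
  for (i in seq_len(n_seeds)) {
    truth <- with_seed_helper(1000 + i, sample.int(500, 10))
    sim <- simulate_expression(500, 20, 20, planted = truth, delta = 2,
                               seed = 2000 + i)
    x <- normalize_genes(sim$x)
    ok[i, "tnom"] <- recovered_in_top(tnom_scores(x), truth) >= 8
    ok[i, "mdmr"] <- recovered_in_top(mdmr_scores(x), truth) >= 8
    ok[i, "wepo"] <- recovered_in_top(wepo_scores(x), truth) >= 8
  }
  expect_true(all(colMeans(ok) >= 0.9))
})
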