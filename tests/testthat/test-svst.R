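# KKT conditions for a fitted soft-margin model, at tolerance tol.
kkt_ok <- function(m, tol = 1e-4) {
  yf <- m$labels * m$fx
  a <- m$alpha
  all(a >= -tol, a <= m$C + tol,
      abs(sum(a * m$labels)) < tol,
      yf[a < tol] >= 1 - tol,
      abs(yf[a > tol & a < m$C - tol] - 1) <= tol,
      yf[a > m$C - tol] <= 1 + tol)
}

sim_instance <- function(seed, g = 30, n = 10, delta = 2) {
  truth <- with_seed_helper(seed, sample.int(g, 5))
  sim <- simulate_expression(g, n, n, planted = truth, delta = delta,
                             seed = seed + 1)
  normalize_genes(sim$x)
}

test_that("the 1-D two-point toy has the hand-derived KKT solution", {
  em <- make_em(c(-1, 1), labels = c(-1, 1))
  m <- fit_linear_svm(em, C = 1)
  expect_equal(unname(m$w), 1, tolerance = 1e-4)
  expect_equal(m$b, 0, tolerance = 1e-4)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(m$fx, c(-1, 1), tolerance = 1e-4)
})

test_that("dual feasibility, margin geometry and KKT hold on synthetic fits", {
  for (i in 1:20) {
    m <- fit_linear_svm(sim_instance(800 + 7 * i), C = 1)
    expect_lt(abs(sum(m$alpha * m$labels)), 1e-6)
    expect_true(kkt_ok(m))
  }
})

test_that("an interior point far from the margin gets alpha = 0", {
  # separable 2-D cloud with one deep-interior positive point
  v <- rbind(c(2, 2.2, 1.9, 8, -2, -2.1, -1.8),
             c(0.1, -0.2, 0.15, 0, 0.1, -0.1, 0.2))
  em <- make_em(v, labels = c(1, 1, 1, 1, -1, -1, -1))
  m <- fit_linear_svm(em, C = 1)
  expect_lt(m$alpha[4], 1e-8)          # x = (8, 0) is far inside
  expect_gt(m$labels[4] * m$fx[4], 1)
})

test_that("refitting on the support vectors alone reproduces (w, b)", {
  for (i in 1:20) {
    x <- sim_instance(900 + 11 * i)
    m <- fit_linear_svm(x, C = 1)
    sv <- select_support_samples(m, "all_sv")
    sub <- expression_matrix(x$values[, sv$indices, drop = FALSE],
                             x$gene_ids, x$sample_ids[sv$indices],
                             labels = x$labels[sv$indices])
    m2 <- fit_linear_svm(sub, C = 1)
    expect_equal(m2$w, m$w, tolerance = 1e-4)
    expect_equal(m2$b, m$b, tolerance = 1e-4)
  }
})

test_that("fit agrees with an independent QP solver (kernlab)", {
  skip_if_not_installed("kernlab")
  x <- sim_instance(123)
  m <- fit_linear_svm(x, C = 1)
  k <- kernlab::ksvm(t(x$values), factor(x$labels, levels = c(-1, 1)),
                     kernel = "vanilladot", C = 1, scaled = FALSE,
                     kpar = list())
  w_k <- drop(crossprod(kernlab::coef(k)[[1]],
                        t(x$values)[kernlab::alphaindex(k)[[1]], ,
                                    drop = FALSE]))
  # kernlab's internal sign may be flipped; compare up to overall sign
  s <- sign(sum(w_k * unname(m$w)))
  expect_equal(s * unname(w_k), unname(m$w), tolerance = 1e-3)
  expect_equal(s * -kernlab::b(k), m$b, tolerance = 1e-3)
})

test_that("support-sample selection policies threshold alpha correctly", {
  m <- structure(list(alpha = c(0.5, 0.5, 0, 0), C = 1,
                      labels = c(1L, -1L, 1L, -1L),
                      sample_ids = paste0("s", 1:4),
                      fx = c(1, -1, 2, -2)), class = "SvmModel")
  expect_identical(select_support_samples(m, "all_sv")$indices, c(1L, 2L))
  m$alpha <- c(1.0, 0.3, 0, 0)
  sel <- select_support_samples(m, "unbounded_only")
  expect_identical(sel$indices, 2L)
  expect_identical(select_support_samples(m, "all_sv")$status[1], "bounded")
  m$alpha <- c(1.0, 1.0, 0, 0)
  expect_error(select_support_samples(m, "unbounded_only"), "all_sv")
})

test_that("svst equals snr on the full matrix when every sample is a support vector", {
  # heavy class overlap + small C forces every sample onto/inside the margin
  sim <- simulate_expression(20, 6, 6, planted = 1:2, delta = 0.3,
                             seed = 77)
  x <- normalize_genes(sim$x)
  m <- fit_linear_svm(x, C = 0.01)
  expect_true(all(m$alpha > 1e-8))  # precondition of this fixture
  r <- svst_rank(x, C = 0.01)
  expect_equal(r$scores, snr_scores(x)$scores, tolerance = 1e-9)
  expect_identical(r$n_support, ncol(x$values))
})

test_that("svst drops the deepest-interior samples and ignores alpha-0 samples", {
  x <- sim_instance(222, g = 40, n = 12, delta = 2)
  m <- fit_linear_svm(x, C = 1)
  sv <- select_support_samples(m, "all_sv")
  outside <- setdiff(seq_along(m$alpha), sv$indices)
  expect_true(all(m$labels[outside] * m$fx[outside] > 1 - 1e-4))
  # dropping a non-SV sample leaves the ranking unchanged
  if (length(outside) > 0) {
    keep <- setdiff(seq_along(m$alpha), outside[1])
    x2 <- expression_matrix(x$values[, keep], x$gene_ids,
                            x$sample_ids[keep], labels = x$labels[keep])
    expect_equal(svst_rank(x2, C = 1)$scores, svst_rank(x, C = 1)$scores,
                 tolerance = 1e-6)
  }
})

test_that("the support report tabulates alpha, status and y*f(x)", {
  x <- sim_instance(333)
  m <- fit_linear_svm(x, C = 1)
  rep <- support_report(m)
  expect_identical(nrow(rep), length(m$alpha))
  expect_true(all(rep$status %in% c("non_sv", "unbounded", "bounded")))
  expect_equal(rep$y_fx, m$labels * m$fx)
  expect_true(all(abs(rep$y_fx[rep$status == "unbounded"] - 1) < 1e-4))
})

test_that("svst recovers planted genes on synthetic data", {
  n_seeds <- 50
  ok <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    truth <- with_seed_helper(1000 + i, sample.int(500, 10))
    sim <- simulate_expression(500, 20, 20, planted = truth, delta = 2,
                               seed = 2000 + i)
    x <- normalize_genes(sim$x)
    ok[i] <- recovered_in_top(svst_rank(x, C = 1), truth) >= 8
  }
  expect_gte(mean(ok), 0.9)
})
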