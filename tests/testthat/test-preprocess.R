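test_that("quantile normalization has its defining properties", {
  # identical columns are a fixed point
  m <- matrix(rep(c(1, 5, 9), 3), 3,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  expect_equal(quantile_normalize(m), m)

  # two-point symmetric case: ranks map to cross-column means
  m2 <- matrix(c(1, 2, 3, 4), 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_equal(unname(quantile_normalize(m2)),
               matrix(c(2, 3, 2, 3), 2))

  # random matrix: every column's sorted values equal the row-wise means of
  # the input's sorted columns
  set.seed(1)
  r <- matrix(rexp(200) + 0.1, 50,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
  q <- quantile_normalize(r)
  target <- rowMeans(apply(r, 2, sort))
  for (j in 1:4) expect_equal(unname(sort(q[, j])), target)
  expect_equal(sum(q), sum(r))

  # idempotence
  expect_equal(quantile_normalize(q), q, tolerance = 1e-9)

  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "identity")
})

test_that("median polish summarization matches an independent oracle", {
  d1 <- array_design("e1", list(paste0("p", 1:8)))

  # constant matrix: expression is log2(c) everywhere
  mc <- matrix(32, 8, 3, dimnames = list(paste0("p", 1:8), paste0("s", 1:3)))
  expect_equal(unname(median_polish_summarize(mc, d1)),
               matrix(5, 1, 3))

  # single probe surviving in the matrix: the model collapses to that probe
  msingle <- matrix(c(4, 8, 16), 1, dimnames = list("p1", paste0("s", 1:3)))
  expect_equal(unname(median_polish_summarize(msingle, d1)),
               matrix(c(2, 3, 4), 1))

  # 3 probes x 3 samples toy vs oracle run to convergence
  set.seed(7)
  m3 <- matrix(2^rnorm(9, 8, 1), 3,
               dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  got <- median_polish_summarize(m3, d1, tol = 1e-10, max_iter = 500)
  orc <- oracle_median_polish(log2(m3))
  expect_equal(unname(got[1, ]), unname(orc$overall + orc$col),
               tolerance = 1e-6)

  # an EST whose probes are all absent is an error
  expect_error(
    median_polish_summarize(mc[0, , drop = FALSE], d1), "no design probes")
})

test_that("summarization is equivariant under per-sample constant shifts", {
  # on exactly additive data (the model the polish fits) equivariance is
  # exact: the shift is absorbed entirely by the sample effect
  sim0 <- simulate_experiment(sim_config(n_ests = 25, noise_sd = 0, seed = 6))
  m0 <- sim0$probes[[1]]
  b0 <- median_polish_summarize(m0, sim0$design)
  s0 <- m0
  s0[, 2] <- s0[, 2] * 2^1.7  # +1.7 on the log2 scale
  e0 <- median_polish_summarize(s0, sim0$design)
  expect_equal(e0[, 2], b0[, 2] + 1.7, tolerance = 1e-9)
  expect_equal(e0[, -2], b0[, -2], tolerance = 1e-9)

  # with residual noise the robust sweeps can settle in a nearby fixed
  # point, so equivariance is approximate at the noise scale
  sim <- simulate_experiment(sim_config(n_ests = 25, seed = 6))
  m <- sim$probes[[1]]
  base <- median_polish_summarize(m, sim$design, tol = 1e-10, max_iter = 500)
  shifted <- m
  shifted[, 2] <- shifted[, 2] * 2^1.7
  e2 <- median_polish_summarize(shifted, sim$design, tol = 1e-10,
                                max_iter = 500)
  expect_equal(e2[, 2], base[, 2] + 1.7, tolerance = 0.1)
  expect_equal(e2[, -2], base[, -2], tolerance = 0.1)
})

test_that("median-polish residuals have near-zero row and column medians", {
  set.seed(3)
  y <- matrix(rnorm(44, 8, 1), 11,
              dimnames = list(paste0("p", 1:11), paste0("s", 1:4)))
  fit <- stats::medpolish(y, eps = 0.01, maxiter = 10, trace.iter = FALSE)
  expect_lt(max(abs(apply(fit$residuals, 1, median))), 0.01)
  expect_lt(max(abs(apply(fit$residuals, 2, median))), 0.01)
})

test_that("sample QC flags deviant replicates and only those", {
  sim <- simulate_experiment(sim_config(n_ests = 200, seed = 11))
  d <- sim$design
  expr <- median_polish_summarize(quantile_normalize(sim$probes[[1]]), d)
  sheet <- sim$sheet
  qc <- sample_qc(expr, sheet)
  expect_equal(qc$flagged, character(0))

  # duplicated columns: perfect correlation, no flags
  dup <- expr
  dup[, 2] <- dup[, 1]
  expect_equal(sample_qc(dup, sheet)$flagged, character(0))

  # one column replaced by independent noise gets flagged
  bad <- expr
  bad[, 3] <- rnorm(nrow(bad), 8, 1.5)
  qc_bad <- sample_qc(bad, sheet, threshold = 0.5)
  expect_equal(qc_bad$flagged, colnames(bad)[3])

  # a vacuous threshold flags nothing
  expect_equal(sample_qc(bad, sheet, threshold = 0)$flagged, character(0))
})
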