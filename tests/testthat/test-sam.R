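test_that("d with s0 = 0 is the pooled-variance t statistic", {
  expr <- rbind(a = c(1, 2, 3, 2, 3, 4),
                b = c(4, 5, 6, 4, 5, 6))
  colnames(expr) <- paste0("s", 1:6)
  labels <- rep(c("male", "female"), each = 3)
  r <- compute_d(expr, labels, s0 = 0)

  # textbook two-sample pooled t for (1,2,3) vs (2,3,4)
  x1 <- c(1, 2, 3); x2 <- c(2, 3, 4)
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
               (length(x1) + length(x2) - 2))
  t_text <- (mean(x2) - mean(x1)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(r$d["a"]), t_text)

  # equal group means give d = 0 regardless of s0
  expect_equal(unname(r$d["b"]), 0)
  expect_equal(unname(compute_d(expr, labels, s0 = 5)$d["b"]), 0)

  # swapping the group designation negates every d
  swapped <- compute_d(expr, labels, s0 = 0, control_label = "female",
                       treatment_label = "male")
  expect_equal(swapped$d, -r$d)
  expect_equal(swapped$s, r$s)
})

test_that("degenerate variance with s0 = 0 is rejected", {
  expr <- rbind(a = c(1, 1, 1, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:6)
  labels <- rep(c("male", "female"), each = 3)
  expect_error(compute_d(expr, labels, s0 = 0), "s0")
  expect_equal(unname(compute_d(expr, labels, s0 = 0.5)$d["a"]), 1 / 0.5)
})

test_that("s0 estimation follows its scan criterion and its edge rules", {
  expect_equal(estimate_s0(c(1, 2), c(1, 1), method = "zero"), 0)

  # identical s: any s0 gives the same ordering; the scan returns the
  # smallest candidate
  expect_equal(estimate_s0(rnorm(50), rep(2, 50)), 2)

  # scan agrees with a brute-force oracle over the same candidates
  set.seed(12)
  s <- rexp(1000, 5) + 0.01
  r <- rnorm(1000) * (s + 0.1)
  expect_equal(estimate_s0(r, s), oracle_s0_scan(r, s))

  expect_equal(estimate_s0(r, s, method = "fixed_percentile",
                           s0_percentile = 0.5),
               unname(quantile(s, 0.5)))
})

test_that("permutation null enumerates exhaustively when feasible", {
  set.seed(5)
  expr <- matrix(rnorm(60, 8, 1), 10,
                 dimnames = list(paste0("e", 1:10), paste0("s", 1:6)))
  labels <- rep(c("male", "female"), each = 3)
  cfg <- sam_config(n_permutations = 500, seed = 1)
  null <- permutation_null(expr, labels, s0 = 0.1, cfg)
  expect_equal(null$n_assignments, choose(6, 3))  # 20
  expect_true(null$exhaustive)
  # expected order statistics are non-decreasing
  expect_true(all(diff(null$dbar) >= 0))

  # a request for exactly the total is also exhaustive and identical
  cfg20 <- sam_config(n_permutations = 20, seed = 9)
  null20 <- permutation_null(expr, labels, s0 = 0.1, cfg20)
  expect_equal(null20$dbar, null$dbar)
})

test_that("sampled permutations converge to full enumeration on a 4+4 set", {
  set.seed(8)
  expr <- matrix(rnorm(160, 8, 1), 20,
                 dimnames = list(paste0("e", 1:20), paste0("s", 1:8)))
  labels <- rep(c("male", "female"), each = 4)
  full <- permutation_null(expr, labels, 0.1,
                           sam_config(n_permutations = 70, seed = 1))
  expect_true(full$exhaustive)
  expect_equal(full$n_assignments, 70)
  err <- vapply(c(20, 65), function(B) {
    part <- permutation_null(expr, labels, 0.1,
                             sam_config(n_permutations = B, seed = 2))
    max(abs(part$dbar - full$dbar))
  }, numeric(1))
  expect_lt(err[2], err[1])  # more sampled assignments, closer to the truth
  expect_lt(err[2], 0.2)
})

test_that("delta selection is monotone and handles the no-call regime", {
  set.seed(21)
  G <- 400
  expr <- matrix(rnorm(G * 12, 8, 0.5), G,
                 dimnames = list(sprintf("e%03d", 1:G), paste0("s", 1:12)))
  expr[1:10, 1:6] <- expr[1:10, 1:6] + 1.5  # ten real effects
  labels <- rep(c("male", "female"), each = 6)
  base <- compute_d(expr, labels, 0)
  rr <- base$mean_treatment - base$mean_control
  s0 <- estimate_s0(rr, base$s)
  d <- rr / (base$s + s0)
  cfg <- sam_config(n_permutations = 200, seed = 4)
  null <- permutation_null(expr, labels, s0, cfg)
  sel <- select_delta(d, null, cfg$delta_grid, 0.03, 1)
  tab <- sel$table
  # called set shrinks as delta grows
  expect_true(all(diff(tab$n_called) <= 0))
  # permutation exceedances shrink too
  expect_true(all(diff(tab$median_false) <= 1e-9))
  # a huge delta calls nothing
  expect_warning(
    none <- select_delta(d, null, delta_grid = 50, 0.03, 1), "no delta")
  expect_equal(none$n_called, 0)
  expect_equal(none$fdr, 0)
})

test_that("full SAM run calls planted effects with correct direction", {
  sim <- simulate_experiment(sim_config(n_ests = 600, seed = 14,
                                        frac_z = 0.2,
                                        frac_z_uncompensated = 0.5,
                                        dosage_log2fc = log2(1.5),
                                        frac_effect_shared = 1))
  expr <- median_polish_summarize(quantile_normalize(sim$probes[[1]]),
                                  sim$design)
  sheet <- sim$sheet[sim$sheet$species == names(sim$probes)[1], ]
  sex <- sheet$sex[match(colnames(expr), sheet$sample_id)]
  res <- sam(expr, sex, sam_config(n_permutations = 200, seed = 3))
  sig <- res$est[res$est$significant, ]
  expect_gt(nrow(sig), 10)
  truth <- sim$truth
  planted <- truth$est_id[truth$direction == "male"]
  hits <- intersect(sig$est_id, planted)
  expect_gte(length(hits) / nrow(sig), 0.85)
  expect_true(all(sig$direction[sig$est_id %in% planted] == "male"))

  # direction calls do not depend on which sex is the control group
  cfg_sw <- sam_config(n_permutations = 200, seed = 3,
                       control_label = "female", treatment_label = "male")
  res_sw <- sam(expr, sex, cfg_sw)
  expect_equal(res_sw$est$direction, res$est$direction)
})

test_that("fold changes follow the unlogged male-over-female definition", {
  expr <- log2(rbind(same = rep(6, 6),
                     dbl = c(10, 10, 10, 5, 5, 5),
                     mixed = c(8, 10, 12, 5, 5, 5)))
  colnames(expr) <- paste0("s", 1:6)
  sex <- rep(c("male", "female"), each = 3)
  fc <- fold_change(expr, sex = sex)
  expect_equal(unname(fc["same"]), 1)
  expect_equal(unname(fc["dbl"]), 2)
  expect_equal(unname(fc["mixed"]), 10 / 5)
})
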