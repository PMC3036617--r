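test_that("chromosome classification applies the E-value significance rule", {
  expect_equal(classify_chromosome("Z", 1e-30), "Z")
  expect_equal(classify_chromosome("Z", 1e-10), "none")   # hit too weak
  expect_equal(classify_chromosome("Z", 1e-20), "Z")      # boundary included
  expect_equal(classify_chromosome("4", 1e-25), "autosomal")
  expect_equal(classify_chromosome("none", NA_real_), "none")
  expect_equal(classify_chromosome(NA, 1e-30), "none")
  expect_equal(classify_chromosome(c("Z", "1", "none"),
                                   c(1e-30, 1e-5, NA)),
               c("Z", "none", "none"))
})

test_that("collapse groups shared gene ids and detects ambiguity", {
  fx <- build_call_fixture(list(
    list(n_est_male = 2),                      # multi, consistent
    list(n_est_male = 1, n_est_female = 1),    # ambiguous
    list(n_est_male = 1)                       # singleton
  ))
  gc <- collapse_genes(fx$calls, fx$design)
  expect_equal(gc$n_genes, 3)
  expect_equal(gc$n_multi, 2)
  expect_equal(gc$n_ambiguous, 1)
  amb <- gc$genes[gc$genes$direction == "ambiguous", ]
  expect_equal(amb$majority_direction, "tie")
  expect_equal(gc$genes$mean_fc[gc$genes$gene_id == "G0001"], 1.1)

  # every significant EST lands in exactly one gene
  members <- unlist(strsplit(gc$genes$est_ids, ","))
  expect_setequal(members, fx$calls$est_id)
  expect_equal(anyDuplicated(members), 0)
})

test_that("ESTs without gene annotation stay singleton genes", {
  d <- toy_design(3, 8, gene_id = c(NA, NA, "g9"),
                  chromosome = "Z", evalue = 1e-30)
  calls <- data.frame(est_id = d$est$est_id,
                      direction = c("male", "female", "male"),
                      fc = c(1.2, 0.8, 1.3), stringsAsFactors = FALSE)
  gc <- collapse_genes(calls, d)
  expect_equal(gc$n_genes, 3)
  expect_equal(gc$n_ambiguous, 0)
})

test_that("mixed-chromosome genes warn and resolve by majority", {
  est_id <- c("e1", "e2", "e3")
  d <- array_design(est_id, lapply(est_id, function(e) paste0(e, "_", 1:8)),
                    gene_id = "g1",
                    chromosome = c("Z", "Z", "5"),
                    evalue = 1e-30)
  calls <- data.frame(est_id = est_id, direction = "male", fc = 1.1,
                      stringsAsFactors = FALSE)
  expect_warning(gc <- collapse_genes(calls, d), "different chromosome")
  expect_equal(gc$genes$chromosome_class, "Z")

  d2 <- array_design(est_id[1:2],
                     lapply(est_id[1:2], function(e) paste0(e, "_", 1:8)),
                     gene_id = "g1", chromosome = c("Z", "5"),
                     evalue = 1e-30)
  expect_warning(gc2 <- collapse_genes(calls[1:2, ], d2), "different")
  expect_equal(gc2$genes$chromosome_class, "none")  # tie
})

test_that("a 509-EST fixture collapses to 417 genes with 64 multi and 15 ambiguous", {
  # direction-consistent composition: 339 male + 14 female singletons,
  # 44 male multi-EST genes (38x2 + 6x5 = 106 ESTs), 5 female multi
  # (5x4 = 20 ESTs), 15 ambiguous genes (1 male + 1 female EST each)
  spec_genes <- c(
    replicate(339, list(n_est_male = 1), simplify = FALSE),
    replicate(14, list(n_est_female = 1), simplify = FALSE),
    replicate(38, list(n_est_male = 2), simplify = FALSE),
    replicate(6, list(n_est_male = 5), simplify = FALSE),
    replicate(5, list(n_est_female = 4), simplify = FALSE),
    replicate(15, list(n_est_male = 1, n_est_female = 1), simplify = FALSE)
  )
  fx <- build_call_fixture(spec_genes)
  expect_equal(nrow(fx$calls), 509)
  expect_equal(sum(fx$calls$direction == "male"), 460)
  expect_equal(sum(fx$calls$direction == "female"), 49)

  gc <- collapse_genes(fx$calls, fx$design)
  expect_equal(gc$n_genes, 417)
  expect_equal(gc$n_multi, 64)
  expect_equal(gc$n_ambiguous, 15)
  expect_equal(sum(gc$genes$direction == "male"), 383)
  expect_equal(sum(gc$genes$direction == "female"), 19)
})

test_that("direction-wise summary reports counts, percentages and mean FC", {
  fx <- build_call_fixture(list(
    list(n_est_male = 1), list(n_est_male = 1), list(n_est_male = 1),
    list(n_est_female = 1)
  ))
  t1 <- summarize_table1(collapse_genes(fx$calls, fx$design), fx$calls)
  expect_equal(t1$n_ests, c(3, 1))
  expect_equal(t1$pct_ests, c(75, 25))
  expect_equal(sum(t1$pct_ests), 100)
  expect_equal(t1$mean_fc_genes, c(1.1, 0.8))

  # a single significant EST scores 100% for its direction
  fx1 <- build_call_fixture(list(list(n_est_male = 1)))
  t2 <- summarize_table1(collapse_genes(fx1$calls, fx1$design), fx1$calls)
  expect_equal(t2$pct_ests[t2$direction == "male"], 100)
})
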