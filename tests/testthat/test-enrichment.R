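test_that("one-sided Fisher matches hand values and brute enumeration", {
  # degenerate table carries no information
  expect_equal(fisher_one_sided(0, 0, 0, 0, "greater"), 1)
  # the worked 2x2: perfect split of 10 into 5/5
  expect_equal(fisher_one_sided(5, 0, 0, 5, "greater"), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(fisher_one_sided(-1, 0, 0, 5), "negative")
  # oracle equivalence over 500 random small tables, both directions
  set.seed(61)
  for (i in 1:500) {
    tb <- sample(0:12, 4, replace = TRUE)
    dir <- sample(c("greater", "less"), 1)
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4], dir),
                 fisher_brute(tb[1], tb[2], tb[3], tb[4], dir),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment is the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_length(bh_adjust(numeric(0)), 0L)
  set.seed(62)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_literal(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # order invariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), q[o])
  }
})

test_that("element testing flags planted contingencies in both directions", {
  observed <- data.frame(
    element_id = c(sprintf("n%02d", 1:20), "up", "down"),
    element_class = "3UTR",
    obs_ribo = c(rbinom(20, 30, 0.03), 12L, 0L),
    obs_total = 30L)
  set.seed(63)
  observed$obs_ribo[1:20] <- rbinom(20, 30, 0.03)
  expected <- data.frame(
    element_id = observed$element_id,
    exp_ribo = c(rep(6L, 20), 6L, 60L),
    exp_total = 200L)
  res <- test_elements(observed, expected)
  expect_equal(nrow(res), 22L)
  up <- res[res$element_id == "up", ]
  down <- res[res$element_id == "down", ]
  expect_lt(up$q_enriched, 0.05)
  expect_lt(down$q_depleted, 0.05)
  expect_gt(up$odds_ratio, 1)
  expect_lt(down$odds_ratio, 1)
  expect_equal(up$call_q0.05, "enriched")
  expect_equal(down$call_q0.05, "depleted")
  # p-values in both directions cover the whole table space
  expect_true(all(res$p_enriched > 0 & res$p_enriched <= 1))
  expect_true(all(res$q_enriched >= res$p_enriched - 1e-15))
  # unmatched elements are excluded with a warning
  expect_warning(
    res2 <- test_elements(observed,
                          expected[expected$element_id != "up", ]),
    "excluded")
  expect_false("up" %in% res2$element_id)
})

test_that("null contingencies stay unflagged", {
  set.seed(64)
  observed <- data.frame(
    element_id = sprintf("n%02d", 1:30), element_class = "5UTR",
    obs_ribo = rbinom(30, 30, 0.025), obs_total = 30L)
  expected <- data.frame(
    element_id = observed$element_id,
    exp_ribo = rbinom(30, 200, 0.025), exp_total = 200L)
  res <- test_elements(observed, expected)
  expect_equal(sum(res$q_enriched < 0.05), 0L)
  expect_equal(sum(res$q_depleted < 0.05), 0L)
})

test_that("cancer specificity uses a strict 1e-3 threshold", {
  # identical proportions are never specific
  same <- cancer_specific_test(5, 50, 5, 50)
  expect_false(same$is_specific)
  # complete separation of 40 mutations
  sep <- cancer_specific_test(20, 20, 0, 20)
  expect_equal(sep$p, 1 / choose(40, 20), tolerance = 1e-12)
  expect_true(sep$is_specific)
  # zero totals give p = 1
  expect_equal(cancer_specific_test(0, 0, 3, 10)$p, 1)
  # boundary: p exactly at the threshold is NOT specific
  fake <- cancer_specific_test(20, 20, 0, 20, p_threshold = sep$p)
  expect_false(fake$is_specific)
  # depletion direction
  dep <- cancer_specific_test(0, 30, 15, 30, direction = "less")
  expect_lt(dep$p, 1e-3)
  expect_true(dep$is_specific)
})

test_that("binding-site overlap enrichment and padding arithmetic", {
  calls <- data.frame(
    chrom = "chrT",
    pos = c(100L, 105L, 300L, 301L, 302L, 120L, 121L, 400L),
    label = c(rep("ribosnitch", 5), rep("non_ribosnitch", 3)))
  feats <- data.frame(chrom = "chrT", start = 95L, end = 110L)  # 0-based
  ov <- feature_overlap_enrichment(calls, feats, pad = 0L)
  expect_equal(unname(ov$table["ribosnitch", "inside"]), 2L)
  expect_equal(unname(ov$table["non_ribosnitch", "inside"]), 0L)
  # padding pulls boundary positions in: pos 120/121 are 10/11 beyond end
  ov20 <- feature_overlap_enrichment(calls, feats, pad = 20L)
  expect_equal(unname(ov20$table["non_ribosnitch", "inside"]), 2L)
  ov10 <- feature_overlap_enrichment(calls, feats, pad = 10L)
  expect_equal(unname(ov10$table["non_ribosnitch", "inside"]), 1L)
  # all mutations outside features -> p = 1
  far <- data.frame(chrom = "chrT", start = 5000L, end = 5100L)
  expect_equal(feature_overlap_enrichment(calls, far)$p, 1)
  # planted overlap scores small p
  set.seed(65)
  big <- data.frame(
    chrom = "chrT",
    pos = c(sample(95:110, 30, TRUE), sample(1000:2000, 30, TRUE)),
    label = rep(c("ribosnitch", "non_ribosnitch"), each = 30))
  expect_lt(feature_overlap_enrichment(big, feats)$p, 1e-4)
  expect_error(feature_overlap_enrichment(
    data.frame(chrom = "chrT", pos = 1L, label = "intermediate"), feats),
    "no labeled")
})
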