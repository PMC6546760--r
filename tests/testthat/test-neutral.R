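test_that("trinucleotide composition counts collapsed contexts", {
  # ACAG: ACA -> class(C;A,A); CAG -> center A, collapsed CTG -> class(T;C,G)
  comp <- transcript_composition("ACAG")
  expect_equal(sum(comp), 2L)
  expect_equal(unname(comp[["ACA"]]), 1L)
  expect_equal(unname(comp[["CTG"]]), 1L)
  # poly-A collapses entirely to TTT
  pa <- transcript_composition(strrep("A", 30))
  expect_equal(unname(pa[["TTT"]]), 28L)
  expect_equal(sum(pa), 28L)
  # N-free sequences always count L - 2 contexts
  set.seed(51)
  for (i in 1:10) {
    L <- sample(3:200, 1)
    expect_equal(sum(transcript_composition(rand_seq(L))), L - 2L)
  }
  # N-containing windows are skipped
  expect_equal(sum(transcript_composition("ACNGA")), 0L)
  expect_error(transcript_composition("AC"), "shorter")
})

test_that("profile building normalizes counts both ways", {
  intronic <- data.frame(region = "intron",
                         subst_class96 = c(0L, 0L, 17L, 40L))
  p <- build_profile(intronic)
  expect_s3_class(p, "mutation_profile")
  expect_equal(sum(p$rate), 1, tolerance = 1e-12)
  expect_equal(unname(p$rate[1]), 0.5)
  # doubling counts leaves frequencies unchanged
  p2 <- build_profile(intronic[rep(1:4, 2), ])
  expect_equal(p2$rate, p$rate)
  # per-context mode divides by context occurrences
  ctx <- rep(0, 32)
  ctx[ribosnitch:::context_of_class96(c(0L, 17L, 40L)) + 1] <- c(10, 20, 40)
  pr <- build_profile(intronic, ctx, normalization = "per_context_rate")
  expect_equal(unname(pr$rate[1]), 2 / 10)
  expect_equal(unname(pr$rate[18]), 1 / 20)
  # observed class without context occurrences is inconsistent input
  expect_error(build_profile(intronic, rep(0, 32), "per_context_rate"),
               "zero context")
  expect_error(build_profile(intronic[0, ]), "no classified")
})

test_that("profile recovery from simulated draws", {
  set.seed(52)
  target <- runif(96)^2
  target <- target / sum(target)
  draws <- sample.int(96, 1e5, replace = TRUE, prob = target) - 1L
  est <- build_profile(data.frame(region = "intron", subst_class96 = draws))
  tv <- sum(abs(est$rate - target)) / 2
  expect_lt(tv, 0.02)
})

test_that("recalibration weights profile by composition", {
  prof <- as_mutation_profile(rep(1, 96))
  # composition concentrated in one context restricts sampling to its 3
  # pyrimidine substitution classes (uniform among them)
  comp <- rep(0, 32); comp[1] <- 5
  d <- recalibrate_profile(prof, comp)
  expect_equal(sum(d), 1)
  on <- which(d > 0) - 1L
  expect_equal(unname(ribosnitch:::context_of_class96(on)),
               rep(0L, length(on)))
  expect_equal(unname(d[on + 1]), rep(1 / length(on), length(on)))
  # flat composition recovers the profile itself
  prof2 <- as_mutation_profile((1:96) / sum(1:96))
  dflat <- recalibrate_profile(prof2, rep(1, 32))
  expect_equal(unname(dflat), unname(prof2$rate), tolerance = 1e-12)
  # two-context hand example
  prof3 <- as_mutation_profile(c(rep(2, 16), rep(1, 80)))
  comp3 <- rep(0, 32); comp3[1] <- 3; comp3[17] <- 1
  d3 <- recalibrate_profile(prof3, comp3)
  # context 0 (A-C-A) hosts classes {0,16,32} with rates {2,1,1} and weight
  # 3; context 16 (A-T-A) hosts {48,64,80} with rate 1 and weight 1:
  # class 0 gets 2*3 / (3*(2+1+1) + 1*3) = 6/15
  expect_equal(unname(d3[1]), 6 / 15, tolerance = 1e-12)
  expect_error(recalibrate_profile(prof, rep(0, 32)), "incompatible")
})

test_that("simulated mutations respect contexts, classes and the seed", {
  set.seed(53)
  s <- rand_seq(300)
  prof <- as_mutation_profile(runif(96))
  d <- recalibrate_profile(prof, transcript_composition(s))
  sim <- simulate_mutations(s, d, 500)
  # every simulated site carries the reference base it claims
  expect_equal(substring(s, sim$k + 1, sim$k + 1), sim$ref_t)
  expect_true(all(sim$ref_t != sim$alt_t))
  # class labels match reclassification of the drawn site
  tri <- substring(s, sim$k, sim$k + 2)
  recls <- classify_substitution(tri, sim$ref_t, sim$alt_t)
  expect_equal(recls$subst_class96, sim$subst_class96)
  # determinism under the seed
  set.seed(99); a <- simulate_mutations(s, d, 50)
  set.seed(99); b <- simulate_mutations(s, d, 50)
  expect_identical(a, b)
  # interval restriction
  set.seed(1)
  si <- simulate_mutations(s, d, 100, interval = c(50L, 120L))
  expect_true(all(si$k >= 50 & si$k < 120))
  # single supported class on a single matching site
  one <- rep(0, 96); one[1] <- 1
  s1 <- paste0("CCCCC", "ACA", "CCCCC")   # exactly one A_A context with C
  # ACA is the only class-0 context; all draws identical
  set.seed(2)
  mono <- simulate_mutations(s1, setNames(one, subst_class_labels()), 20)
  expect_equal(unique(mono$k), 6L)
  expect_equal(unique(mono$alt_t), "A")
})

test_that("simulated class frequencies match the target distribution", {
  set.seed(54)
  s <- rand_seq(400)
  prof <- as_mutation_profile(runif(96))
  d <- recalibrate_profile(prof, transcript_composition(s))
  # restrict to classes with at least one eligible interior site
  sim <- simulate_mutations(s, d, 2e4)
  freq <- tabulate(sim$subst_class96 + 1L, 96) / nrow(sim)
  active <- d > 0
  # 3-sigma multinomial envelope per class
  sigma <- sqrt(d * (1 - d) / nrow(sim))
  expect_true(all(abs(freq[active] - d[active]) <= 3 * sigma[active] + 1e-3))
})

test_that("expected counts come from the pooled simulated distribution", {
  set.seed(55)
  sims <- data.frame(
    element_id = rep(c("e1", "e2"), each = 200),
    mean_diff = c(runif(200, 0, 0.3), runif(200, 0.2, 1)),
    euc_diff = c(runif(200, 0, 0.3), runif(200, 0.2, 1)))
  ex <- expected_ribo_count(sims, 0.025, 0.025)
  expect_equal(ex$expected_total, 400L)
  expect_equal(sum(ex$per_element$exp_ribo), ex$expected_ribo)
  expect_lte(ex$expected_ribo, ceiling(0.025 * 400))
  # the structured element owns the tail
  expect_gt(ex$per_element$exp_ribo[ex$per_element$element_id == "e2"],
            ex$per_element$exp_ribo[ex$per_element$element_id == "e1"])
})

test_that("intron composition counts all gap 3-mers", {
  g <- tiny_genome(paste0(strrep("A", 10), "GCGT", strrep("A", 10)))
  tr <- tiny_transcript(rbind(c(0L, 10L), c(14L, 24L)))
  ic <- intron_composition(tr, g)
  expect_equal(sum(ic), 2L)    # GCG and CGT
  single <- tiny_transcript(cbind(0L, 10L))
  expect_equal(sum(intron_composition(single, g)), 0L)
})
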